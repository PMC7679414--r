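## Annotation handling: secretion consensus, accounting categories,
## enzyme-class membership.

LPMO_FAMILIES <- c("AA9", "AA11", "AA13", "AA14", "AA16")

#' Two-of-three secretion consensus
#'
#' A protein is called secreted when at least two of the three
#' signal-peptide predictors call it secreted. A missing predictor output
#' counts as a "not secreted" vote (a predictor that returned nothing found
#' no signal peptide).
#'
#' @param calls logical matrix with three columns (one per predictor), or a
#'   single logical vector of length three.
#' @return logical vector, one consensus call per row.
#' @examples
#' consensusSecretion(c(TRUE, TRUE, FALSE))   # TRUE
#' consensusSecretion(c(TRUE, FALSE, FALSE))  # FALSE
#' @export
consensusSecretion <- function(calls) {
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != 3L)
    stop("exactly three predictor calls are required")
  calls[is.na(calls)] <- FALSE
  unname(rowSums(calls) >= 2L)
}

## Family token helpers: "GH5" -> class prefix "GH"; "AA3_2" -> base "AA3".
familyPrefix <- function(fam) sub("^([A-Za-z]+).*$", "\\1", fam)
familyBase <- function(fam) sub("_.*$", "", fam)

#' Assign the single accounting category of a protein
#'
#' Implements the precedence used for secretome summary tables: a catalytic
#' CAZy domain (GH, CE, PL or AA; LPMO families AA9/11/13/14/16 are flagged
#' separately within AA) beats a peptidase domain — in particular a protein
#' annotated both as carbohydrate esterase and as peptidase is counted as a
#' carbohydrate esterase only. A protein with a CBM but no catalytic CAZy
#' domain is "CBM-only". A protein with no CAZy and no peptidase domain is
#' "uncharacterized" when its description is empty or itself says
#' uncharacterized/hypothetical, and "other" when the description names some
#' non-carbohydrate-active function.
#'
#' @param cazy character vector of CAZy family tokens (e.g. "GH5", "AA3_2",
#'   "CBM1").
#' @param peptidase character vector of MEROPS family tokens.
#' @param description free-text description (may be empty or NA).
#' @return one of "GH", "CE", "PL", "AA", "LPMO", "CBM-only", "peptidase",
#'   "uncharacterized", "other".
#' @examples
#' assignCategory(c("CE1"), c("S9"), "")        # "CE"
#' assignCategory(c("CBM1"), character(), "")   # "CBM-only"
#' assignCategory(character(), character(), "uncharacterized protein")
#' @export
assignCategory <- function(cazy = character(), peptidase = character(),
                           description = "") {
  cazy <- cazy[!is.na(cazy) & nzchar(cazy)]
  peptidase <- peptidase[!is.na(peptidase) & nzchar(peptidase)]
  pref <- familyPrefix(cazy)
  for (cl in c("GH", "CE", "PL", "AA")) {
    if (any(pref == cl)) {
      if (cl == "AA" && any(familyBase(cazy) %in% LPMO_FAMILIES))
        return("LPMO")
      return(cl)
    }
  }
  if (length(peptidase)) return("peptidase")
  if (any(pref == "CBM")) return("CBM-only")
  if (is.na(description) || !nzchar(trimws(description)) ||
      grepl("uncharacteri[sz]ed|hypothetical|unknown", description,
            ignore.case = TRUE))
    return("uncharacterized")
  "other"
}

#' Categories counted as CAZymes in secretome summaries
#'
#' Includes stand-alone CBMs, matching the summary-table convention.
#' @return character vector of category labels.
#' @export
cazymeCategories <- function() c("GH", "CE", "PL", "AA", "LPMO", "CBM-only")

#' Construct an AnnotationSet
#'
#' Derives the secretion consensus and the accounting category from the raw
#' annotation columns.
#'
#' @param protein character protein ids (unique).
#' @param cazy,peptidase lists (or CharacterList) of family tokens per
#'   protein.
#' @param signalp,phobius,wolfpsort logical predictor calls per protein
#'   (NA = no call = not-secreted vote).
#' @param description character free text per protein.
#' @return an \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(protein, cazy = NULL, peptidase = NULL,
                          signalp = FALSE, phobius = FALSE,
                          wolfpsort = FALSE, description = "") {
  n <- length(protein)
  toCL <- function(x) {
    if (is.null(x)) x <- rep(list(character()), n)
    if (!is(x, "CharacterList")) x <- CharacterList(x)
    x
  }
  cazy <- toCL(cazy); peptidase <- toCL(peptidase)
  calls <- cbind(signalp = rep_len(as.logical(signalp), n),
                 phobius = rep_len(as.logical(phobius), n),
                 wolfpsort = rep_len(as.logical(wolfpsort), n))
  description <- rep_len(as.character(description), n)
  category <- vapply(seq_len(n), function(i)
    assignCategory(cazy[[i]], peptidase[[i]], description[i]), "")
  new("AnnotationSet", protein = protein, cazy = cazy,
      peptidase = peptidase, calls = calls, description = description,
      secreted = consensusSecretion(calls), category = category)
}

#' @describeIn AnnotationSet protein ids.
#' @param x an AnnotationSet.
#' @export
setMethod("proteinIds", "AnnotationSet", function(x, ...) x@protein)

#' @describeIn AnnotationSet CharacterList of CAZy families.
#' @export
setMethod("cazyFamilies", "AnnotationSet", function(x) {
  names(x@cazy) <- x@protein
  x@cazy
})

#' @describeIn AnnotationSet CharacterList of MEROPS families.
#' @export
setMethod("peptidaseFamilies", "AnnotationSet", function(x) {
  names(x@peptidase) <- x@protein
  x@peptidase
})

#' @describeIn AnnotationSet logical predictor-call matrix.
#' @export
setMethod("predictorCalls", "AnnotationSet", function(x) {
  m <- x@calls; rownames(m) <- x@protein; m
})

#' @describeIn AnnotationSet named logical consensus-secretion vector.
#' @export
setMethod("isSecreted", "AnnotationSet",
          function(x) structure(x@secreted, names = x@protein))

#' @describeIn AnnotationSet named category vector.
#' @export
setMethod("categories", "AnnotationSet",
          function(x) structure(x@category, names = x@protein))

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet:", length(object@protein), "proteins\n")
  print(table(object@category))
  cat("  secreted (consensus):", sum(object@secreted), "\n")
})

#' Map enzyme classes to their member proteins
#'
#' Divides the annotated proteins into (possibly overlapping) enzyme-class
#' sets via a family-to-class map: a protein belongs to every class any of
#' its families maps to, so multi-domain proteins and families mapped to
#' several classes (GH5 counts as both endoglucanase and endomannanase)
#' appear in multiple sets. A subfamily token ("AA3_2") is matched against a
#' subfamily-specific map row first and falls back to its base family
#' ("AA3") otherwise. Families found in neither form trigger one warning and
#' are skipped.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param classMap data.frame with columns \code{family}, \code{class}
#'   (see [defaultEnzymeClassMap()]).
#' @param proteins optional subset of protein ids to consider.
#' @return named list: class label -> character vector of member protein
#'   ids (every class in the map is present, possibly empty).
#' @export
classMembers <- function(annotations, classMap = defaultEnzymeClassMap(),
                         proteins = NULL) {
  stopifnot(all(c("family", "class") %in% colnames(classMap)))
  ids <- proteinIds(annotations)
  fams <- cazyFamilies(annotations)
  if (!is.null(proteins)) {
    keep <- ids %in% proteins
    ids <- ids[keep]; fams <- fams[keep]
  }
  classes <- unique(classMap$class)
  sets <- stats::setNames(rep(list(character()), length(classes)), classes)
  unknown <- character()
  for (i in seq_along(ids)) {
    for (fam in unique(fams[[i]])) {
      hit <- classMap$class[classMap$family == fam]
      if (!length(hit))
        hit <- classMap$class[classMap$family == familyBase(fam)]
      if (!length(hit)) {
        if (familyPrefix(fam) != "CBM") unknown <- c(unknown, fam)
        next
      }
      for (cl in unique(hit)) sets[[cl]] <- c(sets[[cl]], ids[i])
    }
  }
  if (length(unknown))
    warning("families not in the class map were skipped: ",
            paste(sort(unique(unknown)), collapse = ", "))
  lapply(sets, function(s) sort(unique(s)))
}

#' Read a family-to-class map from TSV
#'
#' @param path TSV with columns \code{family}, \code{class}.
#' @return data.frame with those two character columns.
#' @export
readEnzymeClassMap <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "class") %in% colnames(m)))
  m[, c("family", "class")]
}

#' Built-in CAZy-family to enzyme-class map
#'
#' Transcribes the standard lignocellulose-deconstruction class scheme
#' (endoglucanases GH5/7/12/45, cellobiohydrolases GH6/7, cellulose-active
#' LPMOs AA9, xylanases GH10/11, ... , with AA3 and AA5 subfamilies kept
#' separate for class differentiation). Shipped as
#' \code{extdata/enzyme_class_map.tsv}; users may supply their own via
#' [readEnzymeClassMap()].
#'
#' @return data.frame with columns \code{family}, \code{class}.
#' @export
defaultEnzymeClassMap <- function() {
  readEnzymeClassMap(system.file("extdata", "enzyme_class_map.tsv",
                                 package = "secretomeNet", mustWork = TRUE))
}
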
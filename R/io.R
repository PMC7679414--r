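## Readers and writers for the reduced TSV dialects: abundance tables keyed
## fungus|substrate|replicate, dbCAN-style family tables, MEROPS-style
## tables, per-predictor boolean call tables.

#' Read a protein x sample LFQ abundance table
#'
#' TSV with a \code{protein_id} column followed by one column per sample,
#' named \code{fungus|substrate|replicate}. Intensities of 0 and blank
#' cells are recorded as missing ("not detected"), the usual LFQ output
#' convention.
#'
#' @param path TSV file path.
#' @param scale \code{"linear"} (default, raw intensities) or \code{"log2"}.
#' @return a \linkS4class{SecretomeExperiment}.
#' @export
readAbundance <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "protein_id")
    stop("first column must be 'protein_id'")
  ids <- as.character(tab$protein_id)
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keys <- colnames(tab)[-1]
  design <- parseSampleKey(keys)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[!is.na(m) & m == 0] <- NA  # zero intensity = not detected
  rownames(m) <- ids
  SecretomeExperiment(m, fungus = design$fungus,
                      substrate = design$substrate,
                      replicate = design$replicate, scale = scale)
}

#' Write a SecretomeExperiment as an abundance TSV
#'
#' Inverse of [readAbundance()]: missing entries are written as 0 on linear
#' scale (and as empty cells on log2 scale, where 0 is a valid value).
#' Values are written with 17 significant digits so that read-back
#' round-trips exactly.
#'
#' @param x a \linkS4class{SecretomeExperiment}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeAbundance <- function(x, path) {
  m <- abundances(x)
  fmt <- function(v) {
    out <- ifelse(is.na(v),
                  if (metadata(x)$scale == "linear") "0" else "",
                  sprintf("%.17g", v))
    out
  }
  if (nrow(m) == 0) {
    writeLines(paste(c("protein_id", colnames(m)), collapse = "\t"), path)
    return(invisible(path))
  }
  cells <- apply(m, 2, fmt)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(m))
  df <- data.frame(protein_id = rownames(m), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("protein_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTwoColumn <- function(path, valueCol) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", valueCol) %in% colnames(tab)))
    stop("expected columns protein_id, ", valueCol, " in ", path)
  tab
}

#' Read reduced annotation tables into an AnnotationSet
#'
#' Consumes the reduced TSV dialects: a dbCAN-style table
#' (\code{protein_id}, \code{family}; one row per domain), a MEROPS-style
#' table (same shape), three per-predictor call tables (\code{protein_id},
#' \code{secreted} boolean) and an optional description table
#' (\code{protein_id}, \code{description}). Proteins absent from a
#' predictor table get a "no call" (= not-secreted) vote.
#'
#' @param cazyPath,meropsPath,signalpPath,phobiusPath,wolfpsortPath TSV
#'   paths; predictor paths may be \code{NA} (all votes FALSE).
#' @param descriptionPath optional TSV path.
#' @param proteins protein universe; defaults to the union of ids seen.
#' @return an \linkS4class{AnnotationSet}.
#' @export
readAnnotations <- function(cazyPath, meropsPath, signalpPath, phobiusPath,
                            wolfpsortPath, descriptionPath = NULL,
                            proteins = NULL) {
  cz <- readTwoColumn(cazyPath, "family")
  mp <- readTwoColumn(meropsPath, "family")
  preds <- lapply(c(signalpPath, phobiusPath, wolfpsortPath), function(p) {
    if (is.na(p)) return(NULL)
    readTwoColumn(p, "secreted")
  })
  if (is.null(proteins))
    proteins <- sort(unique(c(cz$protein_id, mp$protein_id,
                              unlist(lapply(preds, `[[`, "protein_id")),
                              if (!is.null(descriptionPath))
                                readTwoColumn(descriptionPath,
                                              "description")$protein_id)))
  splitFams <- function(tab)
    lapply(proteins, function(p)
      unique(as.character(tab$family[tab$protein_id == p])))
  callOf <- function(tab) {
    v <- rep(FALSE, length(proteins))
    if (!is.null(tab)) {
      idx <- match(tab$protein_id, proteins)
      v[idx[!is.na(idx)]] <- as.logical(tab$secreted[!is.na(idx)])
    }
    v
  }
  desc <- rep("", length(proteins))
  if (!is.null(descriptionPath)) {
    dt <- readTwoColumn(descriptionPath, "description")
    idx <- match(dt$protein_id, proteins)
    desc[idx[!is.na(idx)]] <- as.character(dt$description[!is.na(idx)])
  }
  AnnotationSet(proteins, cazy = splitFams(cz), peptidase = splitFams(mp),
                signalp = callOf(preds[[1]]), phobius = callOf(preds[[2]]),
                wolfpsort = callOf(preds[[3]]), description = desc)
}
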
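## Synthetic multi-fungus LFQ secretome studies with planted co-induced
## enzyme-class pairs, for end-to-end validation of the pipeline.

defaultClassCatalog <- function()
  c(endoglucanase = 6L, cellobiohydrolase = 6L, xylanase = 6L,
    feruloyl_esterase = 6L, LPMO_cellulose = 6L, oxidoreductase = 6L,
    polygalacturonase = 6L, endomannanase = 6L)

defaultFamilyPool <- function()
  c("GH12", "GH6", "GH10", "CE1", "AA9", "AA3_2", "GH28", "GH26", "GH11",
    "GH45", "CE16", "AA2", "GH43", "GH51", "PL1", "CE15", "AA1", "AA7",
    "GH1", "GH2", "GH3", "GH78", "CE8", "AA4", "AA6", "AA12")

## Default induction design: two planted co-induced pairs
## (endoglucanase+cellobiohydrolase on all polymeric substrates;
## xylanase+feruloyl esterase on the hemicellulose-rich ones), the other
## classes each with their own distinct substrate pattern, and no
## induction on the free sugar.
defaultInduction <- function(classes, substrates, freeSugar, effect = 4) {
  M <- matrix(0, length(classes), length(substrates),
              dimnames = list(classes, substrates))
  plan <- list(endoglucanase = c("bagasse", "birch", "spruce", "cellulose"),
               cellobiohydrolase = c("bagasse", "birch", "spruce",
                                     "cellulose"),
               xylanase = c("bagasse", "birch"),
               feruloyl_esterase = c("bagasse", "birch"),
               LPMO_cellulose = "cellulose",
               oxidoreductase = "spruce",
               polygalacturonase = "bagasse",
               endomannanase = c("birch", "spruce"))
  for (cl in intersect(classes, names(plan)))
    M[cl, intersect(plan[[cl]], substrates)] <- effect
  M[, freeSugar] <- 0
  M
}

#' Configure a synthetic secretome study
#'
#' The generative model works on the log2 scale: protein baseline
#' \eqn{b_p \sim N(\mu, \sigma^2)} shared across fungi, plus an additive
#' substrate-dependent induction effect for the protein's enzyme class,
#' plus replicate noise; a measurement below the detection threshold is
#' censored to "not detected" (left-censoring, the typical LFQ
#' missingness mechanism). Enzyme classes receive no induction on the
#' designated free-sugar substrate, emulating catabolite-repressed CAZyme
#' expression on glucose. Class pairs whose (nonzero) induction patterns
#' are identical are the planted co-induced pairs recorded in the truth.
#'
#' @param nFungi,nSubstrates,nReplicates,nProteins study dimensions
#'   (defaults 5 fungi x 5 substrates x 3 replicates, 200 proteins).
#' @param substrates substrate labels; \code{freeSugar} must be among
#'   them.
#' @param freeSugar the no-induction substrate (default "glucose").
#' @param classCatalog named integer vector, proteins per enzyme class.
#' @param inductionEffects classes x substrates numeric matrix of additive
#'   log2 effects; defaults to the planted-pair design above with effect
#'   size \code{effect}. The free-sugar column is forced to zero.
#' @param effect default induction effect size in log2 units (16-fold).
#' @param baseMu,baseSigma baseline log2 location/scale (raw LFQ-like).
#' @param noiseSigma replicate noise sd (log2).
#' @param detectionThreshold log2 censoring threshold.
#' @param multiAnnotationRate fraction of class proteins given a second
#'   CAZy family (multi-domain proteins).
#' @param predictorErrorRate per-predictor call flip probability.
#' @param secretionRateClass,secretionRateOther true-secretion probability
#'   for class / background proteins.
#' @param seed RNG seed; one stream drives the whole study.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nFungi = 5L, nSubstrates = 5L,
                            nReplicates = 3L, nProteins = 200L,
                            substrates = NULL, freeSugar = "glucose",
                            classCatalog = defaultClassCatalog(),
                            inductionEffects = NULL, effect = 4,
                            baseMu = 25, baseSigma = 2, noiseSigma = 0.5,
                            detectionThreshold = 23,
                            multiAnnotationRate = 0.1,
                            predictorErrorRate = 0.05,
                            secretionRateClass = 0.9,
                            secretionRateOther = 0.3, seed = 1L) {
  if (is.null(substrates)) {
    base <- c("bagasse", "birch", "spruce", "cellulose", "glucose")
    substrates <- if (nSubstrates <= 5) base[seq_len(nSubstrates)]
                  else c(base, paste0("substrate_",
                                      seq_len(nSubstrates - 5)))
    if (!freeSugar %in% substrates) substrates[nSubstrates] <- freeSugar
  }
  classCatalog <- structure(as.integer(classCatalog),
                            names = names(classCatalog))
  if (is.null(inductionEffects))
    inductionEffects <- defaultInduction(names(classCatalog), substrates,
                                         freeSugar, effect)
  inductionEffects <- inductionEffects[names(classCatalog), substrates,
                                       drop = FALSE]
  inductionEffects[, freeSugar] <- 0
  new("SyntheticConfig", nFungi = as.integer(nFungi),
      nSubstrates = as.integer(nSubstrates),
      nReplicates = as.integer(nReplicates),
      nProteins = as.integer(nProteins),
      fungi = paste0("fungus_", seq_len(nFungi)),
      substrates = substrates, freeSugar = freeSugar,
      classCatalog = classCatalog, inductionEffects = inductionEffects,
      baseMu = baseMu, baseSigma = baseSigma, noiseSigma = noiseSigma,
      detectionThreshold = detectionThreshold,
      multiAnnotationRate = multiAnnotationRate,
      predictorErrorRate = predictorErrorRate,
      secretionRateClass = secretionRateClass,
      secretionRateOther = secretionRateOther, seed = as.integer(seed))
}

plantedPairsOf <- function(induction) {
  cls <- rownames(induction)
  out <- NULL
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (j <= i) next
    if (any(induction[i, ] != 0) &&
        identical(unname(induction[i, ]), unname(induction[j, ])))
      out <- rbind(out, sort(c(cls[i], cls[j])))
  }
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("class1", "class2")
  out
}

#' Generate a synthetic secretome study
#'
#' Draws abundances, annotations and ground truth from one RNG stream
#' seeded by \code{config@seed}; the same config therefore yields
#' byte-identical fixtures. See [syntheticConfig()] for the model.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with elements \code{abundance} (linear-scale
#'   \linkS4class{SecretomeExperiment}, NA = censored), \code{annotations}
#'   (\linkS4class{AnnotationSet}), \code{classMap} (data.frame family,
#'   class as emitted for this study) and \code{truth}
#'   (\linkS4class{TruthRecord}).
#' @export
generateStudy <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@nProteins
    ids <- sprintf("P%04d", seq_len(n))
    catalog <- config@classCatalog
    classOf <- rep("", n)
    classOf[seq_len(sum(catalog))] <- rep(names(catalog), catalog)
    names(classOf) <- ids

    famPool <- defaultFamilyPool()
    famOf <- if (length(catalog) <= length(famPool))
      famPool[seq_along(catalog)] else
      c(famPool, paste0("GH", 100 + seq_len(length(catalog) -
                                              length(famPool))))
    names(famOf) <- names(catalog)
    classMap <- data.frame(family = unname(famOf), class = names(catalog),
                           stringsAsFactors = FALSE)

    # --- abundances -----------------------------------------------------
    base <- rnorm(n, config@baseMu, config@baseSigma)
    design <- expand.grid(replicate = seq_len(config@nReplicates),
                          substrate = config@substrates,
                          fungus = config@fungi,
                          stringsAsFactors = FALSE)[, 3:1]
    nSamp <- nrow(design)
    induct <- config@inductionEffects
    effectOf <- matrix(0, n, nSamp)
    isClass <- classOf != ""
    effectOf[isClass, ] <- induct[classOf[isClass], design$substrate]
    log2val <- base + effectOf +
      matrix(rnorm(n * nSamp, 0, config@noiseSigma), n, nSamp)
    missing <- log2val < config@detectionThreshold
    lin <- 2^log2val
    lin[missing] <- NA
    rownames(lin) <- ids
    se <- SecretomeExperiment(lin, fungus = design$fungus,
                              substrate = design$substrate,
                              replicate = design$replicate,
                              scale = "linear")

    # --- annotations ----------------------------------------------------
    cazy <- lapply(seq_len(n), function(i)
      if (isClass[i]) unname(famOf[classOf[i]]) else character())
    extra <- isClass & runif(n) < config@multiAnnotationRate
    for (i in which(extra)) {
      others <- setdiff(names(catalog), classOf[i])
      if (length(others))
        cazy[[i]] <- c(cazy[[i]],
                       unname(famOf[others[sample.int(length(others), 1)]]))
    }
    peptidase <- rep(list(character()), n)
    meropsPool <- c("S8", "S9", "A1", "M28", "M35", "G1")
    bgDraw <- runif(n)
    for (i in which(!isClass & bgDraw < 0.15))
      peptidase[[i]] <- meropsPool[sample.int(length(meropsPool), 1)]
    for (i in which(!isClass & bgDraw >= 0.15 & bgDraw < 0.20))
      cazy[[i]] <- "CBM1"
    description <- ifelse(isClass, gsub("_", " ", classOf),
                   ifelse(lengths(peptidase) > 0, "peptidase",
                   ifelse(lengths(cazy) > 0, "carbohydrate-binding protein",
                          "uncharacterized protein")))

    trueSecreted <- runif(n) < ifelse(isClass, config@secretionRateClass,
                                      config@secretionRateOther)
    names(trueSecreted) <- ids
    flip <- matrix(runif(3 * n) < config@predictorErrorRate, n, 3)
    calls <- xor(matrix(trueSecreted, n, 3), flip)

    ann <- AnnotationSet(ids, cazy = cazy, peptidase = peptidase,
                         signalp = calls[, 1], phobius = calls[, 2],
                         wolfpsort = calls[, 3], description = description)

    truth <- new("TruthRecord", plantedPairs = plantedPairsOf(induct),
                 classOf = classOf, secreted = trueSecreted,
                 detectionThreshold = config@detectionThreshold)
    list(abundance = se, annotations = ann, classMap = classMap,
         truth = truth)
  })
}

#' @describeIn generateStudy planted co-induced class pairs.
#' @param x a TruthRecord.
#' @export
setMethod("plantedPairs", "TruthRecord", function(x) x@plantedPairs)

#' @describeIn generateStudy named true class label per protein ("" =
#'   background).
#' @export
setMethod("trueClassOf", "TruthRecord", function(x) x@classOf)

#' @describeIn generateStudy named true secretion flag per protein.
#' @export
setMethod("isSecreted", "TruthRecord", function(x) x@secreted)

setMethod("show", "TruthRecord", function(object) {
  cat("TruthRecord:", length(object@classOf), "proteins,",
      nrow(object@plantedPairs), "planted class pair(s)\n")
})

#' Write a synthetic study as the pipeline's TSV/JSON fixture set
#'
#' Emits the input files the readers consume: \code{abundance.tsv},
#' \code{cazy_families.tsv}, \code{peptidase_families.tsv},
#' \code{signalp.tsv}, \code{phobius.tsv}, \code{wolfpsort.tsv},
#' \code{descriptions.tsv}, \code{class_map.tsv} and \code{truth.json}.
#' Output is deterministic, so the same config yields byte-identical
#' files; read-back via [readStudy()] round-trips losslessly.
#'
#' @param bundle the list returned by [generateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written paths.
#' @export
writeFixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeAbundance(bundle$abundance, p("abundance.tsv"))
  ann <- bundle$annotations
  ids <- proteinIds(ann)
  famTab <- function(cl) {
    lst <- as.list(cl)
    data.frame(protein_id = rep(ids, lengths(lst)),
               family = unlist(lst, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  wt <- function(df, f) write.table(df, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  wt(famTab(cazyFamilies(ann)), "cazy_families.tsv")
  wt(famTab(peptidaseFamilies(ann)), "peptidase_families.tsv")
  calls <- predictorCalls(ann)
  for (nm in colnames(calls))
    wt(data.frame(protein_id = ids, secreted = calls[, nm]),
       paste0(nm, ".tsv"))
  wt(data.frame(protein_id = ids, description = ann@description),
     "descriptions.tsv")
  wt(bundle$classMap, "class_map.tsv")
  truth <- bundle$truth
  jsonlite::write_json(
    list(planted_pairs = as.data.frame(truth@plantedPairs),
         class_of = as.list(truth@classOf),
         secreted = as.list(truth@secreted),
         detection_threshold = truth@detectionThreshold),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(abundance = p("abundance.tsv"), truth = p("truth.json")))
}

#' Read a fixture directory back into a study bundle
#'
#' @param dir directory written by [writeFixtures()] (or assembled by the
#'   user in the same layout).
#' @return list with \code{abundance}, \code{annotations},
#'   \code{classMap}, and \code{truth} (NULL when no truth.json present).
#' @export
readStudy <- function(dir) {
  p <- function(f) file.path(dir, f)
  se <- readAbundance(p("abundance.tsv"))
  ann <- readAnnotations(p("cazy_families.tsv"),
                         p("peptidase_families.tsv"), p("signalp.tsv"),
                         p("phobius.tsv"), p("wolfpsort.tsv"),
                         descriptionPath = p("descriptions.tsv"),
                         proteins = rownames(se))
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    pp <- as.matrix(tj$planted_pairs)
    if (!length(pp)) pp <- matrix(character(0), 0, 2)
    dimnames(pp) <- list(NULL, c("class1", "class2"))
    truth <- new("TruthRecord", plantedPairs = pp,
                 classOf = unlist(tj$class_of),
                 secreted = unlist(tj$secreted),
                 detectionThreshold = tj$detection_threshold)
  }
  list(abundance = se, annotations = ann,
       classMap = readEnzymeClassMap(p("class_map.tsv")), truth = truth)
}
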
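## Central S4 classes. Constructors live in the module files; accessors in
## AllGenerics.R / the module files.

#' SecretomeExperiment: proteins x samples LFQ container
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"abundance"}
#' holds LFQ intensities (linear or log2 scale, see
#' \code{metadata(x)$scale}) with \code{NA} marking "not detected".
#' \code{colData} carries the study design axes: \code{fungus},
#' \code{substrate} and \code{replicate} (the sample key
#' \code{fungus|substrate|replicate} is the column name). Replicate is
#' \code{NA} for replicate-averaged tables.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [SecretomeExperiment()] the constructor.
#' @export
setClass("SecretomeExperiment", contains = "SummarizedExperiment")

setValidity("SecretomeExperiment", function(object) {
  msg <- NULL
  if (!("abundance" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'abundance' is required")
  cd <- colData(object)
  need <- c("fungus", "substrate", "replicate")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain fungus, substrate, replicate")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate protein ids")
  if (all(need %in% colnames(cd))) {
    key <- paste(cd$fungus, cd$substrate, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (fungus, substrate, replicate) sample keys")
  }
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("linear", "log2"))
    msg <- c(msg, "metadata(x)$scale must be 'linear' or 'log2'")
  if (is.null(msg)) TRUE else msg
})

#' AnnotationSet: per-protein functional annotation
#'
#' Holds, per protein: CAZy family assignments (dbCAN-style, possibly
#' several per protein, subfamilies written \code{"AA3_2"}), MEROPS peptidase
#' families, the three boolean secretion-predictor calls (SignalP-, Phobius-
#' and WoLF-PSORT-style), a free-text description, plus two derived columns:
#' the two-of-three secretion consensus and the single accounting category
#' (see [assignCategory()]).
#'
#' @slot protein character, unique protein ids.
#' @slot cazy CharacterList of CAZy family labels per protein.
#' @slot peptidase CharacterList of MEROPS family labels per protein.
#' @slot calls logical matrix, columns signalp / phobius / wolfpsort;
#'   \code{NA} means the predictor produced no call (treated as FALSE).
#' @slot description character free text (may be empty).
#' @slot secreted logical, derived consensus.
#' @slot category character, derived accounting category.
#' @export
setClass("AnnotationSet",
  representation(protein = "character",
                 cazy = "CharacterList",
                 peptidase = "CharacterList",
                 calls = "matrix",
                 description = "character",
                 secreted = "logical",
                 category = "character"))

setValidity("AnnotationSet", function(object) {
  n <- length(object@protein)
  msg <- NULL
  if (anyDuplicated(object@protein))
    msg <- c(msg, "duplicate protein ids")
  if (length(object@cazy) != n || length(object@peptidase) != n ||
      nrow(object@calls) != n || length(object@description) != n ||
      length(object@secreted) != n || length(object@category) != n)
    msg <- c(msg, "slot lengths differ")
  if (!identical(colnames(object@calls),
                 c("signalp", "phobius", "wolfpsort")))
    msg <- c(msg, "calls must have columns signalp, phobius, wolfpsort")
  ok <- c("GH", "CE", "PL", "AA", "LPMO", "CBM-only", "peptidase",
          "uncharacterized", "other")
  if (!all(object@category %in% ok))
    msg <- c(msg, "invalid category value")
  if (is.null(msg)) TRUE else msg
})

#' FilterDecision: outcome of the replicate detection filter
#'
#' Per protein and fungus, whether the protein passed the
#' two-of-three-replicates rule on at least one carbon source
#' (\code{keep}), and on which (fungus, substrate) pairs it counts as
#' present (one detected replicate suffices once kept: the single-replicate
#' carry-over rule).
#'
#' @slot proteins,fungi,substrates character label vectors.
#' @slot keep logical matrix proteins x fungi.
#' @slot presentOn logical array proteins x fungi x substrates.
#' @slot minReplicates integer threshold used (default 2).
#' @export
setClass("FilterDecision",
  representation(proteins = "character", fungi = "character",
                 substrates = "character", keep = "matrix",
                 presentOn = "array", minReplicates = "integer"))

setValidity("FilterDecision", function(object) {
  d <- dim(object@presentOn)
  msg <- NULL
  if (!identical(dim(object@keep),
                 c(length(object@proteins), length(object@fungi))))
    msg <- c(msg, "keep has wrong dimensions")
  if (!identical(d, c(length(object@proteins), length(object@fungi),
                      length(object@substrates))))
    msg <- c(msg, "presentOn has wrong dimensions")
  # present anywhere implies kept for that fungus
  if (is.null(msg)) {
    anyPresent <- apply(object@presentOn, c(1, 2), any)
    if (any(anyPresent & !object@keep))
      msg <- c(msg, "presentOn set for a protein/fungus that is not kept")
  }
  if (is.null(msg)) TRUE else msg
})

#' ProteinNetwork: per-fungus protein co-expression adjacency
#'
#' Symmetric weighted graph over one fungus's proteins; edge weight
#' \eqn{e_{vu} = |PCC(v, u)|^\beta \in [0, 1]}, diagonal 1.
#'
#' @slot nodes character protein ids.
#' @slot weights numeric symmetric matrix in [0, 1], unit diagonal.
#' @slot fungus character(1) label.
#' @slot beta numeric soft-threshold power used.
#' @export
setClass("ProteinNetwork",
  representation(nodes = "character", weights = "matrix",
                 fungus = "character", beta = "numeric"))

setValidity("ProteinNetwork", function(object) {
  w <- object@weights
  msg <- NULL
  if (!identical(dim(w), c(length(object@nodes), length(object@nodes))))
    msg <- c(msg, "weight matrix dimensions do not match nodes")
  else {
    if (length(w) && max(abs(w - t(w))) > 1e-10)
      msg <- c(msg, "weight matrix is not symmetric")
    if (length(w) && (min(w) < -1e-10 || max(w) > 1 + 1e-10))
      msg <- c(msg, "weights outside [0, 1]")
    if (length(w) && max(abs(diag(w) - 1)) > 1e-10)
      msg <- c(msg, "diagonal must be 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' ClassNetwork: enzyme-class co-expression network
#'
#' Nodes are enzyme classes with size |S_i| (number of member proteins);
#' the symmetric interaction matrix \code{C} holds the normalized
#' class-class interaction coefficients (diagonal = intra-class
#' coefficient), with \code{NA} marking undefined entries (empty class, or
#' singleton intra-class). Integer weights, per-edge p-values and node
#' strengths are filled in by the downstream steps and are empty until then.
#'
#' @slot classes character class labels.
#' @slot sizes numeric |S_i| per class.
#' @slot C numeric symmetric matrix, NA = undefined.
#' @slot intWeights numeric matrix of discretized weights (0-100), or 0-dim.
#' @slot pvalues numeric matrix of MLF upper-tail p-values, or 0-dim.
#' @slot strengths numeric per-class strength, or length 0.
#' @export
setClass("ClassNetwork",
  representation(classes = "character", sizes = "numeric", C = "matrix",
                 intWeights = "matrix", pvalues = "matrix",
                 strengths = "numeric"))

setValidity("ClassNetwork", function(object) {
  n <- length(object@classes)
  msg <- NULL
  if (!identical(dim(object@C), c(n, n)))
    msg <- c(msg, "C has wrong dimensions")
  else {
    d <- object@C
    if (any(!is.na(d) & (d < -1e-9 | d > 1 + 1e-9)))
      msg <- c(msg, "defined C entries must lie in [0, 1]")
    if (max(abs(ifelse(is.na(d), 0, d) - ifelse(is.na(t(d)), 0, t(d)))) > 1e-10 ||
        !identical(is.na(d), is.na(t(d))))
      msg <- c(msg, "C must be symmetric (including NA pattern)")
  }
  if (length(object@sizes) != n)
    msg <- c(msg, "sizes length mismatch")
  if (length(object@strengths) && length(object@strengths) != n)
    msg <- c(msg, "strengths length mismatch")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticConfig: parameters of the synthetic secretome study
#'
#' Describes a synthetic multi-fungus LFQ study: log2-normal baseline
#' abundances, additive substrate-dependent induction of co-regulated
#' enzyme classes, replicate noise, left-censoring at a detection
#' threshold, multi-domain (two-family) proteins and noisy secretion
#' predictors. See [syntheticConfig()].
#'
#' @slot nFungi,nSubstrates,nReplicates,nProteins integer counts.
#' @slot fungi,substrates character labels; \code{freeSugar} names the
#'   substrate on which enzyme classes receive no induction.
#' @slot classCatalog named integer: proteins per enzyme class.
#' @slot inductionEffects numeric matrix classes x substrates, additive
#'   log2 effect.
#' @slot baseMu,baseSigma numeric log2 baseline location / scale.
#' @slot noiseSigma numeric replicate noise sd (log2).
#' @slot detectionThreshold numeric log2 abundance below which a
#'   measurement is censored to "not detected".
#' @slot multiAnnotationRate numeric fraction of class proteins given a
#'   second CAZy family.
#' @slot predictorErrorRate numeric per-predictor flip probability.
#' @slot secretionRateClass,secretionRateOther numeric probability that a
#'   class / background protein is truly secreted.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(nFungi = "integer", nSubstrates = "integer",
                 nReplicates = "integer", nProteins = "integer",
                 fungi = "character", substrates = "character",
                 freeSugar = "character", classCatalog = "integer",
                 inductionEffects = "matrix", baseMu = "numeric",
                 baseSigma = "numeric", noiseSigma = "numeric",
                 detectionThreshold = "numeric",
                 multiAnnotationRate = "numeric",
                 predictorErrorRate = "numeric",
                 secretionRateClass = "numeric",
                 secretionRateOther = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  cnt <- c(object@nFungi, object@nSubstrates, object@nReplicates,
           object@nProteins)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (any(object@classCatalog < 1L))
    msg <- c(msg, "class protein counts must be >= 1")
  if (sum(object@classCatalog) > object@nProteins)
    msg <- c(msg, "class protein counts sum to more than nProteins")
  p <- c(object@multiAnnotationRate, object@predictorErrorRate,
         object@secretionRateClass, object@secretionRateOther)
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@baseSigma <= 0 || object@noiseSigma < 0)
    msg <- c(msg, "baseSigma must be > 0 and noiseSigma >= 0")
  if (!object@freeSugar %in% object@substrates)
    msg <- c(msg, "freeSugar must be one of the substrates")
  if (!identical(sort(rownames(object@inductionEffects)),
                 sort(names(object@classCatalog))) ||
      !identical(sort(colnames(object@inductionEffects)),
                 sort(object@substrates)))
    msg <- c(msg, "inductionEffects must be indexed by classes x substrates")
  if (length(object@fungi) != object@nFungi ||
      length(object@substrates) != object@nSubstrates)
    msg <- c(msg, "label vectors must match the counts")
  if (is.null(msg)) TRUE else msg
})

#' TruthRecord: ground truth of a synthetic study
#'
#' @slot plantedPairs character matrix, two columns, one row per planted
#'   co-induced class pair.
#' @slot classOf named character: true enzyme class per protein (`""` for
#'   background proteins).
#' @slot secreted named logical: true secretion status per protein.
#' @slot detectionThreshold numeric, the censoring threshold used.
#' @export
setClass("TruthRecord",
  representation(plantedPairs = "matrix", classOf = "character",
                 secreted = "logical", detectionThreshold = "numeric"))

setValidity("TruthRecord", function(object) {
  if (length(object@plantedPairs) && ncol(object@plantedPairs) != 2L)
    return("plantedPairs must have two columns")
  TRUE
})
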
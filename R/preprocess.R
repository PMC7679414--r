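## Detection filtering, log2 + Tukey-biweight normalization, replicate QC,
## replicate averaging.

#' Tukey's biweight location estimate
#'
#' Robust average used to put all samples (raw files) on the same scale:
#' iterated re-weighting started at the median, with scale fixed at the
#' (unscaled) median absolute deviation and bisquare weights
#' \eqn{(1 - u^2)^2} for \eqn{|u| < 1}, \eqn{u = (x - t) / (c \cdot MAD)}.
#' With \code{oneStep = TRUE} the classical one-step estimator (a single
#' re-weighting from the median) is returned. A zero MAD (at least half the
#' values tied) falls back to the median.
#'
#' @param x numeric values; NAs are dropped.
#' @param c positive tuning constant (default 5).
#' @param epsilon convergence tolerance on the location update.
#' @param maxIter iteration cap.
#' @param oneStep logical; stop after the first re-weighted mean.
#' @return scalar location estimate.
#' @examples
#' tukeyBiweight(c(1, 2, 3, 100), oneStep = TRUE)  # 2.0545: outlier zeroed
#' tukeyBiweight(rep(7, 4))                        # 7
#' @export
tukeyBiweight <- function(x, c = 5, epsilon = 1e-6, maxIter = 50L,
                          oneStep = FALSE) {
  stopifnot(c > 0, epsilon > 0)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  t0 <- median(x)
  s <- median(abs(x - t0))
  if (s == 0) return(t0)
  for (i in seq_len(maxIter)) {
    u <- (x - t0) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    t1 <- sum(w * x) / sum(w)
    if (oneStep) return(t1)
    if (abs(t1 - t0) < epsilon) return(t1)
    t0 <- t1
  }
  t0
}

#' Normalize samples by log2 transform and biweight subtraction
#'
#' Puts all raw files on the same scale: each sample's detected
#' intensities are log2-transformed and the sample's Tukey-biweight
#' location (a robust average abundance) is subtracted. Missing entries
#' stay missing. A table already on log2 scale is centered without
#' re-transforming, so normalization is idempotent up to the convergence
#' tolerance.
#'
#' @param x a \linkS4class{SecretomeExperiment}.
#' @param c,epsilon,maxIter,oneStep passed to [tukeyBiweight()].
#' @return a log2-scale, normalized \linkS4class{SecretomeExperiment};
#'   per-sample offsets are kept in \code{metadata(x)$biweightOffsets}.
#' @export
normalizeAbundance <- function(x, c = 5, epsilon = 1e-6, maxIter = 50L,
                               oneStep = FALSE) {
  m <- abundances(x)
  if (metadata(x)$scale == "linear") {
    if (any(!is.na(m) & m <= 0))
      stop("nonpositive detected intensity on linear scale")
    m <- log2(m)
  }
  offsets <- apply(m, 2, function(col)
    tukeyBiweight(col[!is.na(col)], c = c, epsilon = epsilon,
                  maxIter = maxIter, oneStep = oneStep))
  m <- sweep(m, 2, offsets, "-")
  out <- SecretomeExperiment(m, fungus = sampleFungus(x),
                             substrate = sampleSubstrate(x),
                             replicate = sampleReplicate(x),
                             scale = "log2", normalized = TRUE)
  metadata(out)$biweightOffsets <- offsets
  out
}

#' Replicate-based detection filter
#'
#' A protein is kept for a fungus when it was detected in at least
#' \code{minReplicates} (default two of three) biological replicates on at
#' least one carbon source. A kept protein then counts as present on every
#' substrate with at least one detected replicate — the single-replicate
#' carry-over convention used in per-substrate detection tables.
#'
#' @param x a \linkS4class{SecretomeExperiment} with replicate-level
#'   columns.
#' @param minReplicates detection threshold per substrate (default 2);
#'   applies unchanged when fewer replicates are available.
#' @return a \linkS4class{FilterDecision}.
#' @export
detectionFilter <- function(x, minReplicates = 2L) {
  det <- isDetected(x)
  fungi <- unique(sampleFungus(x))
  substrates <- unique(sampleSubstrate(x))
  np <- nrow(det)
  keep <- matrix(FALSE, np, length(fungi),
                 dimnames = list(rownames(det), fungi))
  pres <- array(FALSE, c(np, length(fungi), length(substrates)),
                dimnames = list(rownames(det), fungi, substrates))
  nDet <- array(0L, c(np, length(fungi), length(substrates)))
  for (fi in seq_along(fungi)) for (si in seq_along(substrates)) {
    cols <- sampleFungus(x) == fungi[fi] &
      sampleSubstrate(x) == substrates[si]
    if (!any(cols)) next
    nDet[, fi, si] <- rowSums(det[, cols, drop = FALSE])
  }
  for (fi in seq_along(fungi)) {
    keep[, fi] <- apply(nDet[, fi, , drop = FALSE] >= minReplicates, 1, any)
    for (si in seq_along(substrates))
      pres[, fi, si] <- keep[, fi] & nDet[, fi, si] >= 1L
  }
  new("FilterDecision", proteins = rownames(det), fungi = fungi,
      substrates = substrates, keep = keep, presentOn = pres,
      minReplicates = as.integer(minReplicates))
}

#' @describeIn detectionFilter protein ids kept for a fungus (or, with
#'   \code{fungus = NULL}, kept for at least one fungus).
#' @param fungus optional fungus label.
#' @export
setMethod("keptProteins", "FilterDecision", function(x, fungus = NULL) {
  if (is.null(fungus)) return(x@proteins[rowSums(x@keep) > 0])
  x@proteins[x@keep[, fungus]]
})

#' @describeIn detectionFilter protein ids present on a (fungus, substrate)
#'   pair under the carry-over rule.
#' @param substrate substrate label.
#' @export
setMethod("presentOn", "FilterDecision", function(x, fungus, substrate) {
  x@proteins[x@presentOn[, fungus, substrate]]
})

setMethod("show", "FilterDecision", function(object) {
  cat("FilterDecision:", length(object@proteins), "proteins,",
      length(object@fungi), "fungi,", length(object@substrates),
      "substrates (min replicates:", object@minReplicates, ")\n")
  for (f in object@fungi)
    cat("  ", f, ": ", sum(object@keep[, f]), " kept\n", sep = "")
})

#' Apply a FilterDecision to an abundance table
#'
#' Rows kept by no fungus are dropped; for the remaining proteins, values
#' measured in a fungus for which the protein failed the filter are masked
#' as missing.
#'
#' @param x a \linkS4class{SecretomeExperiment}.
#' @param decision the matching \linkS4class{FilterDecision}.
#' @return the filtered \linkS4class{SecretomeExperiment}.
#' @export
applyFilter <- function(x, decision) {
  stopifnot(identical(rownames(x), decision@proteins))
  m <- abundances(x)
  for (f in decision@fungi) {
    cols <- sampleFungus(x) == f
    m[!decision@keep[, f], cols] <- NA
  }
  keepAny <- rowSums(decision@keep) > 0
  out <- SecretomeExperiment(m[keepAny, , drop = FALSE],
                             fungus = sampleFungus(x),
                             substrate = sampleSubstrate(x),
                             replicate = sampleReplicate(x),
                             scale = metadata(x)$scale,
                             normalized = isTRUE(metadata(x)$normalized))
  out
}

#' Pairwise Pearson correlation between replicates
#'
#' Repeatability QC: for every fungus and substrate, the Pearson
#' correlation between each pair of replicate samples over
#' pairwise-complete (both detected) proteins. Pairs with fewer than three
#' common proteins are reported as \code{NA}.
#'
#' @param x a normalized \linkS4class{SecretomeExperiment}.
#' @return data.frame with columns fungus, substrate, rep1, rep2, n, r.
#' @export
replicateCorrelation <- function(x) {
  m <- abundances(x)
  out <- list()
  for (f in unique(sampleFungus(x))) for (s in unique(sampleSubstrate(x))) {
    cols <- which(sampleFungus(x) == f & sampleSubstrate(x) == s)
    reps <- sampleReplicate(x)[cols]
    if (length(cols) < 2) next
    for (i in seq_along(cols)[-length(cols)])
      for (j in seq((i + 1), length(cols))) {
        a <- m[, cols[i]]; b <- m[, cols[j]]
        ok <- !is.na(a) & !is.na(b)
        r <- if (sum(ok) < 3) NA_real_ else cor(a[ok], b[ok])
        out[[length(out) + 1L]] <-
          data.frame(fungus = f, substrate = s, rep1 = reps[i],
                     rep2 = reps[j], n = sum(ok), r = r)
      }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @describeIn replicateCorrelation per-fungus range of replicate
#'   correlations.
#' @param corrs the data.frame returned by \code{replicateCorrelation}.
#' @export
replicateCorrelationRange <- function(corrs) {
  do.call(rbind, lapply(split(corrs, corrs$fungus), function(d) {
    r <- d$r[!is.na(d$r)]
    data.frame(fungus = d$fungus[1],
               min_r = if (length(r)) min(r) else NA_real_,
               max_r = if (length(r)) max(r) else NA_real_,
               row.names = NULL)
  }))
}

#' Average abundance over detected replicates
#'
#' Collapses replicate columns to one column per (fungus, substrate),
#' taking the mean over the detected replicates only; a protein detected in
#' no replicate stays missing (no imputation, so averages are not dragged
#' toward a detection floor).
#'
#' @param x a \linkS4class{SecretomeExperiment} with replicate columns.
#' @return a \linkS4class{SecretomeExperiment} with one column per
#'   fungus/substrate and \code{replicate = NA}.
#' @export
averageReplicates <- function(x) {
  m <- abundances(x)
  groups <- unique(data.frame(fungus = sampleFungus(x),
                              substrate = sampleSubstrate(x),
                              stringsAsFactors = FALSE))
  avg <- vapply(seq_len(nrow(groups)), function(g) {
    cols <- sampleFungus(x) == groups$fungus[g] &
      sampleSubstrate(x) == groups$substrate[g]
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  avg[is.nan(avg)] <- NA
  rownames(avg) <- rownames(m)
  SecretomeExperiment(avg, fungus = groups$fungus,
                      substrate = groups$substrate,
                      replicate = NA_integer_,
                      scale = metadata(x)$scale,
                      normalized = isTRUE(metadata(x)$normalized))
}
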
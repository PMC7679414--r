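#' Construct a SecretomeExperiment
#'
#' @param abundance numeric matrix, proteins x samples; \code{NA} (or, on
#'   linear scale, values read as 0 upstream) marks "not detected".
#' @param fungus,substrate,replicate per-sample design vectors, recycled
#'   checks apply; \code{replicate} may be \code{NA} for averaged tables.
#' @param scale \code{"linear"} (raw LFQ intensities) or \code{"log2"}.
#' @param normalized logical, whether sample-wise biweight centering has
#'   been applied.
#' @return a \linkS4class{SecretomeExperiment}.
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(c("P1", "P2"), NULL))
#' se <- SecretomeExperiment(m, fungus = "fA", substrate = c("birch", "spruce"),
#'                           replicate = c(1L, 1L))
#' se
#' @export
SecretomeExperiment <- function(abundance, fungus, substrate, replicate,
                                scale = c("linear", "log2"),
                                normalized = FALSE) {
  scale <- match.arg(scale)
  abundance <- as.matrix(abundance)
  n <- ncol(abundance)
  fungus <- rep_len(as.character(fungus), n)
  substrate <- rep_len(as.character(substrate), n)
  replicate <- rep_len(as.integer(replicate), n)
  cd <- DataFrame(fungus = fungus, substrate = substrate,
                  replicate = replicate)
  colnames(abundance) <- makeSampleKey(fungus, substrate,
                                       ifelse(is.na(replicate), "avg",
                                              replicate))
  rownames(cd) <- colnames(abundance)
  se <- SummarizedExperiment(assays = list(abundance = abundance),
                             colData = cd,
                             metadata = list(scale = scale,
                                             normalized = normalized))
  new("SecretomeExperiment", se)
}

#' @describeIn SecretomeExperiment the abundance matrix (NA = not detected).
#' @param x a SecretomeExperiment.
#' @export
setMethod("abundances", "SecretomeExperiment",
          function(x, ...) assay(x, "abundance"))

#' @describeIn SecretomeExperiment logical matrix of detection.
#' @export
setMethod("isDetected", "SecretomeExperiment",
          function(x, ...) !is.na(assay(x, "abundance")))

#' @describeIn SecretomeExperiment protein identifiers (rownames).
#' @export
setMethod("proteinIds", "SecretomeExperiment", function(x, ...) rownames(x))

#' @describeIn SecretomeExperiment per-sample fungus labels.
#' @export
setMethod("sampleFungus", "SecretomeExperiment",
          function(x) colData(x)$fungus)

#' @describeIn SecretomeExperiment per-sample substrate labels.
#' @export
setMethod("sampleSubstrate", "SecretomeExperiment",
          function(x) colData(x)$substrate)

#' @describeIn SecretomeExperiment per-sample replicate index (NA once
#'   averaged).
#' @export
setMethod("sampleReplicate", "SecretomeExperiment",
          function(x) colData(x)$replicate)

setMethod("show", "SecretomeExperiment", function(object) {
  cat("SecretomeExperiment:", nrow(object), "proteins x", ncol(object),
      "samples\n")
  cat("  fungi:     ", paste(unique(sampleFungus(object)), collapse = ", "),
      "\n")
  cat("  substrates:", paste(unique(sampleSubstrate(object)),
                             collapse = ", "), "\n")
  cat("  scale:", metadata(object)$scale,
      if (isTRUE(metadata(object)$normalized)) "(normalized)" else "", "\n")
  cat("  missing:", sum(!isDetected(object)), "of",
      length(assay(object)), "entries\n")
})
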
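## Heat-map ordering (UPGMA on Euclidean distances) and per-protein
## substrate profiles.

#' Hierarchical ordering of proteins for heat maps
#'
#' UPGMA (average linkage) clustering on Euclidean distances between
#' protein rows. Missing entries are filled with a stated constant for the
#' distance computation only (default -10, the same "absent" sentinel the
#' network module uses).
#'
#' @param x numeric matrix (e.g. replicate-averaged abundances) or a
#'   \linkS4class{SecretomeExperiment}.
#' @param missingFill value substituted for missing entries before
#'   computing distances.
#' @return an \code{hclust} object (merge tree, heights, leaf order).
#' @export
hierarchicalOrder <- function(x, missingFill = -10) {
  m <- if (is(x, "SecretomeExperiment")) abundances(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  m[is.na(m)] <- missingFill
  hclust(dist(m, method = "euclidean"), method = "average")
}

#' Substrate expression profile of one protein
#'
#' The replicate-averaged, normalized log2 abundance of a protein across
#' the carbon sources, in a fixed substrate order — the quantity drawn in
#' radar/heat displays of individual enzymes. Missing means "not detected
#' on that substrate". The conventional display range [-4, 8] is attached
#' as the \code{"range"} attribute; values are not clamped.
#'
#' @param x a replicate-averaged \linkS4class{SecretomeExperiment}.
#' @param protein protein id (must be present in \code{x}).
#' @param fungus fungus label; may be omitted when \code{x} has one fungus.
#' @param substrates substrate display order; defaults to the order of
#'   appearance in \code{x}.
#' @return named numeric vector over substrates (NA = not detected).
#' @export
substrateProfile <- function(x, protein, fungus = NULL, substrates = NULL) {
  if (!protein %in% rownames(x)) stop("unknown protein: ", protein)
  if (is.null(fungus)) {
    fungus <- unique(sampleFungus(x))
    if (length(fungus) > 1) stop("specify fungus; table has several")
  }
  if (is.null(substrates)) substrates <- unique(sampleSubstrate(x))
  v <- vapply(substrates, function(s) {
    col <- which(sampleFungus(x) == fungus & sampleSubstrate(x) == s)
    if (!length(col)) return(NA_real_)
    abundances(x)[protein, col[1]]
  }, 0)
  names(v) <- substrates
  attr(v, "range") <- c(-4, 8)
  v
}

#' Heat-map matrix ordered by a dendrogram
#'
#' Rows permuted into dendrogram leaf order; missing entries keep the
#' \code{NA} sentinel (rendered grey); the conventional color-scale bounds
#' [-5, 10] for normalized log2 LFQ are recorded as metadata.
#'
#' @param x numeric matrix or replicate-averaged
#'   \linkS4class{SecretomeExperiment}.
#' @param dendrogram an \code{hclust} over the rows of \code{x}, or
#'   \code{NULL} for the identity order.
#' @return list with elements \code{matrix} (ordered, NA = missing),
#'   \code{rowLabels}, and \code{colorRange}.
#' @export
heatmapMatrix <- function(x, dendrogram = NULL) {
  m <- if (is(x, "SecretomeExperiment")) abundances(x) else as.matrix(x)
  ord <- if (is.null(dendrogram)) seq_len(nrow(m)) else dendrogram$order
  stopifnot(length(ord) == nrow(m))
  list(matrix = m[ord, , drop = FALSE], rowLabels = rownames(m)[ord],
       colorRange = c(-5, 10))
}

#' Write an ordered heat-map matrix as TSV
#'
#' @param hm list returned by [heatmapMatrix()].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeHeatmapTSV <- function(hm, path) {
  df <- data.frame(protein_id = hm$rowLabels, hm$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
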
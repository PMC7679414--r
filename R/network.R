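## Enzyme-class co-expression network: protein adjacency -> class collapse
## -> cross-fungus average -> strength -> percent discretization ->
## marginal-likelihood edge filter -> export.

#' Substitute missing values with the "absent" sentinel
#'
#' Before computing co-expression adjacencies, missing (not detected)
#' entries are substituted with -10, below the lowest observed normalized
#' LFQ value, so absence itself carries signal.
#'
#' @param x numeric matrix or \linkS4class{SecretomeExperiment}.
#' @param value sentinel (default -10).
#' @return numeric matrix with no missing entries.
#' @export
imputeMissing <- function(x, value = -10) {
  m <- if (is(x, "SecretomeExperiment")) abundances(x) else as.matrix(x)
  m[is.na(m)] <- value
  m
}

#' Protein-level co-expression adjacency
#'
#' Builds one fungus's protein network: nodes are proteins, the edge
#' weight between two proteins is \eqn{|PCC|^\beta} of their expression
#' profiles over the replicate-level samples (after missing-value
#' substitution), with \eqn{\beta = 1} by default so the weight is
#' literally the absolute Pearson correlation. A zero-variance (e.g.
#' all-substituted) profile has undefined correlation; its edge weights
#' are set to 0 — a constant profile carries no co-expression signal.
#' The diagonal is 1.
#'
#' @param x numeric matrix proteins x samples with no missing values
#'   (see [imputeMissing()]), or a \linkS4class{SecretomeExperiment} for a
#'   single fungus (imputed internally).
#' @param beta soft-threshold power (>= 0).
#' @param fungus label stored on the network.
#' @return a \linkS4class{ProteinNetwork}.
#' @export
proteinAdjacency <- function(x, beta = 1, fungus = NA_character_) {
  m <- imputeMissing(x)
  if (ncol(m) < 3) stop("need at least 3 samples")
  e <- abs(suppressWarnings(cor(t(m))))^beta
  e[is.na(e)] <- 0
  diag(e) <- 1
  e <- (e + t(e)) / 2
  e[e > 1] <- 1
  new("ProteinNetwork", nodes = rownames(m), weights = e,
      fungus = as.character(fungus), beta = beta)
}

#' @describeIn proteinAdjacency the symmetric edge-weight matrix.
#' @export
setMethod("edgeWeights", "ProteinNetwork", function(x) {
  w <- x@weights
  dimnames(w) <- list(x@nodes, x@nodes)
  w
})

setMethod("show", "ProteinNetwork", function(object) {
  cat("ProteinNetwork (", object@fungus, "): ", length(object@nodes),
      " proteins, beta = ", object@beta, "\n", sep = "")
})

#' Collapse a protein network onto enzyme-class sets
#'
#' The class-class interaction coefficient is the collective edge strength
#' between the two (possibly overlapping) member sets, normalized by the
#' maximal possible strength:
#' \deqn{C_{S_i S_j} = \frac{\sum_{v \in S_i} \sum_{u \in S_j} e_{vu}}
#'   {|S_i| \cdot |S_j|}}
#' For the intra-class case (i = j) both numerator and denominator are
#' reduced by \eqn{|S_i|}, removing the self-correlations (the unit
#' diagonal); a singleton class therefore has an undefined intra-class
#' coefficient. Proteins with multiple annotations belong to multiple
#' sets. Class sets are intersected with the network's nodes; empty
#' classes give undefined (NA) rows.
#'
#' @param net a \linkS4class{ProteinNetwork}.
#' @param classSets named list: class -> protein ids (see
#'   [classMembers()]).
#' @return a \linkS4class{ClassNetwork}.
#' @export
collapseClasses <- function(net, classSets) {
  classes <- names(classSets)
  e <- edgeWeights(net)
  sets <- lapply(classSets, function(s) intersect(s, net@nodes))
  n <- lengths(sets)
  k <- length(classes)
  M <- matrix(0, k, nrow(e))
  for (i in seq_len(k)) M[i, match(sets[[i]], net@nodes)] <- 1
  S <- M %*% e %*% t(M)
  C <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (n[i] == 0 || n[j] == 0) next
    if (i == j) {
      if (n[i] > 1) C[i, j] <- (S[i, i] - n[i]) / (n[i]^2 - n[i])
    } else C[i, j] <- S[i, j] / (n[i] * n[j])
  }
  C[!is.na(C) & C > 1] <- pmin(1, C[!is.na(C) & C > 1])  # guard fp noise
  new(Class = "ClassNetwork", classes = classes, sizes = as.numeric(n), C = C,
      intWeights = matrix(numeric(0), 0, 0),
      pvalues = matrix(numeric(0), 0, 0), strengths = numeric(0))
}

#' @describeIn collapseClasses the interaction-coefficient matrix
#'   (NA = undefined).
#' @param x a ClassNetwork.
#' @export
setMethod("interactionMatrix", "ClassNetwork", function(x) x@C)

#' @describeIn collapseClasses per-class member counts |S_i|.
#' @export
setMethod("classSizes", "ClassNetwork",
          function(x) structure(x@sizes, names = x@classes))

#' @describeIn collapseClasses discretized integer-weight matrix (empty
#'   until [discretizeWeights()]).
#' @export
setMethod("integerWeights", "ClassNetwork", function(x) x@intWeights)

#' @describeIn collapseClasses MLF p-value matrix (empty until
#'   [mlfEdgePvalues()]).
#' @export
setMethod("edgePvalues", "ClassNetwork", function(x) x@pvalues)

setMethod("show", "ClassNetwork", function(object) {
  k <- length(object@classes)
  off <- object@C[upper.tri(object@C)]
  cat("ClassNetwork:", k, "classes;", sum(!is.na(off)),
      "defined class pairs\n")
  if (length(object@strengths)) {
    top <- order(object@strengths, decreasing = TRUE)[seq_len(min(3, k))]
    cat("  top strength:",
        paste(sprintf("%s (%.2f)", object@classes[top],
                      object@strengths[top]), collapse = ", "), "\n")
  }
})

#' Average class networks across fungi
#'
#' Collapses per-fungus class networks into one consensus network: each
#' entry is the mean over the networks in which it is defined; entries
#' undefined everywhere stay undefined. Node sizes are summed (total
#' member proteins across fungi).
#'
#' @param nets list of \linkS4class{ClassNetwork} objects on a shared
#'   class vocabulary.
#' @return a \linkS4class{ClassNetwork}.
#' @export
averageClassNetworks <- function(nets) {
  if (!length(nets)) stop("empty network list")
  classes <- nets[[1]]@classes
  for (nt in nets) stopifnot(identical(nt@classes, classes))
  k <- length(classes)
  total <- matrix(0, k, k)
  cnt <- matrix(0L, k, k)
  sizes <- numeric(k)
  for (nt in nets) {
    d <- !is.na(nt@C)
    total[d] <- total[d] + nt@C[d]
    cnt <- cnt + d
    sizes <- sizes + nt@sizes
  }
  C <- ifelse(cnt > 0, total / cnt, NA_real_)
  dimnames(C) <- list(classes, classes)
  new(Class = "ClassNetwork", classes = classes, sizes = sizes, C = C,
      intWeights = matrix(numeric(0), 0, 0),
      pvalues = matrix(numeric(0), 0, 0), strengths = numeric(0))
}

#' @describeIn collapseClasses node strength: the sum of the defined
#'   weighted edges incident to a class, with the intra-class self-loop
#'   counted once; used to rank hub classes. Computed from the full
#'   (pre-filter) interaction matrix.
#' @export
setMethod("nodeStrength", "ClassNetwork", function(x, ...) {
  s <- rowSums(x@C, na.rm = TRUE)
  names(s) <- x@classes
  s
})

#' Discretize interaction coefficients to integer weights 0-100
#'
#' Maps each defined coefficient (in [0, 1]) onto the integer percent
#' scale via half-up rounding; integer weight 0 means "no edge" for the
#' downstream significance filter. Also records node strengths from the
#' continuous pre-discretization matrix.
#'
#' @param net a \linkS4class{ClassNetwork} (typically cross-fungus
#'   averaged).
#' @return the network with \code{integerWeights} and \code{strengths}
#'   filled in.
#' @export
discretizeWeights <- function(net) {
  if (any(!is.na(net@C) & (net@C < 0 | net@C > 1)))
    stop("weights outside [0, 1]")
  w <- roundHalfUp(100 * net@C)
  new(Class = "ClassNetwork", classes = net@classes, sizes = net@sizes, C = net@C,
      intWeights = w, pvalues = net@pvalues,
      strengths = unname(nodeStrength(net)))
}

#' Marginal-likelihood filter edge p-values
#'
#' Backbone-extraction null model for integer-weighted graphs: with total
#' weight \eqn{T} (sum over distinct-pair edges) and integer strengths
#' \eqn{k_i}, each of the \eqn{T} unit edges attaches to the pair (i, j)
#' with probability \eqn{p_{ij} = k_i k_j / (2 T^2)}, so the observed
#' weight is Binomial(T, p_ij) under the null and the edge p-value is the
#' upper tail \eqn{P(W \ge w_{ij})}. Intra-class self-loops are excluded
#' from the null (and never filtered); a defined edge of weight 0 has
#' p-value 1.
#'
#' @param net a \linkS4class{ClassNetwork} with integer weights (see
#'   [discretizeWeights()]).
#' @return the network with the p-value matrix filled in (NA on the
#'   diagonal and on undefined entries).
#' @export
mlfEdgePvalues <- function(net) {
  w <- net@intWeights
  if (!length(w)) stop("run discretizeWeights() first")
  sig <- edgeSignificance(w)
  k <- length(net@classes)
  P <- matrix(NA_real_, k, k, dimnames = dimnames(w))
  off <- !is.na(w) & row(w) != col(w)
  P[off] <- 1
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      i <- sig$i[r]; j <- sig$j[r]
      P[i, j] <- P[j, i] <- sig$pvalue[r]
    }
  }
  new(Class = "ClassNetwork", classes = net@classes, sizes = net@sizes, C = net@C,
      intWeights = w, pvalues = P, strengths = net@strengths)
}

#' @describeIn mlfEdgePvalues the per-edge significance table for an
#'   integer weight matrix: integer strengths, total weight, null edge
#'   probability and binomial upper-tail p-value for every positive-weight
#'   distinct-pair edge.
#' @param w symmetric integer weight matrix (NA allowed; diagonal
#'   ignored).
#' @return data.frame with columns i, j (indices), class_i, class_j, w,
#'   k_i, k_j, T, p_null, pvalue.
#' @export
edgeSignificance <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  w0 <- w
  w0[is.na(w0)] <- 0
  diag(w0) <- 0
  k <- rowSums(w0)
  Tw <- sum(w0[upper.tri(w0)])
  idx <- which(upper.tri(w0) & w0 > 0, arr.ind = TRUE)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(w)))
  if (Tw == 0 || !nrow(idx))
    return(data.frame(i = integer(), j = integer(), class_i = character(),
                      class_j = character(), w = numeric(), k_i = numeric(),
                      k_j = numeric(), T = numeric(), p_null = numeric(),
                      pvalue = numeric()))
  i <- idx[, 1]; j <- idx[, 2]
  pNull <- pmin(1, k[i] * k[j] / (2 * Tw^2))
  pv <- pbinom(w0[idx] - 1, Tw, pNull, lower.tail = FALSE)
  data.frame(i = i, j = j, class_i = labs[i], class_j = labs[j],
             w = w0[idx], k_i = k[i], k_j = k[j], T = Tw, p_null = pNull,
             pvalue = pv, row.names = NULL)
}

#' Keep only significant edges
#'
#' Retains distinct-pair edges with MLF p-value below \code{alpha};
#' non-significant edges are removed (their C and integer weight become
#' undefined). Nodes are kept even if isolated, self-loops are exempt,
#' and node strengths are reported from the pre-filter network, matching
#' the convention that strength is a property of the full network while
#' filtering only prunes displayed edges.
#'
#' @param net a \linkS4class{ClassNetwork} with p-values (see
#'   [mlfEdgePvalues()]).
#' @param alpha significance level (default 0.05; edges kept when
#'   p < alpha).
#' @return the filtered \linkS4class{ClassNetwork}.
#' @export
filterNetwork <- function(net, alpha = 0.05) {
  if (!length(net@pvalues)) stop("run mlfEdgePvalues() first")
  drop <- row(net@C) != col(net@C) &
    (is.na(net@pvalues) | net@pvalues >= alpha)
  C <- net@C; C[drop] <- NA
  w <- net@intWeights; w[drop] <- NA
  strengths <- if (length(net@strengths)) net@strengths
               else unname(nodeStrength(net))
  new(Class = "ClassNetwork", classes = net@classes, sizes = net@sizes, C = C,
      intWeights = w, pvalues = net@pvalues, strengths = strengths)
}

classNetworkTables <- function(net) {
  strengths <- if (length(net@strengths)) net@strengths
               else unname(nodeStrength(net))
  nodes <- data.frame(class = net@classes, size = net@sizes,
                      strength = strengths,
                      C_self = diag(net@C), stringsAsFactors = FALSE)
  idx <- which(upper.tri(net@C) & !is.na(net@C), arr.ind = TRUE)
  hasW <- length(net@intWeights) > 0
  hasP <- length(net@pvalues) > 0
  edges <- data.frame(
    source = net@classes[idx[, 1]], target = net@classes[idx[, 2]],
    C = net@C[idx],
    w_int = if (hasW) net@intWeights[idx] else rep(NA_real_, nrow(idx)),
    pvalue = if (hasP) net@pvalues[idx] else rep(NA_real_, nrow(idx)),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Export a class network
#'
#' Writes either GraphML (via igraph, ready for Cytoscape import) or a SIF
#' file plus node/edge attribute TSVs. Node attributes: class size |S_i|,
#' strength, intra-class coefficient; edge attributes: C, integer weight,
#' MLF p-value.
#'
#' @param net a \linkS4class{ClassNetwork}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param format "sif", "graphml" or "both".
#' @return invisibly, the written file paths.
#' @export
exportNetwork <- function(net, dir, prefix = "class_network",
                          format = c("sif", "graphml", "both")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- classNetworkTables(net)
  paths <- character()
  if (format %in% c("sif", "both")) {
    sif <- file.path(dir, paste0(prefix, ".sif"))
    lines <- if (nrow(tabs$edges))
      paste(tabs$edges$source, "co_expr", tabs$edges$target) else character()
    iso <- setdiff(net@classes, c(tabs$edges$source, tabs$edges$target))
    writeLines(c(lines, iso), sif)
    nodeP <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    edgeP <- file.path(dir, paste0(prefix, "_edges.tsv"))
    fmtNum <- function(df) {
      for (col in names(df))
        if (is.numeric(df[[col]]))
          df[[col]] <- ifelse(is.na(df[[col]]), "NA",
                              sprintf("%.17g", df[[col]]))
      df
    }
    write.table(fmtNum(tabs$nodes), nodeP, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fmtNum(tabs$edges), edgeP, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, sif, nodeP, edgeP)
  }
  if (format %in% c("graphml", "both")) {
    g <- igraph::graph_from_data_frame(
      tabs$edges, directed = FALSE,
      vertices = tabs$nodes[, c("class", "size", "strength", "C_self")])
    gp <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(g, gp, format = "graphml")
    paths <- c(paths, gp)
  }
  invisible(paths)
}

#' Re-import a class network written by [exportNetwork()]
#'
#' Reads the node/edge attribute TSVs back into a
#' \linkS4class{ClassNetwork} (SIF format).
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used at export.
#' @return a \linkS4class{ClassNetwork}.
#' @export
importClassNetwork <- function(dir, prefix = "class_network") {
  nodes <- read.delim(file.path(dir, paste0(prefix, "_nodes.tsv")),
                      stringsAsFactors = FALSE)
  edges <- read.delim(file.path(dir, paste0(prefix, "_edges.tsv")),
                      stringsAsFactors = FALSE)
  k <- nrow(nodes)
  classes <- as.character(nodes$class)
  C <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  w <- P <- C
  diag(C) <- as.numeric(nodes$C_self)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- match(edges$source[r], classes); j <- match(edges$target[r], classes)
    C[i, j] <- C[j, i] <- edges$C[r]
    w[i, j] <- w[j, i] <- edges$w_int[r]
    P[i, j] <- P[j, i] <- edges$pvalue[r]
  }
  new(Class = "ClassNetwork", classes = classes, sizes = as.numeric(nodes$size),
      C = C,
      intWeights = if (all(is.na(w))) matrix(numeric(0), 0, 0) else w,
      pvalues = if (all(is.na(P))) matrix(numeric(0), 0, 0) else P,
      strengths = as.numeric(nodes$strength))
}

#' Per-fungus class networks from a filtered, normalized table
#'
#' Convenience wrapper running, for each fungus: -10 substitution on the
#' replicate-level columns of that fungus's kept proteins, protein
#' adjacency, and the class collapse over the given class sets.
#'
#' @param x normalized replicate-level \linkS4class{SecretomeExperiment}.
#' @param decision a \linkS4class{FilterDecision} (defines kept proteins
#'   per fungus).
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param classMap family-to-class map data.frame.
#' @param beta adjacency power.
#' @return named list of per-fungus \linkS4class{ClassNetwork} objects.
#' @export
perFungusClassNetworks <- function(x, decision, annotations,
                                   classMap = defaultEnzymeClassMap(),
                                   beta = 1) {
  fungi <- decision@fungi
  nets <- list()
  classes <- unique(classMap$class)
  for (f in fungi) {
    kept <- intersect(keptProteins(decision, f), rownames(x))
    cols <- sampleFungus(x) == f
    sets <- classMembers(annotations, classMap, proteins = kept)
    if (length(kept) < 2) {
      k <- length(classes)
      nets[[f]] <- new(Class = "ClassNetwork", classes = classes,
                       sizes = as.numeric(lengths(sets)),
                       C = matrix(NA_real_, k, k,
                                  dimnames = list(classes, classes)),
                       intWeights = matrix(numeric(0), 0, 0),
                       pvalues = matrix(numeric(0), 0, 0),
                       strengths = numeric(0))
      next
    }
    m <- imputeMissing(abundances(x)[kept, cols, drop = FALSE])
    pn <- proteinAdjacency(m, beta = beta, fungus = f)
    nets[[f]] <- collapseClasses(pn, sets)
  }
  nets
}
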
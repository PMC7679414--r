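## Independent oracles used across the test files. These re-derive expected
## values by brute force or closed form and never call the package code
## paths they check.

## Naive O(n^3) UPGMA on a row matrix: average linkage over the original
## pairwise Euclidean distances; ties merge the lowest-index pair.
naiveUPGMA <- function(m) {
  d0 <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in seq((i + 1), length(clusters))) {
        dij <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dij < best[1] - 1e-12) best <- c(dij, i, j)
      }
    heights <- c(heights, best[1])
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  heights
}

## Brute-force double-sum evaluation of the class-interaction coefficient.
bruteCollapse <- function(e, sets) {
  classes <- names(sets)
  k <- length(classes)
  C <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    Si <- sets[[i]]; Sj <- sets[[j]]
    if (!length(Si) || !length(Sj)) next
    tot <- 0
    for (v in Si) for (u in Sj) tot <- tot + e[v, u]
    if (i == j) {
      if (length(Si) > 1)
        C[i, j] <- (tot - length(Si)) / (length(Si)^2 - length(Si))
    } else C[i, j] <- tot / (length(Si) * length(Sj))
  }
  C
}

## Exact binomial upper tail by direct summation (no pbinom).
binomTailOracle <- function(w, T, p) {
  if (w <= 0) return(1)
  sum(vapply(w:T, function(t) choose(T, t) * p^t * (1 - p)^(T - t), 0))
}

## Adjusted Rand index between two label vectors.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## Rank-based ROC AUC of scores for positives vs negatives.
rocAUC <- function(pos, neg)
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))

## Random weighted protein network + overlapping class sets, for the
## collapse oracle property.
randomCollapseInstance <- function(maxProteins = 10, maxClasses = 4) {
  np <- sample(2:maxProteins, 1)
  ids <- paste0("p", seq_len(np))
  e <- matrix(runif(np * np), np, np)
  e <- (e + t(e)) / 2
  diag(e) <- 1
  dimnames(e) <- list(ids, ids)
  nc <- sample(1:maxClasses, 1)
  sets <- lapply(seq_len(nc), function(i)
    sample(ids, sample(0:np, 1)))
  names(sets) <- paste0("cl", seq_len(nc))
  list(e = e, sets = sets, ids = ids)
}

## One full synthetic recovery run; returns AUC of C for planted pairs and
## whether all planted pairs pass the MLF at alpha.
recoveryRun <- function(seed, alpha = 0.05) {
  b <- generateStudy(syntheticConfig(seed = seed))
  d <- detectionFilter(b$abundance)
  n <- normalizeAbundance(applyFilter(b$abundance, d))
  nets <- perFungusClassNetworks(n, d, b$annotations, b$classMap)
  g <- mlfEdgePvalues(discretizeWeights(averageClassNetworks(nets)))
  C <- interactionMatrix(g)
  P <- edgePvalues(g)
  pp <- plantedPairs(b$truth)
  pl <- apply(pp, 1, function(p) paste(sort(p), collapse = "|"))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  lab <- apply(ut, 1, function(ij)
    paste(sort(rownames(C)[ij]), collapse = "|"))
  vals <- C[upper.tri(C)]
  isP <- lab %in% pl
  c(auc = rocAUC(vals[isP], vals[!isP][!is.na(vals[!isP])]),
    survived = all(P[upper.tri(P)][isP] < alpha),
    meanPlanted = mean(vals[isP]),
    meanBackground = mean(vals[!isP], na.rm = TRUE))
}

## All weak compositions of total n into k nonnegative parts.
compositionsOf <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (first in 0:n)
    out <- rbind(out, cbind(first, compositionsOf(n - first, k - 1)))
  unname(out)
}
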
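## helper: ClassNetwork straight from a coefficient matrix
cnFromC <- function(C, sizes = rep(2, nrow(C))) {
  classes <- rownames(C)
  new(Class = "ClassNetwork", classes = classes, sizes = sizes, C = C,
      intWeights = matrix(numeric(0), 0, 0),
      pvalues = matrix(numeric(0), 0, 0), strengths = numeric(0))
}

symC <- function(k, fill, labels = LETTERS[seq_len(k)]) {
  C <- matrix(fill, k, k, dimnames = list(labels, labels))
  C
}

test_that("missing-value substitution touches only missing entries", {
  m <- rbind(a = c(NA, NA), b = c(1, NA), c = c(1, 2))
  out <- imputeMissing(m)
  expect_equal(unname(out), rbind(c(-10, -10), c(1, -10), c(1, 2)))
  expect_identical(imputeMissing(rbind(a = c(1, 2))), rbind(a = c(1, 2)))
})

test_that("protein adjacency is |PCC|^beta with unit diagonal", {
  withr::with_seed(61, {
    m <- matrix(rnorm(6 * 10), 6, dimnames = list(paste0("p", 1:6), NULL))
    for (beta in c(1, 6)) {
      net <- proteinAdjacency(m, beta = beta)
      oracle <- abs(cor(t(m)))^beta
      diag(oracle) <- 1
      expect_equal(edgeWeights(net), oracle, tolerance = 1e-12)
    }
    # duplicate and sign-flipped profiles both give weight 1
    dup <- rbind(u = m[1, ], v = m[1, ], w = 2 * mean(m[1, ]) - m[1, ])
    e <- edgeWeights(proteinAdjacency(dup))
    expect_equal(e["u", "v"], 1)
    expect_equal(e["u", "w"], 1)
    # zero-variance profile: undefined correlation -> weight 0
    flat <- rbind(a = rep(-10, 10), b = m[1, ])
    expect_equal(edgeWeights(proteinAdjacency(flat))["a", "b"], 0)
    expect_error(proteinAdjacency(m[, 1:2]), "at least 3")
  })
})

test_that("class collapse matches hand-evaluated double sums", {
  e <- symC(3, 1, c("a", "b", "c"))
  e["a", "c"] <- e["c", "a"] <- 0.5
  e["b", "c"] <- e["c", "b"] <- 0.7
  e["a", "b"] <- e["b", "a"] <- 0.8
  net <- new(Class = "ProteinNetwork", nodes = c("a", "b", "c"),
             weights = e, fungus = "f", beta = 1)
  cn <- collapseClasses(net, list(Si = c("a", "b"), Sj = "c"))
  C <- interactionMatrix(cn)
  expect_equal(C["Si", "Sj"], (0.5 + 0.7) / 2)        # 0.6
  expect_equal(C["Si", "Si"], (1 + 0.8 + 0.8 + 1 - 2) / (4 - 2))  # 0.8
  expect_true(is.na(C["Sj", "Sj"]))                   # singleton intra
  # singleton-singleton identity
  cn2 <- collapseClasses(net, list(A = "a", B = "b"))
  expect_equal(interactionMatrix(cn2)["A", "B"], 0.8)
})

test_that("class collapse equals the brute-force oracle with overlap", {
  withr::with_seed(67, {
    for (rep in 1:60) {
      inst <- randomCollapseInstance()
      net <- new(Class = "ProteinNetwork", nodes = inst$ids,
                 weights = inst$e, fungus = "f", beta = 1)
      got <- interactionMatrix(collapseClasses(net, inst$sets))
      ref <- bruteCollapse(inst$e, lapply(inst$sets, sort))
      expect_equal(got, ref, tolerance = 1e-12)
      defined <- got[!is.na(got)]
      expect_true(all(defined >= 0 & defined <= 1))
    }
  })
})

test_that("cross-fungus averaging omits undefined entries", {
  C1 <- symC(2, NA_real_); C1["A", "B"] <- C1["B", "A"] <- 0.2
  C1["A", "A"] <- 0.4
  C2 <- symC(2, NA_real_); C2["A", "B"] <- C2["B", "A"] <- 0.6
  n1 <- cnFromC(C1); n2 <- cnFromC(C2)
  avg <- averageClassNetworks(list(n1, n2))
  M <- interactionMatrix(avg)
  expect_equal(M["A", "B"], 0.4)        # mean of defined entries
  expect_equal(M["A", "A"], 0.4)        # defined once -> kept as is
  expect_true(is.na(M["B", "B"]))       # defined nowhere
  expect_equal(classSizes(avg)[["A"]], 4)  # sizes summed
  # averaging a single network, or k copies, is the identity
  expect_equal(interactionMatrix(averageClassNetworks(list(n1))), C1)
  expect_equal(interactionMatrix(averageClassNetworks(list(n1, n1, n1))),
               C1)
})

test_that("node strength sums defined incident edges, self-loop once", {
  C <- symC(3, NA_real_)
  C[upper.tri(C)] <- 0.5
  C[lower.tri(C)] <- 0.5
  net <- cnFromC(C)
  expect_equal(nodeStrength(net), c(A = 1, B = 1, C = 1))
  # isolated class
  Ciso <- symC(2, NA_real_)
  expect_equal(nodeStrength(cnFromC(Ciso)), c(A = 0, B = 0))
  withr::with_seed(71, {
    M <- matrix(runif(36), 6, 6); M <- (M + t(M)) / 2
    M[sample(36, 6)] <- NA
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    dimnames(M) <- list(letters[1:6], letters[1:6])
    s <- nodeStrength(cnFromC(M, sizes = rep(2, 6)))
    for (i in 1:6)
      expect_equal(unname(s[i]), sum(M[i, ], na.rm = TRUE))
  })
})

test_that("discretization maps [0,1] to percent integers, half up", {
  C <- symC(3, NA_real_)
  C["A", "B"] <- C["B", "A"] <- 0.006
  C["A", "C"] <- C["C", "A"] <- 0.0049
  C["B", "C"] <- C["C", "B"] <- 1.0
  net <- discretizeWeights(cnFromC(C))
  w <- integerWeights(net)
  expect_equal(w["A", "B"], 1)
  expect_equal(w["A", "C"], 0)
  expect_equal(w["B", "C"], 100)
  expect_equal(w["A", "B"], 1)
  # 0.125 -> 13 under half-up (round() would give 12)
  C2 <- symC(2, NA_real_); C2["A", "B"] <- C2["B", "A"] <- 0.125
  expect_equal(integerWeights(discretizeWeights(cnFromC(C2)))["A", "B"],
               13)
  # zero-weight edges are dropped from the edge list
  sig <- edgeSignificance(w)
  expect_false(any(sig$class_i == "A" & sig$class_j == "C"))
})

test_that("MLF p-values match the exact binomial-tail oracle", {
  # triangle AB=5, AC=3, BC=2: T=10, k=(8,7,5), p_AB=0.28
  w <- symC(3, 0)
  w["A", "B"] <- w["B", "A"] <- 5
  w["A", "C"] <- w["C", "A"] <- 3
  w["B", "C"] <- w["C", "B"] <- 2
  sig <- edgeSignificance(w)
  ab <- sig[sig$class_i == "A" & sig$class_j == "B", ]
  expect_equal(ab$T, 10)
  expect_equal(ab$k_i, 8); expect_equal(ab$k_j, 7)
  expect_equal(ab$p_null, 0.28)
  expect_equal(ab$pvalue, binomTailOracle(5, 10, 0.28), tolerance = 1e-12)
  expect_lt(abs(ab$pvalue - 0.118), 5e-4)
  # degenerate single edge: p_null = 1/2, upper tail = 0.5^w
  for (wq in c(1, 3, 6)) {
    w1 <- symC(2, 0); w1["A", "B"] <- w1["B", "A"] <- wq
    s1 <- edgeSignificance(w1)
    expect_equal(s1$p_null, 0.5)
    expect_equal(s1$pvalue, 0.5^wq, tolerance = 1e-12)
  }
  # weight-zero edges carry p-value 1 in the matrix form
  wz <- symC(2, 0)
  net <- mlfEdgePvalues(discretizeWeights(cnFromC(symC(2, 0))))
  expect_equal(edgePvalues(net)["A", "B"], 1)
})

test_that("the null tail is non-increasing in the observed weight", {
  for (p in c(0.1, 0.28, 0.5)) for (T in c(5, 12)) {
    tails <- vapply(0:T, binomTailOracle, 0, T = T, p = p)
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("edge filtering keeps p < alpha and pre-filter strengths", {
  C <- symC(3, NA_real_)
  C["A", "B"] <- C["B", "A"] <- 0.9
  C["A", "C"] <- C["C", "A"] <- 0.1
  C["B", "C"] <- C["C", "B"] <- 0.1
  net <- mlfEdgePvalues(discretizeWeights(cnFromC(C)))
  preStrength <- nodeStrength(net)
  all_ <- filterNetwork(net, alpha = 1)
  expect_equal(interactionMatrix(all_), C)
  none <- filterNetwork(net, alpha = 0)
  expect_true(all(is.na(interactionMatrix(none)[upper.tri(C)])))
  expect_identical(none@classes, c("A", "B", "C"))  # isolated nodes kept
  some <- filterNetwork(net, alpha = 0.05)
  expect_equal(structure(some@strengths, names = some@classes),
               preStrength)
})

test_that("networks export, re-import and snapshot faithfully", {
  C <- symC(3, NA_real_)
  C["A", "B"] <- C["B", "A"] <- 0.5
  C["A", "A"] <- 0.25
  net <- mlfEdgePvalues(discretizeWeights(cnFromC(C, sizes = c(3, 1, 2))))
  dir <- tempfile()
  exportNetwork(net, dir, format = "both")
  back <- importClassNetwork(dir)
  expect_equal(interactionMatrix(back), interactionMatrix(net))
  expect_equal(classSizes(back), classSizes(net))
  expect_equal(back@strengths,
               if (length(net@strengths)) net@strengths
               else unname(nodeStrength(net)))
  expect_equal(edgePvalues(back)["A", "B"], edgePvalues(net)["A", "B"])
  # SIF snapshot: one co_expr line plus the isolated node
  expect_identical(readLines(file.path(dir, "class_network.sif")),
                   c("A co_expr B", "C"))
  g <- igraph::read_graph(file.path(dir, "class_network.graphml"),
                          format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  # empty network still yields a valid, edge-free file set
  emptyNet <- cnFromC(symC(2, NA_real_))
  dir2 <- tempfile()
  exportNetwork(emptyNet, dir2, format = "sif")
  expect_identical(readLines(file.path(dir2, "class_network.sif")),
                   c("A", "B"))
  expect_equal(nrow(importClassNetwork(dir2)@C), 2)
  unlink(c(dir, dir2), recursive = TRUE)
})
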
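## Small builder: one fungus, named substrates, 3 replicates, one protein
## per detection pattern.
patternSE <- function(patterns, substrates = c("bagasse", "birch"),
                      nReps = 3) {
  np <- length(patterns)
  design <- expand.grid(replicate = seq_len(nReps), substrate = substrates,
                        stringsAsFactors = FALSE)
  m <- matrix(NA_real_, np, nrow(design))
  for (p in seq_len(np)) {
    for (hit in patterns[[p]]) {
      s <- hit[[1]]; r <- hit[[2]]
      m[p, which(design$substrate == s & design$replicate == r)] <- 100
    }
  }
  rownames(m) <- paste0("P", seq_len(np))
  SecretomeExperiment(m, fungus = "fA", substrate = design$substrate,
                      replicate = design$replicate)
}

test_that("detection filter keeps two-of-three proteins with carry-over", {
  se <- patternSE(list(
    # two replicates on bagasse, one on birch: kept, present on both
    list(list("bagasse", 1), list("bagasse", 2), list("birch", 2)),
    # single replicates on two substrates: dropped entirely
    list(list("bagasse", 1), list("birch", 2)),
    # never detected: dropped
    list()))
  fd <- detectionFilter(se)
  expect_identical(keptProteins(fd), "P1")
  expect_identical(presentOn(fd, "fA", "bagasse"), "P1")
  expect_identical(presentOn(fd, "fA", "birch"), "P1")
  filtered <- applyFilter(se, fd)
  expect_identical(rownames(filtered), "P1")
})

test_that("the filter rule matches an exhaustive enumeration of patterns", {
  # all 64 detection patterns over 2 substrates x 3 replicates
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  patterns <- lapply(seq_len(nrow(grid)), function(i) {
    det <- unlist(grid[i, ])
    hits <- list()
    for (k in which(det)) {
      s <- if (k <= 3) "bagasse" else "birch"
      hits[[length(hits) + 1L]] <- list(s, ((k - 1) %% 3) + 1)
    }
    hits
  })
  se <- patternSE(patterns)
  fd <- detectionFilter(se)
  for (i in seq_len(nrow(grid))) {
    det <- unlist(grid[i, ])
    nBag <- sum(det[1:3]); nBirch <- sum(det[4:6])
    keepRef <- nBag >= 2 || nBirch >= 2
    id <- paste0("P", i)
    expect_identical(id %in% keptProteins(fd), keepRef, label = id)
    expect_identical(id %in% presentOn(fd, "fA", "bagasse"),
                     keepRef && nBag >= 1, label = id)
    expect_identical(id %in% presentOn(fd, "fA", "birch"),
                     keepRef && nBirch >= 1, label = id)
  }
})

test_that("adding a detection never removes keep or presence", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      det <- runif(6) < 0.4
      off <- which(!det)
      if (!length(off)) next
      det2 <- det
      det2[sample(off, 1)] <- TRUE
      toPat <- function(d) {
        hits <- list()
        for (k in which(d))
          hits[[length(hits) + 1L]] <-
            list(if (k <= 3) "bagasse" else "birch", ((k - 1) %% 3) + 1)
        hits
      }
      f1 <- detectionFilter(patternSE(list(toPat(det))))
      f2 <- detectionFilter(patternSE(list(toPat(det2))))
      expect_true(!"P1" %in% keptProteins(f1) || "P1" %in% keptProteins(f2))
      for (s in c("bagasse", "birch"))
        expect_true(!"P1" %in% presentOn(f1, "fA", s) ||
                      "P1" %in% presentOn(f2, "fA", s))
    }
  })
})

test_that("Tukey biweight handles constants, symmetry and outliers", {
  expect_equal(tukeyBiweight(rep(7, 4)), 7)
  expect_equal(tukeyBiweight(c(-3, 0, 3)), 0)
  # hand evaluation: median 2.5, MAD 1, u = (x - 2.5)/5, outlier weight 0
  w <- c((1 - 0.3^2)^2, (1 - 0.1^2)^2, (1 - 0.1^2)^2, 0)
  byHand <- sum(w * c(1, 2, 3, 100)) / sum(w)
  expect_equal(tukeyBiweight(c(1, 2, 3, 100), c = 5, oneStep = TRUE),
               byHand, tolerance = 1e-12)
  expect_equal(byHand, 2.0545, tolerance = 2e-4)
  expect_error(tukeyBiweight(numeric(0)), "no finite values")
})

test_that("biweight stays inside the data range and matches the mean
           when nothing is downweighted", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- rnorm(15)
      t <- tukeyBiweight(x)
      expect_gte(t, min(x)); expect_lte(t, max(x))
      # huge c: all weights ~1 -> arithmetic mean
      expect_equal(tukeyBiweight(x, c = 1e6), mean(x), tolerance = 1e-6)
    }
  })
})

test_that("normalization centers each sample at biweight zero", {
  withr::with_seed(19, {
    m <- matrix(2^rnorm(300, 20, 3), 100, 3,
                dimnames = list(sprintf("P%03d", 1:100), NULL))
    m[sample(300, 40)] <- NA
    se <- SecretomeExperiment(m, fungus = "fA", substrate = "birch",
                              replicate = 1:3)
    nm <- normalizeAbundance(se)
    expect_identical(metadata(nm)$scale, "log2")
    for (j in 1:3) {
      v <- abundances(nm)[, j]
      expect_lt(abs(tukeyBiweight(v[!is.na(v)])), 1e-6)
    }
    # constant sample: log2 values all 8 -> all zero
    se8 <- SecretomeExperiment(matrix(2^8, 5, 1), "fA", "birch", 1L)
    expect_equal(unname(abundances(normalizeAbundance(se8))[, 1]),
                 rep(0, 5))
    expect_error(normalizeAbundance(
      SecretomeExperiment(matrix(c(-1, 2), 2, 1), "fA", "birch", 1L)),
      "nonpositive")
  })
})

test_that("normalization is shift-equivariant and idempotent", {
  withr::with_seed(23, {
    x <- 2^rnorm(50, 20, 2)
    m <- cbind(x, 3.7 * x)
    rownames(m) <- paste0("P", 1:50)
    se <- SecretomeExperiment(m, "fA", "birch", 1:2)
    nm <- abundances(normalizeAbundance(se))
    # samples differing by a constant factor normalize identically
    expect_equal(nm[, 1], nm[, 2], tolerance = 1e-9)
    # second pass subtracts ~0
    n1 <- normalizeAbundance(se)
    n2 <- normalizeAbundance(n1)
    expect_equal(abundances(n1), abundances(n2), tolerance = 1e-6)
  })
})

test_that("replicate correlations match the direct formula", {
  withr::with_seed(29, {
    m <- matrix(rnorm(300), 100, 3, dimnames = list(paste0("P", 1:100),
                                                    NULL))
    m[sample(300, 30)] <- NA
    se <- SecretomeExperiment(m, "fA", "birch", 1:3, scale = "log2")
    rc <- replicateCorrelation(se)
    expect_equal(nrow(rc), 3L)
    for (r in seq_len(nrow(rc))) {
      a <- m[, rc$rep1[r]]; b <- m[, rc$rep2[r]]
      ok <- !is.na(a) & !is.na(b)
      x <- a[ok]; y <- b[ok]
      oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(rc$r[r], oracle, tolerance = 1e-12)
    }
    # duplicated replicate -> r = 1; anti-proportional -> r = -1
    dup <- SecretomeExperiment(cbind(m[, 1], m[, 1]), "fA", "birch", 1:2,
                               scale = "log2")
    expect_equal(replicateCorrelation(dup)$r, 1)
    anti <- SecretomeExperiment(cbind(1:5, 11 - (1:5) * 2),
                                "fA", "birch", 1:2, scale = "log2")
    expect_equal(replicateCorrelation(anti)$r, -1)
    # fewer than 3 common proteins -> undefined
    sparse <- matrix(c(1, 2, NA, NA, NA, NA, 3, 4), 4, 2)
    rownames(sparse) <- paste0("P", 1:4)
    seS <- SecretomeExperiment(sparse, "fA", "birch", 1:2, scale = "log2")
    expect_true(is.na(replicateCorrelation(seS)$r))
  })
})

test_that("replicate averaging ignores missing values", {
  m <- rbind(P1 = c(1, 2, 3), P2 = c(4, NA, NA), P3 = c(NA, NA, NA))
  se <- SecretomeExperiment(m, "fA", "birch", 1:3, scale = "log2")
  avg <- abundances(averageReplicates(se))
  expect_equal(unname(avg[, 1]), c(2, 4, NA))
  expect_true(is.na(sampleReplicate(averageReplicates(se))))
})
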
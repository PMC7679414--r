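test_that("count-based summaries use half-up integer percentages", {
  s <- secretomeSummaryFromCounts(data.frame(
    fungus = c("A", "B"), nIdentified = c(112, 10),
    nSecreted = c(102, 0)))
  expect_equal(s$pctSecreted[1:2], c(91, 0))
  expect_equal(s$nIdentified[s$fungus == "total"], 122)
  # mean CAZyme percentage is the rounded mean of per-fungus percentages
  s2 <- secretomeSummaryFromCounts(data.frame(
    fungus = letters[1:5], nIdentified = 100,
    nSecreted = 50, nCazymes = c(68, 33, 39, 40, 71)))
  expect_equal(attr(s2, "meanCazymePct"), 50)
})

test_that("secretome summaries count filtered proteins per fungus", {
  b <- generateStudy(syntheticConfig(nFungi = 2L, nProteins = 80L,
                                     seed = 77L))
  d <- detectionFilter(b$abundance)
  s <- summarizeSecretome(b$annotations, d)
  for (f in d@fungi) {
    row <- s[s$fungus == f, ]
    ids <- keptProteins(d, f)
    expect_equal(row$nIdentified, length(ids))
    cats <- categories(b$annotations)[ids]
    expect_equal(row$nCazymes, sum(cats %in% cazymeCategories()))
    expect_equal(row$nUncharacterized, sum(cats == "uncharacterized"))
    expect_lte(row$nSecreted, row$nIdentified)
  }
})

test_that("class-by-substrate tables honor multi-class counting and
           carry-over", {
  # one GH5 protein: two replicates on bagasse, one on spruce
  m <- matrix(NA_real_, 1, 9, dimnames = list("P1", NULL))
  design <- expand.grid(replicate = 1:3,
                        substrate = c("bagasse", "birch", "spruce"),
                        stringsAsFactors = FALSE)
  m[1, design$substrate == "bagasse" & design$replicate <= 2] <- 100
  m[1, design$substrate == "spruce" & design$replicate == 1] <- 100
  se <- SecretomeExperiment(m, "fA", design$substrate, design$replicate)
  d <- detectionFilter(se)
  ann <- AnnotationSet("P1", cazy = list("GH5"))
  tab <- classSubstrateTable(ann, d, "fA")
  eg <- tab[tab$class == "endoglucanase", ]
  em <- tab[tab$class == "endomannanase", ]
  for (row in list(eg, em)) {
    expect_equal(row$total, 1L)
    expect_equal(row$bagasse, 1L)
    expect_equal(row$spruce, 1L)  # single-replicate carry-over
    expect_equal(row$birch, 0L)
  }
  expect_true(all(tab$class[tab$total > 0] %in%
                    c("endoglucanase", "endomannanase")))
  # genome-encoded counts merge as an optional column
  tab2 <- classSubstrateTable(ann, d, "fA",
                              genomeCounts = c(endoglucanase = 28))
  expect_equal(tab2$genome[tab2$class == "endoglucanase"], 28)
})

test_that("a synthetic fixture's table equals a hand enumeration", {
  b <- generateStudy(syntheticConfig(nFungi = 1L, nProteins = 60L,
                                     seed = 81L))
  d <- detectionFilter(b$abundance)
  tab <- classSubstrateTable(b$annotations, d, "fungus_1", b$classMap)
  kept <- keptProteins(d, "fungus_1")
  fams <- cazyFamilies(b$annotations)
  for (cl in b$classMap$class) {
    fam <- b$classMap$family[b$classMap$class == cl]
    members <- kept[vapply(kept, function(p) fam %in% fams[[p]], TRUE)]
    expect_equal(tab$total[tab$class == cl], length(members))
    for (s in d@substrates)
      expect_equal(tab[tab$class == cl, s],
                   sum(members %in% presentOn(d, "fungus_1", s)))
  }
})

test_that("the pipeline is deterministic end to end", {
  cfg <- list(input = list(synthetic = list(seed = 7, nProteins = 80,
                                            nFungi = 2)))
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- runPipeline(cfg, d1)
  r2 <- runPipeline(cfg, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  # all advertised artifacts exist
  expect_true(all(c("manifest.json", "secretome_summary.tsv",
                    "heatmap_matrix.tsv", "class_network.sif",
                    "class_network_edges.tsv", "class_network.graphml",
                    "edge_significance.tsv",
                    "replicate_correlations.tsv") %in% list.files(d1)))
  expect_s4_class(r1$final, "ClassNetwork")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the pipeline runs from fixture files on disk", {
  b <- generateStudy(syntheticConfig(nFungi = 2L, nProteins = 60L,
                                     seed = 15L))
  fdir <- tempfile()
  writeFixtures(b, fdir)
  out <- tempfile()
  cfg <- list(input = list(paths = list(
    abundance = file.path(fdir, "abundance.tsv"),
    cazy = file.path(fdir, "cazy_families.tsv"),
    merops = file.path(fdir, "peptidase_families.tsv"),
    signalp = file.path(fdir, "signalp.tsv"),
    phobius = file.path(fdir, "phobius.tsv"),
    wolfpsort = file.path(fdir, "wolfpsort.tsv"),
    descriptions = file.path(fdir, "descriptions.tsv"),
    class_map = file.path(fdir, "class_map.tsv"))))
  res <- runPipeline(cfg, out)
  expect_s4_class(res$final, "ClassNetwork")
  expect_true(file.exists(file.path(out, "secretome_summary.tsv")))
  unlink(c(fdir, out), recursive = TRUE)
})

test_that("config errors name the offending key", {
  expect_error(runPipeline(list(input = list(paths = list())), tempfile()),
               "input.paths.abundance")
  expect_error(runPipeline(list(), tempfile()), "input.synthetic")
})

test_that("YAML configs are accepted", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("input:", "  synthetic:", "    seed: 3", "    nProteins: 60",
               "    nFungi: 1", "network:", "  alpha: 0.1"), path)
  out <- tempfile()
  res <- runPipeline(path, out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$parameters$network$alpha, 0.1)
  expect_equal(manifest$seed, 3)
  unlink(out, recursive = TRUE)
})
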
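## Summary tables (secretome composition, per-class per-substrate
## detection counts) and the end-to-end pipeline runner.

#' Secretome summary from raw counts
#'
#' Computes the printed-table form of a secretome summary: per fungus the
#' number of identified proteins and the counts and half-up-rounded
#' percentages of predicted-secreted proteins, CAZymes and uncharacterized
#' proteins, plus a totals row. The mean of the per-fungus CAZyme
#' percentages (itself half-up rounded) is attached as
#' \code{attr(x, "meanCazymePct")}.
#'
#' @param counts data.frame with columns \code{fungus},
#'   \code{nIdentified}, \code{nSecreted} and optionally \code{nCazymes},
#'   \code{nUncharacterized}.
#' @return data.frame with count and \code{pct*} columns and a final
#'   "total" row.
#' @examples
#' secretomeSummaryFromCounts(data.frame(
#'   fungus = "A", nIdentified = 112, nSecreted = 102))$pctSecreted  # 91
#' @export
secretomeSummaryFromCounts <- function(counts) {
  stopifnot(all(c("fungus", "nIdentified", "nSecreted") %in%
                  colnames(counts)))
  for (col in c("nCazymes", "nUncharacterized"))
    if (!col %in% colnames(counts)) counts[[col]] <- NA_real_
  out <- counts[, c("fungus", "nIdentified", "nSecreted", "nCazymes",
                    "nUncharacterized")]
  out$pctSecreted <- percentHalfUp(out$nSecreted, out$nIdentified)
  out$pctCazymes <- percentHalfUp(out$nCazymes, out$nIdentified)
  out$pctUncharacterized <- percentHalfUp(out$nUncharacterized,
                                          out$nIdentified)
  total <- data.frame(fungus = "total",
                      nIdentified = sum(out$nIdentified),
                      nSecreted = sum(out$nSecreted),
                      nCazymes = sum(out$nCazymes),
                      nUncharacterized = sum(out$nUncharacterized),
                      pctSecreted = NA_real_, pctCazymes = NA_real_,
                      pctUncharacterized = NA_real_)
  res <- rbind(out, total)
  attr(res, "meanCazymePct") <-
    if (all(is.na(out$pctCazymes))) NA_real_
    else roundHalfUp(mean(out$pctCazymes, na.rm = TRUE))
  res
}

#' Summarize the filtered secretome of each fungus
#'
#' Counts, per fungus, the proteins kept by the detection filter and how
#' many of them are consensus-secreted, CAZymes (including stand-alone
#' CBMs) or uncharacterized, with half-up-rounded percentages.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param decision a \linkS4class{FilterDecision}.
#' @return see [secretomeSummaryFromCounts()].
#' @export
summarizeSecretome <- function(annotations, decision) {
  cat_ <- categories(annotations)
  sec <- isSecreted(annotations)
  rows <- lapply(decision@fungi, function(f) {
    ids <- intersect(keptProteins(decision, f), proteinIds(annotations))
    data.frame(fungus = f, nIdentified = length(ids),
               nSecreted = sum(sec[ids]),
               nCazymes = sum(cat_[ids] %in% cazymeCategories()),
               nUncharacterized = sum(cat_[ids] == "uncharacterized"))
  })
  secretomeSummaryFromCounts(do.call(rbind, rows))
}

#' Per-class, per-substrate detection counts for one fungus
#'
#' The per-substrate detection table: for every enzyme class, the total
#' number of detected (filter-passing) member proteins and the number
#' present on each substrate. Presence uses the single-replicate
#' carry-over rule of the detection filter, and proteins whose families
#' map to several classes are counted in every one of them. Genome-encoded
#' counts per class, when available from an external family scan, can be
#' merged in as an optional column.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param decision a \linkS4class{FilterDecision}.
#' @param fungus fungus label.
#' @param classMap family-to-class map data.frame.
#' @param genomeCounts optional named numeric: class -> genome-encoded
#'   count.
#' @return data.frame: class, (genome), total, then one column per
#'   substrate.
#' @export
classSubstrateTable <- function(annotations, decision, fungus,
                                classMap = defaultEnzymeClassMap(),
                                genomeCounts = NULL) {
  kept <- intersect(keptProteins(decision, fungus),
                    proteinIds(annotations))
  sets <- classMembers(annotations, classMap, proteins = kept)
  out <- data.frame(class = names(sets), total = lengths(sets),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (s in decision@substrates) {
    pres <- presentOn(decision, fungus, s)
    out[[s]] <- vapply(sets, function(mem) sum(mem %in% pres), 0L)
  }
  if (!is.null(genomeCounts))
    out <- cbind(out[, 1, drop = FALSE],
                 genome = unname(genomeCounts[out$class]),
                 out[, -1, drop = FALSE])
  out
}

pipelineDefaults <- function() list(
  normalization = list(c = 5, one_step = FALSE),
  filter = list(min_replicates = 2L),
  network = list(beta = 1, alpha = 0.05),
  cluster = list(missing_fill = -10),
  output = list(formats = c("sif", "graphml")))

mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      mergeConfig(defaults[[k]], user[[k]]) else user[[k]]
  }
  defaults
}

#' Run the full secretome analysis pipeline
#'
#' Executes, in order: input loading (or synthetic-study generation),
#' detection filtering, log2 + biweight normalization, replicate QC,
#' replicate averaging, hierarchical heat-map ordering, per-fungus protein
#' and class networks, cross-fungus averaging, strength computation,
#' percent discretization, MLF edge p-values and filtering, network
#' export, and the secretome-summary and class-by-substrate report
#' tables. All artifacts plus a manifest (package version, seed, all
#' effective parameters) land in \code{outDir}; runs with the same config
#' are byte-identical.
#'
#' @param config path to a YAML config file, or an equivalent nested
#'   list. Inputs come either from \code{input$synthetic} (arguments to
#'   [syntheticConfig()]) or \code{input$paths} (keys \code{abundance},
#'   \code{cazy}, \code{merops}, \code{signalp}, \code{phobius},
#'   \code{wolfpsort}, optional \code{descriptions}, \code{class_map}).
#'   Tunables: \code{normalization$c}, \code{normalization$one_step},
#'   \code{filter$min_replicates}, \code{network$beta},
#'   \code{network$alpha}.
#' @param outDir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # --- input ------------------------------------------------------------
  if (!is.null(cfg$input$synthetic)) {
    sc <- do.call(syntheticConfig, cfg$input$synthetic)
    bundle <- generateStudy(sc)
    seed <- sc@seed
  } else if (!is.null(cfg$input$paths)) {
    p <- cfg$input$paths
    if (is.null(p$abundance))
      stop("config key input.paths.abundance is required")
    for (k in c("cazy", "merops", "signalp", "phobius", "wolfpsort"))
      if (is.null(p[[k]]))
        stop("config key input.paths.", k, " is required")
    se <- readAbundance(p$abundance)
    ann <- readAnnotations(p$cazy, p$merops, p$signalp, p$phobius,
                           p$wolfpsort, descriptionPath = p$descriptions,
                           proteins = rownames(se))
    cm <- if (!is.null(p$class_map)) readEnzymeClassMap(p$class_map)
          else defaultEnzymeClassMap()
    bundle <- list(abundance = se, annotations = ann, classMap = cm,
                   truth = NULL)
    seed <- NA_integer_
  } else stop("config key input.synthetic or input.paths is required")

  # --- preprocess -------------------------------------------------------
  decision <- detectionFilter(bundle$abundance,
                              cfg$filter$min_replicates)
  filtered <- applyFilter(bundle$abundance, decision)
  normed <- normalizeAbundance(filtered, c = cfg$normalization$c,
                               oneStep = isTRUE(cfg$normalization$one_step))
  qc <- replicateCorrelation(normed)
  avg <- averageReplicates(normed)

  # --- clustering -------------------------------------------------------
  hm <- NULL
  if (nrow(avg) >= 2) {
    dend <- hierarchicalOrder(avg, cfg$cluster$missing_fill)
    hm <- heatmapMatrix(avg, dend)
    writeHeatmapTSV(hm, file.path(outDir, "heatmap_matrix.tsv"))
  }

  # --- networks ---------------------------------------------------------
  nets <- perFungusClassNetworks(normed, decision, bundle$annotations,
                                 bundle$classMap, beta = cfg$network$beta)
  grand <- averageClassNetworks(nets)
  grand <- discretizeWeights(grand)
  grand <- mlfEdgePvalues(grand)
  final <- filterNetwork(grand, alpha = cfg$network$alpha)
  for (fmt in cfg$output$formats)
    exportNetwork(final, outDir, prefix = "class_network", format = fmt)
  write.table(edgeSignificance(integerWeights(grand)),
              file.path(outDir, "edge_significance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- reports ----------------------------------------------------------
  summary <- summarizeSecretome(bundle$annotations, decision)
  write.table(summary, file.path(outDir, "secretome_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in decision@fungi) {
    tab <- classSubstrateTable(bundle$annotations, decision, f,
                               bundle$classMap)
    write.table(tab, file.path(outDir,
                               paste0("class_substrate_", f, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(qc, file.path(outDir, "replicate_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(package = "secretomeNet",
                   version = as.character(packageVersion("secretomeNet")),
                   seed = seed, parameters = cfg[c("normalization",
                                                   "filter", "network",
                                                   "cluster")],
                   artifacts = sort(list.files(outDir)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(decision = decision, normalized = normed, averaged = avg,
                 qc = qc, heatmap = hm, networks = nets, grand = grand,
                 final = final, summary = summary))
}
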
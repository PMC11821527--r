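#' Screen pipeline configuration
#'
#' Centralizes every tunable of the end-to-end screen analysis with its
#' standard default: the |log2 FC| > 0.7 / P < 0.05 significance rule, the
#' width 0.3 / down shift 1.8 imputation law, average-linkage clustering into
#' four groups, and the top-50 correlation report.  Unknown keys are
#' rejected.
#'
#' @param ... overrides of the default fields (see the function body or the
#'   returned list for the full set).
#' @param file optional YAML file of overrides, applied before \code{...}.
#' @return named list of class \code{screenConfig}.
#' @export
screenConfig <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    simulate = TRUE,            # FALSE: read matrix_path instead
    matrix_path = NULL,
    sim = list(),               # overrides for screenSimConfig()
    impute = TRUE,
    impute_width = 0.3,
    impute_downshift = 1.8,
    fc_threshold = 0.7,
    p_threshold = 0.05,
    fdr = FALSE,
    cluster = TRUE,
    n_clusters = 4L,
    linkage = "average",
    correlate = TRUE,
    query = "tag_significant",  # or a character vector of molecule ids
    top_n = 50L,
    enrichment_direction = "down",
    out_dir = NULL)
  overrides <- list(...)
  if (!is.null(file)) {
    fromFile <- yaml::read_yaml(file)
    overrides <- modifyList(fromFile, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  .check(length(unknown) == 0, "unknown config key(s): %s",
         paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  class(cfg) <- "screenConfig"
  cfg
}

#' Run the end-to-end screen analysis
#'
#' Chains the full pipeline on synthetic or user data: impute missing values,
#' compute condition-wise mean fold changes, per-condition significance
#' against the wild-type reference, mitochondrial enrichment, strain
#' clustering, and the TAG-query average-rank correlation score, writing a
#' deterministic report bundle.
#'
#' The default TAG query set is the data-driven one the screen used:
#' significantly decreased TAG species in the recovering (G3) strains at the
#' early timepoint; an explicit id vector can be supplied instead via
#' \code{config$query}.
#'
#' @param config a \code{\link{screenConfig}}.
#' @return list (invisibly also written to \code{config$out_dir} when set)
#'   with elements \code{experiment}, \code{fc_matrix}, \code{significance}
#'   (per-condition classified records), \code{enrichment},
#'   \code{clustering}, \code{ranking}, \code{top}, \code{query_ids},
#'   \code{log}.  When \code{out_dir} is set the bundle is written as TSV /
#'   JSON files, each run reproducible byte-for-byte under a fixed seed.
#' @export
runScreen <- function(config = screenConfig()) {
  cfg <- config
  t0 <- Sys.time()
  if (isTRUE(cfg$simulate)) {
    simCfg <- do.call(screenSimConfig, modifyList(list(seed = cfg$seed),
                                                  cfg$sim))
    sim <- simulateScreen(simCfg)
    se <- sim$experiment
    truth <- sim$truth
  } else {
    .check(!is.null(cfg$matrix_path), "matrix_path required when simulate ",
           "is FALSE")
    se <- readAbundanceMatrix(cfg$matrix_path)
    truth <- NULL
  }
  if (isTRUE(cfg$impute))
    se <- imputeMissing(se, width = cfg$impute_width,
                        downshift = cfg$impute_downshift, seed = cfg$seed)
  refSel <- selectSamples(se, group = "WT", timepoint = "E")
  fcMat <- conditionMeanFC(se, ref = refSel)

  ## per-condition significance vs the WT reference
  cond <- conditionOf(se)
  refCond <- unique(cond[refSel])
  sigTables <- list()
  for (cl in setdiff(unique(cond), refCond)) {
    rec <- log2FoldChanges(se, case = cond == cl, ref = refSel)
    sigTables[[cl]] <- classifySignificant(rec, cfg$fc_threshold,
                                           cfg$p_threshold, fdr = cfg$fdr)
  }

  ## mitochondrial enrichment among decreased proteins, per condition
  mitoIds <- rownames(se)[isMito(se)]
  prot <- moleculeLayer(se) == "protein"
  enrich <- lapply(sigTables, function(tab)
    mitoEnrichment(tab[prot, ], intersect(mitoIds, tab$molecule_id[prot]),
                   direction = cfg$enrichment_direction))

  clustering <- NULL
  if (isTRUE(cfg$cluster))
    clustering <- clusterStrains(fcMat[, setdiff(colnames(fcMat), refCond),
                                       drop = FALSE],
                                 n_clusters = cfg$n_clusters,
                                 linkage = cfg$linkage)

  ranking <- NULL; top <- NULL; queryIds <- NULL
  if (isTRUE(cfg$correlate)) {
    queryIds <- if (identical(cfg$query, "tag_significant")) {
      .significantTagQuery(se, sigTables)
    } else cfg$query
    if (length(queryIds) >= 2) {
      ranking <- averageRankScore(fcMat, queryIds)
      top <- topCorrelates(ranking, min(cfg$top_n, nrow(rankingTable(
        ranking))))
    }
  }

  logInfo <- list(seed = cfg$seed,
                  package_version = as.character(utils::packageVersion(
                    "mitoscreen")),
                  n_molecules = nrow(se), n_samples = ncol(se),
                  query_ids = queryIds,
                  config = cfg[setdiff(names(cfg), c("sim", "out_dir"))])
  bundle <- list(experiment = se, truth = truth, fc_matrix = fcMat,
                 significance = sigTables, enrichment = enrich,
                 clustering = clustering, ranking = ranking, top = top,
                 query_ids = queryIds, log = logInfo)
  if (!is.null(cfg$out_dir)) writeReportBundle(bundle, cfg$out_dir, cfg)
  invisible(bundle)
}

## TAG species significantly decreased in the G3 strains at E (the screen's
## data-driven query set); union over G3 E conditions
.significantTagQuery <- function(se, sigTables) {
  tag <- rownames(se)[!is.na(lipidClass(se)) & lipidClass(se) == "TAG"]
  g3e <- unique(conditionOf(se)[colData(se)$group == "G3" &
                                  colData(se)$timepoint == "E"])
  hits <- character()
  for (cl in intersect(g3e, names(sigTables))) {
    tab <- sigTables[[cl]]
    hits <- union(hits, tab$molecule_id[tab$molecule_id %in% tag &
                                          tab$significant &
                                          tab$direction == "down"])
  }
  sort(hits)
}

#' Write a screen report bundle to disk
#'
#' Writes the fold-change matrix, per-condition significance tables, the
#' enrichment summary, the clustering, the correlation ranking and a JSON run
#' log into \code{out_dir}.  Output is deterministic for a fixed seed and
#' config; the log carries the md5 of the serialized config so bundles can
#' be compared by hash.
#'
#' @param bundle result of \code{\link{runScreen}}.
#' @param out_dir output directory (created if needed).
#' @param config the \code{\link{screenConfig}} used.
#' @return character vector of files written, invisibly.
#' @export
writeReportBundle <- function(bundle, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  fcDf <- data.frame(molecule_id = rownames(bundle$fc_matrix),
                     as.data.frame(bundle$fc_matrix, check.names = FALSE),
                     check.names = FALSE)
  wr(fcDf, "fold_changes.tsv")
  for (cl in names(bundle$significance))
    wr(bundle$significance[[cl]], paste0("significance_", cl, ".tsv"))
  enr <- do.call(rbind, lapply(names(bundle$enrichment), function(cl) {
    e <- bundle$enrichment[[cl]]
    data.frame(condition = cl, direction = e@direction,
               mito_changed = e@contingency[1, 1],
               mito_unchanged = e@contingency[1, 2],
               other_changed = e@contingency[2, 1],
               other_unchanged = e@contingency[2, 2],
               odds_ratio = e@oddsRatio, p_value = e@pValue)
  }))
  wr(enr, "enrichment.tsv")
  if (!is.null(bundle$clustering)) {
    cj <- file.path(out_dir, "clustering.json")
    hc <- clusterTree(bundle$clustering)
    jsonlite::write_json(list(labels = as.list(clusterLabels(
      bundle$clustering)), merge = hc$merge, height = hc$height,
      order_labels = hc$labels[hc$order]), cj, auto_unbox = TRUE,
      digits = NA)
    files <- c(files, cj)
  }
  if (!is.null(bundle$ranking)) wr(rankingTable(bundle$ranking),
                                   "correlation_ranking.tsv")
  if (!is.null(bundle$top)) wr(bundle$top, "top_correlates.tsv")
  cfgFile <- file.path(out_dir, "config.json")
  jsonlite::write_json(bundle$log, cfgFile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, cfgFile)
  logFile <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(seed = bundle$log$seed,
                            package_version = bundle$log$package_version,
                            config_md5 = unname(tools::md5sum(cfgFile)),
                            files = basename(files)),
                       logFile, auto_unbox = TRUE, digits = NA)
  invisible(c(files, logFile))
}

#' md5 digest of every file in a report bundle directory
#'
#' Convenience for determinism checks: returns the md5 of each regular file
#' in \code{dir}, named by relative path.
#'
#' @param dir bundle directory.
#' @return named character vector of md5 hashes.
#' @export
bundleHashes <- function(dir) {
  f <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(f)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
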
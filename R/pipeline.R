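#' Assemble a pipeline run configuration
#'
#' Collects every knob of \code{\link{runTimeline}} with documented
#' defaults. Either \code{inputDir} (a directory of TSV tables for
#' \code{\link{readDataset}}) or \code{sim} (a
#' \code{\link{SimulationConfig-class}} for the synthetic generator) must be
#' provided; the seed is recorded in the run manifest and drives every
#' random draw.
#'
#' @param outDir output directory for the run.
#' @param seed integer master seed.
#' @param inputDir optional directory with an existing dataset.
#' @param sim optional \code{SimulationConfig}; defaults to
#'   \code{simulationConfig(seed = seed)} when \code{inputDir} is absent.
#' @param ageRule \code{"second_oldest"} (default) or \code{"oldest"}.
#' @param eraWidth era width on the nd timeline (default 0.1).
#' @param nRand ER ensemble size for small-world rows (default 20).
#' @param reps power-law bootstrap replicates (default 100).
#' @param pMethod power-law p-value method (default \code{"bootstrap"}).
#' @param minWeight edge-weight threshold of the reduced subnetwork
#'   representation (default 2).
#' @param topK centrality top-list size (default 10).
#' @return A validated list of class \code{"runConfig"}.
#' @export
runConfig <- function(outDir, seed = 1L, inputDir = NULL, sim = NULL,
                      ageRule = c("second_oldest", "oldest"),
                      eraWidth = 0.1, nRand = 20L, reps = 100L,
                      pMethod = c("bootstrap", "analytic"),
                      minWeight = 2L, topK = 10L) {
  ageRule <- match.arg(ageRule)
  pMethod <- match.arg(pMethod)
  if (is.null(inputDir) && is.null(sim))
    sim <- simulationConfig(seed = seed)
  if (!is.null(sim)) stopifnot(is(sim, "SimulationConfig"))
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              inputDir = inputDir, sim = sim, ageRule = ageRule,
              eraWidth = eraWidth, nRand = as.integer(nRand),
              reps = as.integer(reps), pMethod = pMethod,
              minWeight = as.integer(minWeight), topK = as.integer(topK))
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{runConfig}}; the optional
#' \code{sim:} block mirrors \code{\link{simulationConfig}} (snake_case or
#' camelCase keys both accepted).
#'
#' @param path YAML file.
#' @param outDir overrides the file's \code{outDir} when given.
#' @return A \code{"runConfig"} list.
#' @export
readRunConfig <- function(path, outDir = NULL) {
  y <- yaml::read_yaml(path)
  camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(y) <- camel(names(y))
  sim <- NULL
  if (!is.null(y$sim)) {
    names(y$sim) <- camel(names(y$sim))
    sim <- do.call(simulationConfig, y$sim)
  }
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  if (!is.null(outDir)) args$outDir <- outDir
  do.call(runConfig, args)
}

.write_matrix_tsv <- function(M, path, rowlab = "id") {
  df <- data.frame(rownames(M), as.data.frame(unclass(M)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowlab
  .write_tsv(df, path)
}

#' Run the full evolutionary network analysis
#'
#' End-to-end orchestration: obtain the dataset (simulate or read), assign
#' enzyme ages, build the subnetwork- and mesonetwork-level bipartite
#' networks and their timeline slices, compute the per-era statistical
#' battery, centralities, recruitment matrices, mesonetwork link tables,
#' Ward dendrogram with modularity heatmap, and (when annotations are
#' present) the taxonomic, functional and catalytic distributions. All
#' outputs are TSV (plus a Newick dendrogram and a YAML manifest recording
#' the configuration, seed, package version and wall time); given the same
#' configuration and seed, two runs produce byte-identical TSVs.
#'
#' @param cfg a \code{\link{runConfig}} list.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the dataset, ages, the metrics table and
#'   the vector of files written.
#' @export
runTimeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "runConfig"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$inputDir)) {
    say("reading dataset from ", cfg$inputDir)
    ds <- readDataset(cfg$inputDir)
  } else {
    say("simulating dataset (seed ", cfg$sim@seed, ")")
    ds <- simulateDataset(cfg$sim)
  }
  files <- writeDataset(ds, file.path(cfg$outDir, "dataset"))

  ages <- enzymeAges(ds, rule = cfg$ageRule)
  ts <- seq(cfg$eraWidth, 1, by = cfg$eraWidth)

  say("computing per-era statistical battery (",
      length(ts), " slices x 3 graph types)")
  metrics <- metricsTimeline(ds, ages, ts = ts, nRand = cfg$nRand,
                             reps = cfg$reps, pMethod = cfg$pMethod,
                             seed = cfg$seed)
  mt <- metrics
  num <- vapply(mt, is.numeric, logical(1))
  mt[num] <- lapply(mt[num], function(x) formatC(x, format = "g",
                                                 digits = 7))
  files <- c(files, .write_tsv(mt, file.path(cfg$outDir,
                                             "metrics_timeseries.tsv")))

  say("centrality tables per slice")
  B <- buildBipartite(ds, ages, "subnetwork")
  for (t in ts) {
    sl <- sliceByAge(B, t)
    if (igraph::vcount(sl) == 0L) next
    enz <- projectOneMode(sl, "enzyme")
    if (igraph::ecount(enz) == 0L) next
    ct <- centralityTable(enz, k = cfg$topK)
    files <- c(files, .write_tsv(
      ct$top, file.path(cfg$outDir, sprintf("centralities_%.1f.tsv", t))))
  }

  say("recruitment matrices and link tables")
  sm <- sharingMatrix(ds, ages, width = cfg$eraWidth)
  files <- c(files, .write_matrix_tsv(sm, file.path(cfg$outDir,
                                                    "sharing_matrix.tsv"),
                                      rowlab = "map_id"))
  ec_tab <- eraCounts(ds, ages, width = cfg$eraWidth)
  files <- c(files, .write_matrix_tsv(ec_tab,
                                      file.path(cfg$outDir,
                                                "era_counts.tsv"),
                                      rowlab = "meso_code"))
  ml <- mesoLinkTable(ds, ages, ts = ts)
  for (t in ts) {
    sub <- ml[ml$t == t, c("meso1", "meso2", "weight"), drop = FALSE]
    files <- c(files, .write_tsv(
      sub, file.path(cfg$outDir, sprintf("meso_links_%.1f.tsv", t))))
  }

  say("subnetwork dendrogram and modularity heatmap")
  sub_proj <- projectOneMode(B, "category")
  sub_lcc <- largestComponent(sub_proj)
  if (igraph::vcount(sub_lcc) >= 2L && igraph::ecount(sub_lcc) >= 1L) {
    A <- as.matrix(igraph::as_adjacency_matrix(sub_lcc, attr = "weight",
                                               sparse = FALSE))
    hc <- wardCluster(A)
    files <- c(files, file.path(cfg$outDir, "dendrogram.nwk"))
    exportNewick(hc, file.path(cfg$outDir, "dendrogram.nwk"))
    hm <- modularityHeatmapMatrix(sub_lcc, order = hc$labels[hc$order])
    files <- c(files, .write_matrix_tsv(
      round(hm, 6), file.path(cfg$outDir, "heatmap_matrix.tsv"),
      rowlab = "map_id"))
    red <- suppressWarnings(
      reduceRepresentation(sub_proj, minWeight = cfg$minWeight))
    if (igraph::ecount(red) > 0L)
      files <- c(files, writeEdgeList(
        red, file.path(cfg$outDir, "subnetwork_reduced_edges.tsv")))
  }

  ann <- annotations(ds)
  if (!is.null(ann$taxa)) {
    say("annotation distributions")
    venn <- vennAssign(ann$taxa)
    venn_df <- data.frame(ec = names(venn), venn_group = unname(venn),
                          stringsAsFactors = FALSE)
    files <- c(files, .write_tsv(venn_df,
                                 file.path(cfg$outDir, "venn_groups.tsv")))
    if (!is.null(ann$functions)) {
      fd <- functionalDistribution(ds, ages, venn = venn,
                                   width = cfg$eraWidth)
      files <- c(files,
                 .write_matrix_tsv(fd$general_by_venn,
                                   file.path(cfg$outDir,
                                             "function_general_by_venn.tsv"),
                                   rowlab = "general"),
                 .write_matrix_tsv(fd$detailed_by_era,
                                   file.path(cfg$outDir,
                                             "function_detailed_by_era.tsv"),
                                   rowlab = "detailed"))
    }
    if (!is.null(ann$catalysis)) {
      cd <- catalyticDistribution(ann$catalysis, venn, ages,
                                  width = cfg$eraWidth)
      files <- c(files,
                 .write_matrix_tsv(cd$by_venn,
                                   file.path(cfg$outDir,
                                             "catalytic_by_venn.tsv"),
                                   rowlab = "role_group"),
                 .write_matrix_tsv(cd$by_era,
                                   file.path(cfg$outDir,
                                             "catalytic_by_era.tsv"),
                                   rowlab = "role_group"))
    }
  }

  manifest <- list(
    package = "metanet",
    version = as.character(utils::packageVersion("metanet")),
    seed = cfg$seed,
    age_rule = cfg$ageRule,
    era_width = cfg$eraWidth,
    n_rand = cfg$nRand,
    bootstrap_reps = cfg$reps,
    p_method = cfg$pMethod,
    min_weight = cfg$minWeight,
    top_k = cfg$topK,
    input = if (is.null(cfg$inputDir)) "simulated" else cfg$inputDir,
    n_enzymes = length(enzymes(ds)),
    wall_time_s = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 2),
    files = sort(basename(files)))
  yaml::write_yaml(manifest, file.path(cfg$outDir, "manifest.yml"))
  say("done in ", manifest$wall_time_s, " s")
  invisible(list(dataset = ds, ages = ages, metrics = metrics,
                 files = files))
}
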
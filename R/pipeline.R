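#' Assemble and validate a pipeline configuration
#'
#' Either a `synthetic` block (arguments for [synthetic_config()]) or the
#' full set of input paths (`activity`, `assay_meta`, `ppi`, plus marker
#' files `essential`, `drug_targets`, `disease_genes`, `bioassay_targets`)
#' must be supplied.  Analysis parameters get the pipeline defaults when
#' absent.  Accepts a YAML file path or a nested list with blocks
#' `inputs` / `synthetic` / `projection` / `enrichment` / `prioritize`.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(projection = list(min_jaccard = 0.10),
                   enrichment = list(n_random = 10000, rng_seed = 1L),
                   prioritize = list(bin_width = 0.5, min_degree = 17))
  for (blk in names(defaults))
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  has_synth <- !is.null(config$synthetic)
  has_paths <- !is.null(config$inputs)
  if (!has_synth && !has_paths)
    stop("config needs either a 'synthetic' block or an 'inputs' block",
         call. = FALSE)
  if (has_paths) {
    need <- c("activity", "assay_meta", "ppi", "essential", "drug_targets",
              "disease_genes", "bioassay_targets")
    missing <- setdiff(need, names(config$inputs))
    if (length(missing))
      stop("inputs block missing path(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (has_synth)
    config$synthetic <- do.call(synthetic_config, config$synthetic)
  with(config$projection,
       stopifnot(min_jaccard > 0, min_jaccard <= 1))
  with(config$enrichment, stopifnot(n_random >= 1))
  with(config$prioritize, stopifnot(bin_width > 0, min_degree >= 0))
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screening-network pipeline
#'
#' Stages: `simulate` (generate synthetic inputs and write them as the same
#' TSV formats the readers consume), `project` (bipartite build + Jaccard
#' projection, GraphML export), `topology` (degree distribution, power-law
#' fit, clustering profile), `enrich` (distance-profile enrichment of
#' bioassay targets around essential genes, drug targets and disease
#' genes), `prioritize` (characteristic distances and binned ranking).
#' `"all"` runs every applicable stage.  Every run writes `run_log.txt`
#' with the configuration echo, RNG seeds and package versions; identical
#' configurations produce byte-identical result tables.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @param out_dir Output directory, created if needed.
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  config <- pipeline_config(config)
  known <- c("simulate", "project", "topology", "enrich", "prioritize")
  if (identical(stages, "all")) stages <- known
  stopifnot(all(stages %in% known))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_lines <- c("assaynet pipeline run",
                 paste("stages:", paste(stages, collapse = ", ")),
                 paste("config:", paste(deparse(unclass(config)),
                                        collapse = " ")),
                 paste("assaynet version:",
                       as.character(utils::packageVersion("assaynet"))),
                 paste("igraph version:",
                       as.character(utils::packageVersion("igraph"))))

  if (!is.null(config$synthetic)) {
    scfg <- config$synthetic
    ppi <- gen_ppi(scfg$n_proteins, scfg$attach_m, scfg$rng_seed)
    markers <- gen_markers(ppi, scfg)
    activity <- gen_activity(scfg, markers)
    if ("simulate" %in% stages) {
      paths$activity <- file.path(out_dir, "activity.tsv")
      paths$assay_meta <- file.path(out_dir, "assays.tsv")
      write_activity(activity, paths$activity, paths$assay_meta)
      paths$ppi <- write_edges(ppi, file.path(out_dir, "ppi_edges.tsv"))
      for (ms in names(markers)) {
        p <- file.path(out_dir, paste0(ms, ".txt"))
        write_marker_set(markers[[ms]], p)
        paths[[ms]] <- p
      }
      log_lines <- c(log_lines, paste("synthetic rng_seed:", scfg$rng_seed))
    }
  } else {
    activity <- read_activity(config$inputs$activity,
                              config$inputs$assay_meta)
    ppi <- read_edges(config$inputs$ppi)
    markers <- structure(
      list(essential = read_marker_set(config$inputs$essential),
           drug_targets = read_marker_set(config$inputs$drug_targets),
           disease_genes = read_marker_set(config$inputs$disease_genes),
           bioassay_targets = read_marker_set(config$inputs$bioassay_targets)),
      class = "marker_sets")
  }

  assay_net <- NULL
  if (any(c("project", "topology") %in% stages)) {
    bip <- build_bipartite(activity)
    assay_net <- project(bip, config$projection$min_jaccard)
  }
  if ("project" %in% stages) {
    paths$assay_network <- write_graphml(
      assay_net, file.path(out_dir, "assay_network.graphml"))
    s <- summarize_bipartite(bip)
    paths$bipartite_summary <- write_table(
      data.frame(n_pairs = s$n_pairs,
                 n_assays_active = s$n_assays_active,
                 n_active_compounds = s$n_active_compounds,
                 mean_compounds_per_assay = s$mean_compounds_per_assay,
                 mean_assays_per_compound = s$mean_assays_per_compound),
      file.path(out_dir, "bipartite_summary.tsv"))
  }
  if ("topology" %in% stages) {
    dist <- degree_distribution(assay_net)
    fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
    prof <- clustering_profile(assay_net)
    topo <- data.frame(
      metric = c("n_nodes", "n_edges", "power_law_exponent",
                 "power_law_r", "power_law_r2",
                 "clustering_mean", "clustering_sd", "diameter"),
      value = c(igraph::vcount(assay_net), igraph::ecount(assay_net),
                fit$exponent %||% NA, fit$pearson_r %||% NA,
                fit$r_squared %||% NA,
                prof$overall_mean, prof$overall_sd,
                net_diameter(assay_net)))
    paths$topology <- write_table(topo, file.path(out_dir, "topology.tsv"))
    paths$degree_distribution <- write_table(
      as.data.frame(dist), file.path(out_dir, "degree_distribution.tsv"))
  }
  if ("enrich" %in% stages) {
    seeds_sets <- list(essential = markers$essential,
                       drug_targets = markers$drug_targets,
                       disease_genes = markers$disease_genes)
    bt <- map_symbols(markers$bioassay_targets, ppi)$mapped
    rows <- do.call(rbind, lapply(names(seeds_sets), function(nm) {
      seeds <- map_symbols(seeds_sets[[nm]], ppi)$mapped
      er <- enrichment(ppi, seeds, bt,
                       n_random = config$enrichment$n_random,
                       rng_seed = config$enrichment$rng_seed)
      data.frame(seed_set = nm, distance = er$distances,
                 mean_fraction = er$mean_fraction,
                 random_mean_fraction = er$random_mean_fraction,
                 p_value = er$p_value)
    }))
    paths$enrichment <- write_table(rows,
                                    file.path(out_dir, "enrichment.tsv"))
    log_lines <- c(log_lines,
                   paste("enrichment rng_seed:", config$enrichment$rng_seed),
                   paste("enrichment n_random:", config$enrichment$n_random))
  }
  if ("prioritize" %in% stages) {
    bt <- map_symbols(markers$bioassay_targets, ppi)$mapped
    ess <- map_symbols(markers$essential, ppi)$mapped
    dt <- map_symbols(markers$drug_targets, ppi)$mapped
    rows <- data.frame(gene = bt,
                       d_essential = characteristic_distances(ppi, bt, ess),
                       d_drug = characteristic_distances(ppi, bt, dt),
                       degree = as.integer(igraph::degree(ppi, v = bt)))
    ranked <- prioritize(rows,
                         bin_width = config$prioritize$bin_width,
                         min_degree = config$prioritize$min_degree,
                         exclude = dt)
    paths$priorities <- write_table(ranked,
                                    file.path(out_dir, "priorities.tsv"))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(paths)
}
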
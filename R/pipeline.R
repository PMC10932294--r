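#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_stage()]. The
#' defaults encode the analysis conventions used throughout the package:
#' DEP thresholds (fold change 1.2, adjusted p 0.1, presence fraction 0.5),
#' network construction (confidence 0.7, centrality weights, PageRank
#' damping 0.85, target filter fold change 1.5, top 10), EEG screening
#' (5 s minimum, 3x amplitude, evolution required) and the synthetic-data
#' condition. Unknown keys are rejected.
#'
#' @param overrides Named list (possibly nested) of settings to override.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    inputs = list(abundance = NULL, design = NULL, peptide_map = NULL,
                  annotations = NULL, model = NULL, edges = NULL, eeg = NULL),
    contrast = list(control = "sham", experimental = "pte"),
    dep = list(fc_threshold = 1.2, adj_p_threshold = 0.1,
               presence_fraction = 0.5, log_scale = TRUE, var_equal = FALSE),
    fba = list(proton_metabolite = "h_i", big_bound = 1000),
    network = list(min_confidence = 0.7, damping = 0.85, fc_min = 1.5,
                   top_k = 10,
                   weights = list(degree = 0.28, stress = 0.28,
                                  betweenness = 0.20, closeness = 0.14,
                                  eccentricity = 0.10)),
    eeg = list(min_duration_s = 5, amplitude_ratio = 3,
               require_evolution = TRUE, background_window_s = 10),
    simulate = list(n_proteins = 200, groups = c("sham", "pte"),
                    n_biological = 5, n_technical = 2, noise_sd = 0.2,
                    dropout_rate = 0.05, n_planted = 10,
                    planted_log2fc = 1.5, model_kind = "etc_toy",
                    capacity = 10, ppin_nodes = 40, n_hubs = 2,
                    eeg_duration_s = 120, eeg_fs = 200)
  )
  config <- merge_config(defaults, overrides, path = "")
  with(config$dep, {
    assert_scalar_number(fc_threshold, "dep.fc_threshold", lower = 1)
    assert_scalar_number(adj_p_threshold, "dep.adj_p_threshold", 0, 1)
    assert_scalar_number(presence_fraction, "dep.presence_fraction", 0, 1)
  })
  with(config$network, {
    assert_scalar_number(min_confidence, "network.min_confidence", 0, 1)
    assert_scalar_number(damping, "network.damping", 0, 1)
    assert_scalar_number(fc_min, "network.fc_min", lower = 1)
  })
  with(config$eeg, {
    assert_scalar_number(min_duration_s, "eeg.min_duration_s", lower = 0)
    assert_scalar_number(amplitude_ratio, "eeg.amplitude_ratio", lower = 1)
  })
  config$seed <- assert_count(config$seed, "seed", min = 0L)
  structure(config, class = "pipeline_config")
}

#' @noRd
merge_config <- function(defaults, overrides, path) {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) abort(sprintf("Config section '%s' must be a mapping.", path))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key '%s%s'.", path, unknown[1]))
  }
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror [pipeline_config()] defaults.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run one pipeline stage
#'
#' Executes a stage of the analysis on the files named in
#' `config$inputs`, writes its artifacts as TSV into `out_dir` together
#' with a `manifest_<stage>.json` (inputs, parameter hash, seed, package
#' version), and returns the written paths. Identical config and seed
#' produce identical artifacts. Stages:
#' `"simulate"` (write synthetic fixtures for every other stage),
#' `"deps"` (normalize, roll up, test, call DEPs), `"enrich"`
#' (over-representation of DEPs in annotation sets), `"fba"` (baseline
#' optimization, fold-change constraints, re-optimization, comparison),
#' `"rank"` (network construction, centralities, weighted ranking,
#' PageRank, target selection), `"eeg"` (seizure-candidate screening) and
#' `"all"` (simulate, then every stage on the simulated artifacts).
#'
#' @param stage Stage name.
#' @param config A `pipeline_config` (or list of overrides).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, character vector of written file paths.
#' @export
run_stage <- function(stage, config = pipeline_config(), out_dir = ".") {
  stages <- c("simulate", "deps", "enrich", "fba", "rank", "eeg", "all")
  if (!is.character(stage) || length(stage) != 1L || !stage %in% stages) {
    abort(sprintf("`stage` must be one of: %s.", paste(stages, collapse = ", ")))
  }
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (stage == "all") {
    written <- run_stage("simulate", config, out_dir)
    sim_inputs <- list(
      abundance = file.path(out_dir, "abundance.tsv"),
      design = file.path(out_dir, "design.tsv"),
      model = file.path(out_dir, "model.tsv"),
      edges = file.path(out_dir, "edges.tsv"),
      eeg = file.path(out_dir, "eeg.tsv")
    )
    config$inputs <- modifyList(config$inputs %||% list(), sim_inputs)
    for (s in c("deps", "fba", "rank", "eeg")) {
      written <- c(written, run_stage(s, config, out_dir))
    }
    return(invisible(written))
  }

  written <- switch(
    stage,
    simulate = stage_simulate(config, out_dir),
    deps = stage_deps(config, out_dir),
    enrich = stage_enrich(config, out_dir),
    fba = stage_fba(config, out_dir),
    rank = stage_rank(config, out_dir),
    eeg = stage_eeg(config, out_dir)
  )
  manifest <- list(
    stage = stage,
    inputs = purrr::compact(config$inputs),
    artifacts = basename(written),
    parameter_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package = "ptenet",
    package_version = as.character(utils::packageVersion("ptenet"))
  )
  manifest_path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, manifest_path))
}

#' @noRd
require_input <- function(config, key) {
  path <- config$inputs[[key]]
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf(
      "Stage input '%s' is missing or does not exist (config$inputs$%s = %s).",
      key, key, if (is.null(path)) "NULL" else sprintf("'%s'", path)
    ))
  }
  path
}

#' @noRd
stage_simulate <- function(config, out_dir) {
  sim <- config$simulate
  planted <- if (sim$n_planted > 0) {
    tibble::tibble(
      protein = seq_len(sim$n_planted),
      group = rep(sim$groups[-1][1], sim$n_planted),
      log2fc = rep_len(c(sim$planted_log2fc, -sim$planted_log2fc), sim$n_planted)
    )
  } else {
    NULL
  }
  ab <- simulate_abundance(
    sim$n_proteins, groups = sim$groups, n_biological = sim$n_biological,
    n_technical = sim$n_technical, planted = planted,
    noise_sd = sim$noise_sd, dropout_rate = sim$dropout_rate,
    seed = config$seed
  )
  toy <- simulate_toy_model(sim$model_kind, capacity = sim$capacity,
                            seed = config$seed)
  net <- simulate_ppin(sim$ppin_nodes, "planted_hub", n_hubs = sim$n_hubs,
                       node_ids = sprintf("P%04d",
                                          seq_len(min(sim$ppin_nodes,
                                                      sim$n_proteins))),
                       seed = config$seed)
  eeg <- simulate_eeg(
    sim$eeg_duration_s, fs = sim$eeg_fs,
    events = tibble::tibble(start = sim$eeg_duration_s * 0.4,
                            duration = 10, ratio = 5),
    seed = config$seed
  )
  paths <- file.path(out_dir, c("abundance.tsv", "design.tsv",
                                "truth_proteins.tsv", "model.tsv",
                                "edges.tsv", "truth_hubs.tsv", "eeg.tsv",
                                "truth_eeg.tsv"))
  readr::write_tsv(ab$abundance, paths[1])
  readr::write_tsv(ab$design, paths[2])
  readr::write_tsv(ab$truth, paths[3])
  write_metabolic_model(toy$model, paths[4])
  readr::write_tsv(net$edges, paths[5])
  readr::write_tsv(tibble::tibble(hub = net$truth$hub_nodes), paths[6])
  write_eeg_text(eeg$trace, paths[7])
  readr::write_tsv(eeg$truth, paths[8])
  paths
}

#' @noRd
stage_deps <- function(config, out_dir) {
  abundance <- readr::read_tsv(require_input(config, "abundance"),
                               show_col_types = FALSE)
  design <- readr::read_tsv(require_input(config, "design"),
                            show_col_types = FALSE)
  abundance <- normalize_intensities(abundance)
  if (!is.null(config$inputs$peptide_map)) {
    map <- readr::read_tsv(require_input(config, "peptide_map"),
                           show_col_types = FALSE)
    abundance <- rollup_proteins(abundance, map)
  }
  de <- differential_expression(
    abundance, design,
    control = config$contrast$control,
    experimental = config$contrast$experimental,
    log_scale = config$dep$log_scale, var_equal = config$dep$var_equal
  )
  de <- call_deps(de, config$dep$fc_threshold, config$dep$adj_p_threshold,
                  config$dep$presence_fraction)
  path <- file.path(out_dir, "deps.tsv")
  readr::write_tsv(tidy(de), path)
  path
}

#' @noRd
read_deps_artifact <- function(config, out_dir) {
  path <- config$inputs$deps %||% file.path(out_dir, "deps.tsv")
  if (!file.exists(path)) {
    abort("DEP table not found; run the 'deps' stage first or set inputs$abundance.")
  }
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @noRd
stage_enrich <- function(config, out_dir) {
  deps <- read_deps_artifact(config, out_dir)
  ann_path <- require_input(config, "annotations")
  ann <- readr::read_tsv(ann_path, show_col_types = FALSE)
  if (!all(c("set", "protein") %in% names(ann))) {
    abort("Annotation file needs columns `set`, `protein`.")
  }
  sets <- split(ann$protein, ann$set)
  res <- ora_enrichment(deps$protein[deps$dep], sets, deps$protein)
  path <- file.path(out_dir, "ora.tsv")
  readr::write_tsv(res, path)
  path
}

#' @noRd
stage_fba <- function(config, out_dir) {
  model_path <- require_input(config, "model")
  model <- if (grepl("\\.json$", model_path, ignore.case = TRUE)) {
    read_bigg_model(model_path)
  } else {
    read_metabolic_model(model_path)
  }
  deps <- read_deps_artifact(config, out_dir)
  base <- fba(model, big_bound = config$fba$big_bound)
  if (base$status != "optimal") {
    abort(sprintf("Baseline FBA did not reach optimality (status: %s).",
                  base$status))
  }
  fc <- setNames(deps$fold_change[deps$dep], deps$protein[deps$dep])
  dys <- if (length(fc) > 0) {
    hit <- suppressWarnings(
      apply_fold_change_constraints(model, base, fc, unmatched = "ignore")
    )
    fba(hit, big_bound = config$fba$big_bound)
  } else {
    base
  }
  cmp <- compare_fluxes(base, dys, model)
  paths <- file.path(out_dir, c("fluxes.tsv", "metabolites.tsv"))
  readr::write_tsv(cmp$reactions, paths[1])
  metabolites <- cmp$metabolites
  proton <- config$fba$proton_metabolite
  if (proton %in% metabolites$metabolite) {
    pc <- suppressWarnings(production_change(model, base, dys, proton))
    metabolites <- dplyr::left_join(
      metabolites,
      dplyr::select(pc, "metabolite", "percent_reduction",
                    "percent_reduction_int"),
      by = "metabolite"
    )
  }
  readr::write_tsv(metabolites, paths[2])
  paths
}

#' @noRd
stage_rank <- function(config, out_dir) {
  edges <- read_string_edges(require_input(config, "edges"))
  net <- build_ppin(edges, min_confidence = config$network$min_confidence)
  cent <- compute_centralities(net)
  ranking <- weighted_rank(cent, weights = unlist(config$network$weights))
  pr <- ppin_pagerank(net, damping = config$network$damping)
  paths <- file.path(out_dir, c("ranking.tsv", "targets.tsv"))
  readr::write_tsv(tibble::as_tibble(ranking), paths[1])

  deps_path <- config$inputs$deps %||% file.path(out_dir, "deps.tsv")
  if (file.exists(deps_path)) {
    deps <- readr::read_tsv(deps_path, show_col_types = FALSE)
    fc <- setNames(deps$fold_change, deps$protein)
  } else {
    # Without measured fold changes every node passes the filter trivially.
    fc <- setNames(rep(config$network$fc_min * 2, nrow(ranking)), ranking$node)
  }
  targets <- suppressWarnings(select_targets(
    ranking, fc, pagerank = pr,
    fc_min = config$network$fc_min, top_k = config$network$top_k
  ))
  readr::write_tsv(targets, paths[2])
  paths
}

#' @noRd
stage_eeg <- function(config, out_dir) {
  path_in <- require_input(config, "eeg")
  trace <- if (grepl("\\.edf$", path_in, ignore.case = TRUE)) {
    read_edf(path_in)
  } else {
    read_eeg_text(path_in)
  }
  screen <- detect_seizure_events(
    trace,
    min_duration_s = config$eeg$min_duration_s,
    amplitude_ratio = config$eeg$amplitude_ratio,
    require_evolution = config$eeg$require_evolution,
    background_window_s = config$eeg$background_window_s
  )
  paths <- file.path(out_dir, c("events.tsv", "rejected_events.tsv"))
  readr::write_tsv(tidy(screen), paths[1])
  readr::write_tsv(screen$rejected, paths[2])
  paths
}
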
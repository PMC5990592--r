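#' Load and validate a pipeline run configuration
#'
#' A run configuration is a nested list (or a YAML/JSON file holding
#' one) with optional blocks `input`, `simulate`, `extraction`, `fit`,
#' `clustering`, `stats`, and a top-level `seed`. `input$type` is one of
#' `"simulate"` (default), `"mzml"` (needs `input$mzml_dir` and
#' `input$metadata` CSV) or `"peak_table"` (needs `input$peak_table`
#' long-format CSV). Referenced paths must exist.
#'
#' @param config Path to a YAML or JSON file, or a list.
#' @return Validated config list with defaults filled in.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    input = list(type = "simulate"),
    simulate = list(),
    extraction = list(ppm = 10, rt_pad_min = 0, min_total_area = 0),
    fit = list(),
    clustering = list(k = NULL, k_range = 1:6, seed = 1L, restarts = 25L,
                      t_max = 32, threshold = 0.85),
    stats = list(alpha_variance = 0.05, adjust = "none"),
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
      }
    }
  }
  type <- config$input$type
  if (!type %in% c("simulate", "mzml", "peak_table")) {
    stop("unknown input type: ", type, call. = FALSE)
  }
  for (p in c("mzml_dir", "metadata", "peak_table", "amino_acid_table")) {
    if (!is.null(config$input[[p]]) && !file.exists(config$input[[p]])) {
      stop("configured path does not exist: ", config$input[[p]], call. = FALSE)
    }
  }
  if (type == "mzml" && (is.null(config$input$mzml_dir) || is.null(config$input$metadata))) {
    stop("input type 'mzml' requires input$mzml_dir and input$metadata", call. = FALSE)
  }
  if (type == "peak_table" && is.null(config$input$peak_table)) {
    stop("input type 'peak_table' requires input$peak_table", call. = FALSE)
  }
  config
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA, null = "null")), f)
  unname(tools::md5sum(f))
}

.write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Generate a synthetic fixture bundle
#'
#' Runs the synthetic-data generator under a pipeline configuration and
#' writes the resulting tables (and optionally per-sample mzML files) to
#' disk: `envelopes.csv`, `observations.csv`, `standards.csv`,
#' `metadata.csv`, `truth.csv`, plus `mzml/` when requested.
#'
#' @param config Run configuration (see [read_run_config()]); the
#'   `simulate` block is passed to [sim_config()].
#' @param output_dir Output directory, created if needed.
#' @param write_mzml Also render every sample as mzML.
#' @return Invisibly, the `isokin_sim` object with `$files` listing what
#'   was written.
#' @export
simulate_run <- function(config = list(), output_dir, write_mzml = FALSE) {
  config <- read_run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- do.call(sim_config, config$simulate)
  sim <- simulate_dataset(sc, seed = config$seed)
  files <- c(
    .write_stage_csv(sim$envelopes, output_dir, "envelopes.csv"),
    .write_stage_csv(sim$observations, output_dir, "observations.csv"),
    .write_stage_csv(sim$standards, output_dir, "standards.csv"),
    .write_stage_csv(sim$metadata, output_dir, "metadata.csv"),
    .write_stage_csv(sim$truth, output_dir, "truth.csv"))
  if (write_mzml) {
    idx <- write_mzml_dataset(sim, file.path(output_dir, "mzml"))
    files <- c(files, .write_stage_csv(idx, output_dir, "mzml_index.csv"))
  }
  sim$files <- files
  invisible(sim)
}

#' Run the full labeling-analysis pipeline
#'
#' Orchestrates every stage end-to-end: obtain envelope observations
#' (simulated, extracted from mzML, or read from a peak table), fit the
#' plateau-exponential model per amino acid x condition, estimate pools
#' and flux-dimension quantities, cluster labeling trajectories and flux
#' values per condition, and run the pairwise condition comparisons.
#' Stage outputs are written as CSV; `manifest.json` records the package
#' version, a hash of the configuration, and all seeds, so identical
#' configurations yield identical outputs.
#'
#' @param config Run configuration; see [read_run_config()].
#' @param output_dir Directory for stage outputs.
#' @return Invisibly, a list with the in-memory stage results
#'   (`observations`, `fits`, `pools`, `clusters`, `comparisons`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), output_dir) {
  config <- read_run_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- if (!is.null(config$input$amino_acid_table)) {
    read_amino_acid_table(config$input$amino_acid_table)
  } else {
    amino_acid_specs()
  }
  files <- character(0)

  ## --- stage: input -------------------------------------------------
  stage <- "input"
  res <- tryCatch({
    type <- config$input$type
    if (type == "simulate") {
      sc <- do.call(sim_config, config$simulate)
      sim <- simulate_dataset(sc, seed = config$seed)
      list(observations = sim$observations, sim = sim)
    } else if (type == "mzml") {
      meta <- utils::read.csv(config$input$metadata, stringsAsFactors = FALSE)
      need <- c("sample_id", "path", "condition", "time_h", "replicate")
      miss <- setdiff(need, names(meta))
      if (length(miss)) {
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      meta$path <- ifelse(file.exists(meta$path), meta$path,
                          file.path(config$input$mzml_dir, meta$path))
      ex <- extract_envelopes(meta, specs,
                              ppm_tol = config$extraction$ppm,
                              rt_pad_min = config$extraction$rt_pad_min,
                              min_total_area = config$extraction$min_total_area)
      list(observations = ex$observations, envelopes = ex$envelopes)
    } else {
      env <- utils::read.csv(config$input$peak_table, stringsAsFactors = FALSE)
      need <- c("sample_id", "code", "condition", "time_h", "replicate",
                "n_label", "area")
      miss <- setdiff(need, names(env))
      if (length(miss)) {
        stop("peak table is missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      list(observations = envelope_observations(
        env, config$extraction$min_total_area), envelopes = env)
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  obs <- res$observations
  files <- c(files, .write_stage_csv(obs, output_dir, "observations.csv"))

  ## --- stage: fit ---------------------------------------------------
  stage <- "fit"
  windows <- if (!is.null(config$fit$windows)) {
    as.data.frame(config$fit$windows)
  } else NULL
  fits <- tryCatch(fit_all(obs, specs, windows), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  files <- c(files, .write_stage_csv(fits, output_dir, "fits.csv"))

  ## --- stage: pools -------------------------------------------------
  stage <- "pools"
  pools <- NULL; pool_reps <- NULL
  if (!is.null(res$sim)) {
    pool_reps <- pool_replicates(res$sim$observations, res$sim$standards,
                                 res$sim$metadata)
    pools <- pool_table(pool_reps, fits)
    files <- c(files,
               .write_stage_csv(pool_reps, output_dir, "pool_replicates.csv"),
               .write_stage_csv(pools, output_dir, "pools.csv"))
  }

  ## --- stage: cluster -----------------------------------------------
  stage <- "cluster"
  cl_cfg <- config$clustering
  clusters <- list()
  for (cond in unique(obs$condition)) {
    mat <- build_feature_matrix(obs[obs$condition == cond, ],
                                t_max = cl_cfg$t_max)
    if (nrow(mat) < 2) next
    k <- cl_cfg$k
    if (is.null(k)) {
      k <- select_k(mat, k_range = cl_cfg$k_range, seed = cl_cfg$seed,
                    n_restarts = cl_cfg$restarts,
                    threshold = cl_cfg$threshold)
    }
    k <- min(k, nrow(mat))
    cr <- kmeans_hw(mat, k, seed = cl_cfg$seed, n_restarts = cl_cfg$restarts)
    models <- fit_cluster_models(obs[obs$condition == cond, ], cr)
    assign_df <- data.frame(condition = cond,
                            code = names(cr$assignments),
                            cluster = as.integer(cr$assignments),
                            stringsAsFactors = FALSE)
    clusters[[cond]] <- list(result = cr, models = models,
                             assignments = assign_df)
    files <- c(files,
               .write_stage_csv(assign_df, output_dir,
                                paste0("cluster_assignments_", cond, ".csv")),
               .write_stage_csv(cbind(condition = cond, models),
                                output_dir,
                                paste0("cluster_models_", cond, ".csv")))
    if (!is.null(pools)) {
      fx <- pools[pools$condition == cond & !is.na(pools$flux), ]
      if (nrow(fx) >= 2) {
        fr <- cluster_flux(stats::setNames(fx$flux, fx$code),
                           condition = cond, seed = cl_cfg$seed,
                           n_restarts = cl_cfg$restarts)
        clusters[[cond]]$flux_result <- fr
        files <- c(files, .write_stage_csv(
          data.frame(condition = cond, code = names(fr$assignments),
                     cluster = as.integer(fr$assignments),
                     stringsAsFactors = FALSE),
          output_dir, paste0("cluster_flux_", cond, ".csv")))
      }
    }
  }

  ## --- stage: compare -----------------------------------------------
  stage <- "compare"
  comparisons <- NULL
  if (!is.null(pool_reps)) {
    reps <- merge(pool_reps, fits[, c("code", "condition", "k", "c")],
                  by = c("code", "condition"), all.x = TRUE)
    reps$p_active <- active_pool(reps$p_initial, ifelse(is.na(reps$c), NA, reps$c))
    reps$flux <- flux(ifelse(is.na(reps$k), NA, reps$k), reps$p_initial)
    reps$flux_active <- flux(ifelse(is.na(reps$k), NA, reps$k), reps$p_active)
    comparisons <- run_all_comparisons(
      reps, quantities = c("p_initial", "p_active", "flux", "flux_active"),
      alpha_variance = config$stats$alpha_variance,
      adjust = config$stats$adjust)
    if (!is.null(comparisons)) {
      files <- c(files, .write_stage_csv(comparisons, output_dir,
                                         "comparisons.csv"))
    }
  }

  ## --- manifest -----------------------------------------------------
  manifest <- list(
    package = "isokin",
    version = as.character(utils::packageVersion("isokin")),
    config_hash = .config_hash(config),
    seed = config$seed,
    clustering_seed = config$clustering$seed,
    outputs = basename(files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(observations = obs, fits = fits, pools = pools,
                 pool_replicates = pool_reps, clusters = clusters,
                 comparisons = comparisons, manifest = manifest,
                 files = c(files, file.path(output_dir, "manifest.json"))))
}
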
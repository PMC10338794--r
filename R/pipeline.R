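#' Pipeline run configuration
#'
#' Bundles every stage's parameters with defaults matching the analysis'
#' standard values: sparsity 0.12-0.40 step 0.01, 1000 null networks,
#' 10000 permutations, exclusion at 3 mm translation / 0.5 mm mean FD,
#' FDR at q < .05.
#'
#' @param input_dir Cohort directory ([write_cohort()] layout); `NULL` to
#'   simulate a cohort from `cohort` instead.
#' @param cohort Optional [cohort_spec()] used when `input_dir` is `NULL`.
#' @param output_dir Directory for stage outputs and the report.
#' @param s_min,s_max,s_step Sparsity grid parameters.
#' @param n_nulls Null networks per sparsity level.
#' @param n_perm Permutations per group test.
#' @param band Passband (Hz) for the joint nuisance + filter design.
#' @param global_signal Include a global-signal column built from the mean
#'   regional series (default `TRUE`).
#' @param max_translation_mm,max_mean_fd_mm Motion exclusion thresholds.
#' @param q_level FDR level.
#' @param clinical_vars,covariates Column names used by
#'   [run_group_analysis()].
#' @param correlation_group Group whose subjects enter the behavior
#'   correlations (default `"B"`, the cohort generator's patient-like
#'   group).
#' @param nodal Compute nodal metrics (default `TRUE`).
#' @param seed Master seed for every stochastic stage.
#' @param cache Reuse stage outputs on rerun when config and inputs are
#'   unchanged (default `TRUE`).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL,
                            output_dir = tempfile("cerenet_run_"),
                            s_min = 0.12, s_max = 0.40, s_step = 0.01,
                            n_nulls = 1000, n_perm = 10000,
                            band = c(0.01, 0.08), global_signal = TRUE,
                            max_translation_mm = 3, max_mean_fd_mm = 0.5,
                            q_level = 0.05,
                            clinical_vars = "score",
                            covariates = c("age", "sex", "education",
                                           "mean_fd"),
                            correlation_group = "B",
                            nodal = TRUE, seed = 1L, cache = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `errors` and `warnings` (character
#'   vectors); errors raise a condition unless `stop_on_error = FALSE`.
#' @param stop_on_error Raise on errors (default `TRUE`).
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  errors <- character(0); warnings <- character(0)
  if (config$s_step <= 0) errors <- c(errors, "s_step must be > 0")
  if (config$s_min <= 0 || config$s_max > 1 || config$s_max < config$s_min)
    errors <- c(errors, "need 0 < s_min <= s_max <= 1")
  if (config$n_nulls < 1) errors <- c(errors, "n_nulls must be >= 1")
  if (config$n_perm < 100) errors <- c(errors, "n_perm must be >= 100")
  if (length(config$band) != 2 || config$band[1] < 0 ||
      config$band[2] <= config$band[1])
    errors <- c(errors, "band must be c(low, high) with 0 <= low < high")
  if (config$q_level <= 0 || config$q_level >= 1)
    errors <- c(errors, "q_level must be in (0, 1)")
  if (is.null(config$input_dir) && is.null(config$cohort))
    errors <- c(errors, "either input_dir or cohort must be given")
  if (config$n_nulls < 1000 && config$n_nulls >= 1)
    warnings <- c(warnings, paste0("n_nulls = ", config$n_nulls,
                                   " is below the standard 1000"))
  if (config$n_perm < 10000 && config$n_perm >= 100)
    warnings <- c(warnings, paste0("n_perm = ", config$n_perm,
                                   " is below the standard 10000"))
  if (length(errors) > 0 && stop_on_error)
    stop("invalid config:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  invisible(list(errors = errors, warnings = warnings))
}

config_hash <- function(config, keys) {
  sub <- config[sort(intersect(keys, names(config)))]
  paste(utils::capture.output(utils::str(sub, digits.d = 12)),
        collapse = "\n")
}

cache_valid <- function(path, hash_path, hash) {
  file.exists(path) && file.exists(hash_path) &&
    identical(readLines(hash_path, warn = FALSE) |>
                paste(collapse = "\n"), hash)
}

#' Run the full connectome pipeline
#'
#' Orchestrates cohort loading (or simulation), motion screening and
#' exclusion, joint nuisance regression + band-pass filtering,
#' connectivity, the sparsity sweep with null-normalized metrics and AUCs,
#' and the permutation/FDR/partial-correlation analysis. Stage outputs are
#' written under `config$output_dir` as delimited text and are reused on
#' rerun when the relevant config is unchanged.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `metric_table`, `analysis`
#'   (a [run_group_analysis()] result), `excluded` (data frame of excluded
#'   subjects and reasons), `output_dir`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  t0 <- Sys.time()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  logf("pipeline start; seed =", config$seed)

  # stage 1: cohort
  if (is.null(config$input_dir)) {
    cohort_dir <- file.path(config$output_dir, "cohort")
    hash <- config_hash(config, c("cohort", "seed"))
    hpath <- file.path(config$output_dir, "cohort.hash")
    if (!(config$cache && cache_valid(file.path(cohort_dir, "manifest.tsv"),
                                      hpath, hash))) {
      spec <- config$cohort
      spec$seed <- as.integer(config$seed)
      write_cohort(simulate_cohort(spec), cohort_dir)
      writeLines(hash, hpath)
      logf("cohort simulated:", spec$n_group_a + spec$n_group_b, "subjects")
    } else logf("cohort stage: cache hit")
    config$input_dir <- cohort_dir
  }
  manifest <- read_manifest(config$input_dir)
  tr <- if (!is.null(config$cohort)) config$cohort$tr_seconds else 2

  # stage 2: prep (motion screening + cleaning) and
  # stage 3-4: connectivity, metrics profile
  metrics_path <- file.path(config$output_dir, "metric_table.tsv")
  hash <- config_hash(config, c("input_dir", "band", "global_signal",
                                "max_translation_mm", "max_mean_fd_mm",
                                "s_min", "s_max", "s_step", "n_nulls",
                                "nodal", "seed", "cohort"))
  hpath <- file.path(config$output_dir, "metric_table.hash")
  excluded <- data.frame(subject_id = character(0), reason = character(0))
  if (config$cache && cache_valid(metrics_path, hpath, hash)) {
    logf("prep/metrics stages: cache hit")
    tab <- read.delim(metrics_path, stringsAsFactors = FALSE)
    excl_path <- file.path(config$output_dir, "excluded.tsv")
    if (file.exists(excl_path))
      excluded <- read.delim(excl_path, stringsAsFactors = FALSE)
  } else {
    grid <- sparsity_grid(config$s_min, config$s_max, config$s_step)
    profiles <- list(); kept <- logical(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$subject_id[i]
      subj <- read_subject(config$input_dir, id, tr_seconds = tr)
      ms <- framewise_displacement(
        subj$motion, max_translation_mm = config$max_translation_mm,
        max_mean_fd_mm = config$max_mean_fd_mm)
      if (ms$excluded) {
        excluded <- rbind(excluded,
                          data.frame(subject_id = id,
                                     reason = ms$exclusion_reason))
        logf("excluded", id, ":", ms$exclusion_reason)
        next
      }
      tissue <- if (config$global_signal)
        matrix(rowMeans(subj$series$data), ncol = 1,
               dimnames = list(NULL, "global")) else NULL
      design <- build_nuisance_design(subj$motion, tissue = tissue,
                                      tr = tr, band = config$band)
      clean <- clean_timeseries(subj$series, design)
      conn <- pearson_connectivity(clean)
      set.seed((as.integer(config$seed) * 100 + i) %% 2147483647)
      profiles[[id]] <- profile_subject(conn, grid,
                                        n_nulls = config$n_nulls,
                                        nodal = config$nodal)
      kept[i] <- TRUE
    }
    if (sum(kept) < 4) stop("fewer than 4 subjects survive exclusion",
                            call. = FALSE)
    manifest_kept <- manifest[kept, , drop = FALSE]
    tab <- metric_table(profiles[manifest_kept$subject_id], manifest_kept)
    write.table(tab, metrics_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(excluded, file.path(config$output_dir, "excluded.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(hash, hpath)
    logf("metrics stage done:", nrow(tab), "subjects kept,",
         nrow(excluded), "excluded")
    # reread so fresh and cached runs feed bit-identical values downstream
    tab <- read.delim(metrics_path, stringsAsFactors = FALSE)
  }

  # stage 5: group statistics
  analysis <- run_group_analysis(
    tab, clinical_vars = config$clinical_vars,
    covariates = config$covariates, n_perm = config$n_perm,
    seed = config$seed, q_level = config$q_level,
    correlation_group = config$correlation_group)
  write.table(analysis$permutation,
              file.path(config$output_dir, "permutation_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(analysis$correlations,
              file.path(config$output_dir, "correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # report
  report <- c(
    sprintf("cerenet pipeline report (seed %d)", as.integer(config$seed)),
    sprintf("subjects analyzed: %d; excluded: %d", nrow(tab),
            nrow(excluded)),
    if (nrow(excluded) > 0)
      paste("  excluded:", excluded$subject_id, "-", excluded$reason),
    sprintf("sparsity grid: %.2f-%.2f step %.2f; %d nulls; %d permutations",
            config$s_min, config$s_max, config$s_step, config$n_nulls,
            config$n_perm),
    sprintf("FDR-significant global metrics: %s",
            paste(analysis$permutation$metric[
              analysis$permutation$significant &
                analysis$permutation$family == "global"],
              collapse = ", ") |> (\(x) if (nzchar(x)) x else "none")()),
    sprintf("FDR-significant nodal metrics: %d",
            sum(analysis$permutation$significant &
                  analysis$permutation$family == "nodal")))
  writeLines(report, file.path(config$output_dir, "report.txt"))
  logf("pipeline done in",
       round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), "s")
  structure(list(metric_table = tab, analysis = analysis,
                 excluded = excluded, output_dir = config$output_dir),
            class = "pipeline_result")
}
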
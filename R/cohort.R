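#' Specify a synthetic two-group cohort
#'
#' Defines the generative model for a validation cohort: two groups of
#' subjects whose regional time series are drawn from zero-mean multivariate
#' Gaussians with block (modular) correlation structure, band-pass filtered
#' to the BOLD low-frequency band, plus random-walk head-motion traces and
#' clinical scores linked to each subject's latent network structure.
#'
#' The group difference is carried entirely by the within-module
#' correlation targets `within_module_corr_a/b`: raising the within-module
#' correlation strengthens local clustering relative to degree-matched
#' random networks, which is the kind of effect the downstream pipeline is
#' designed to detect (a higher normalized clustering coefficient).
#'
#' @param n_group_a,n_group_b Subjects per group (>= 2 each for inference).
#' @param n_rois Number of regions (default 28, a cerebellar parcellation).
#' @param n_timepoints Retained volumes per subject (default 235).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param n_modules Number of covariance blocks (default 4).
#' @param within_module_corr_a,within_module_corr_b Target within-block
#'   correlation per group, in `[0, 1)`.
#' @param between_module_corr Target off-block correlation; must be
#'   `>= 0` and `< ` both within-module targets.
#' @param band Passband in Hz, length-2 (default `c(0.01, 0.08)`); `NULL`
#'   disables filtering.
#' @param motion_sd_mm,motion_sd_deg SD of per-volume motion increments
#'   (random-walk model), in mm and degrees.
#' @param subject_corr_sd SD of the per-subject jitter around the group's
#'   within-module correlation target (gives subjects an individual latent
#'   network strength, which clinical scores can track).
#' @param clinical_effect Slope linking a subject's latent within-module
#'   correlation to its simulated clinical score.
#' @param noise_sd SD of the clinical-score noise.
#' @param age_range,education_range Uniform ranges for covariates (years);
#'   education is drawn on integers.
#' @param sex_prob Bernoulli probability of sex = 1.
#' @param seed Master seed; per-subject child seeds are derived as
#'   `seed * 10000 + subject index` so any subject is reproducible alone.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 40, n_group_b = 40,
                        n_rois = 28, n_timepoints = 235, tr_seconds = 2,
                        n_modules = 4,
                        within_module_corr_a = 0.35,
                        within_module_corr_b = 0.55,
                        between_module_corr = 0.10,
                        band = c(0.01, 0.08),
                        motion_sd_mm = 0.02, motion_sd_deg = 0.02,
                        subject_corr_sd = 0.05,
                        clinical_effect = 20, noise_sd = 1,
                        age_range = c(25, 65), sex_prob = 0.5,
                        education_range = c(9, 19),
                        seed = 1L) {
  stopifnot(n_rois >= 2, n_timepoints >= 3, tr_seconds > 0,
            n_modules >= 1, n_modules <= n_rois)
  for (w in c(within_module_corr_a, within_module_corr_b)) {
    if (!(w < 1 && w > between_module_corr || (w == 0 && between_module_corr == 0)))
      stop("within-module correlations must satisfy 1 > within > between >= 0",
           call. = FALSE)
  }
  if (between_module_corr < 0 || between_module_corr >= 1)
    stop("between_module_corr must be in [0, 1)", call. = FALSE)
  if (!is.null(band)) {
    stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  }
  if (n_timepoints < n_rois)
    warning("n_timepoints < n_rois: sample correlation matrices will be ",
            "rank-deficient", call. = FALSE)
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
    within_module_corr_a = within_module_corr_a,
    within_module_corr_b = within_module_corr_b,
    between_module_corr = between_module_corr,
    band = band, motion_sd_mm = motion_sd_mm, motion_sd_deg = motion_sd_deg,
    subject_corr_sd = subject_corr_sd,
    clinical_effect = clinical_effect, noise_sd = noise_sd,
    age_range = age_range, sex_prob = sex_prob,
    education_range = education_range,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_group_a, "+", x$n_group_b, "subjects,",
      x$n_rois, "ROIs x", x$n_timepoints, "timepoints (TR", x$tr_seconds,
      "s)\n")
  cat("  within-module r:", x$within_module_corr_a, "(A) vs",
      x$within_module_corr_b, "(B); between-module r:",
      x$between_module_corr, "\n")
  invisible(x)
}

# ROIs 1..n assigned to modules in contiguous, near-equal blocks
module_assignment <- function(n_rois, n_modules) {
  sort(rep_len(seq_len(n_modules), n_rois))
}

# Minimal off-diagonal shrinkage restoring positive-definiteness.
# Eigenvalues of I + s*(Sigma - I) are 1 + s*(lambda_i - 1), linear in s,
# so the largest admissible s has closed form.
repair_pd <- function(sigma, min_eig = 1e-6) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  if (lmin >= min_eig) return(sigma)
  s <- (1 - min_eig) / (1 - lmin)
  if (!is.finite(s) || s <= 0)
    stop("covariance cannot be repaired to positive definite", call. = FALSE)
  out <- diag(nrow(sigma)) + s * (sigma - diag(nrow(sigma)))
  ev2 <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev2 < min_eig / 2)
    stop("covariance repair failed (min eigenvalue ", format(ev2),
         "); offending within/between correlations too extreme",
         call. = FALSE)
  out
}

#' Block (modular) correlation matrix for one group
#'
#' Builds the N x N population correlation matrix with unit diagonal,
#' `within` on same-module pairs and `between` elsewhere, then enforces
#' positive-definiteness by minimal off-diagonal shrinkage if needed
#' (with valid targets the matrix is already PD and is returned unchanged).
#'
#' @param spec A [cohort_spec()].
#' @param group `"A"` or `"B"` (selects the within-module target).
#' @param within Optional override of the within-module correlation, used
#'   for per-subject latent structure.
#' @return N x N symmetric positive-definite matrix.
#' @export
make_block_covariance <- function(spec, group = c("A", "B"), within = NULL) {
  group <- match.arg(group)
  w <- within %||%
    if (group == "A") spec$within_module_corr_a else spec$within_module_corr_b
  n <- spec$n_rois
  mod <- module_assignment(n, spec$n_modules)
  same <- outer(mod, mod, "==")
  sigma <- ifelse(same, w, spec$between_module_corr)
  diag(sigma) <- 1
  repair_pd(sigma)
}

# Orthonormal DCT-II basis columns k (frequencies k / (2 * T * TR)).
# Returns T x length(k) matrix.
dct_columns <- function(t, k) {
  if (length(k) == 0) return(matrix(0, t, 0))
  tt <- seq_len(t) - 0.5
  b <- vapply(k, function(kk) {
    col <- cos(pi * kk * tt / t)
    if (kk == 0) col / sqrt(t) else col * sqrt(2 / t)
  }, numeric(t))
  matrix(b, nrow = t)
}

# indices k = 1..T-1 whose frequency k/(2*T*TR) lies inside [band]
dct_k_in_band <- function(t, tr, band) {
  k <- seq_len(t - 1)
  f <- k / (2 * t * tr)
  k[f >= band[1] & f <= band[2]]
}

# Band-pass via projection onto the in-band orthonormal DCT components;
# removes the mean (k = 0 lies below any passband with band[1] > 0).
bandpass_dct <- function(x, tr, band) {
  x <- as.matrix(x)
  k <- dct_k_in_band(nrow(x), tr, band)
  b <- dct_columns(nrow(x), k)
  b %*% crossprod(b, x)
}

#' Simulate one subject's time series, motion trace, and clinical scores
#'
#' Draws a T x N zero-mean Gaussian series with the subject's block
#' correlation structure (the group target plus per-subject jitter), applies
#' the band-pass filter so spectra resemble cleaned BOLD, simulates a
#' 6-parameter random-walk motion trace, and generates a clinical score as
#' `clinical_effect * latent within-module correlation + noise`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"A"` or `"B"`.
#' @param subject_seed Integer seed; the same `(spec, group, subject_seed)`
#'   reproduces the subject bit-for-bit.
#' @param subject_id Identifier stored on the series (default derived from
#'   the seed).
#' @return A list of class `synthetic_subject` with elements `series`
#'   (a [roi_timeseries()]), `motion` (T x 6 matrix), `group`,
#'   `true_scores`, and `ground_truth` (module assignment and the latent
#'   and target correlations, sufficient to rebuild the covariance).
#' @export
simulate_subject <- function(spec, group = c("A", "B"), subject_seed,
                             subject_id = NULL) {
  group <- match.arg(group)
  if (spec$n_timepoints < 3)
    stop("need at least 3 timepoints to define correlations", call. = FALSE)
  set.seed(as.integer(subject_seed %% 2147483647))
  target <- if (group == "A") spec$within_module_corr_a else
    spec$within_module_corr_b
  lo <- spec$between_module_corr
  latent <- target + rnorm(1, 0, spec$subject_corr_sd)
  latent <- min(max(latent, lo + 0.01 * (target > lo)), 0.97)
  sigma <- make_block_covariance(spec, group, within = latent)
  x <- MASS::mvrnorm(spec$n_timepoints, mu = rep(0, spec$n_rois),
                     Sigma = sigma)
  if (!is.null(spec$band))
    x <- bandpass_dct(x, spec$tr_seconds, spec$band)
  region_names <- sprintf("ROI%02d", seq_len(spec$n_rois))
  colnames(x) <- region_names
  motion <- apply(matrix(rnorm(spec$n_timepoints * 6, 0,
                               rep(c(spec$motion_sd_mm, spec$motion_sd_deg),
                                   each = 3 * spec$n_timepoints)),
                         ncol = 6), 2, cumsum)
  motion <- sweep(motion, 2, motion[1, ]) # reference = first volume
  colnames(motion) <- c("dx_mm", "dy_mm", "dz_mm",
                        "pitch_deg", "roll_deg", "yaw_deg")
  score <- spec$clinical_effect * latent + rnorm(1, 0, spec$noise_sd)
  subject_id <- subject_id %||% sprintf("sub-%09d", as.integer(subject_seed))
  out <- list(
    series = roi_timeseries(x, tr_seconds = spec$tr_seconds,
                            region_names = region_names,
                            subject_id = subject_id),
    motion = motion,
    group = group,
    true_scores = c(score = score),
    ground_truth = list(modules = module_assignment(spec$n_rois,
                                                    spec$n_modules),
                        target_within = target,
                        latent_within = latent,
                        between = spec$between_module_corr))
  class(out) <- "synthetic_subject"
  out
}

#' Simulate a full two-group cohort with manifest
#'
#' Generates `n_group_a + n_group_b` subjects via [simulate_subject()]
#' (child seeds `seed * 10000 + index`) and a manifest with group labels,
#' covariates (age uniform, sex Bernoulli, education uniform integers,
#' drawn group-independently as in a matched design), mean framewise
#' displacement, and clinical scores.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort`: `subjects` (list of
#'   [simulate_subject()] results) and `manifest` (data frame).
#' @seealso [write_cohort()] to serialize to the pipeline's input formats.
#' @export
simulate_cohort <- function(spec) {
  if (spec$n_group_a < 2 || spec$n_group_b < 2)
    stop("each group needs at least 2 subjects for group inference",
         call. = FALSE)
  n <- spec$n_group_a + spec$n_group_b
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    child <- (spec$seed * 10000 + i) %% 2147483647
    id <- sprintf("sub-%03d", i)
    subjects[[i]] <- simulate_subject(spec, groups[i], child, subject_id = id)
    set.seed((child + 5000) %% 2147483647) # covariates, separate stream
    fd <- framewise_displacement(subjects[[i]]$motion)
    rows[[i]] <- data.frame(
      subject_id = id,
      group = groups[i],
      age = runif(1, spec$age_range[1], spec$age_range[2]),
      sex = rbinom(1, 1, spec$sex_prob),
      education = sample(seq(spec$education_range[1],
                             spec$education_range[2]), 1),
      mean_fd = fd$mean_fd,
      score = unname(subjects[[i]]$true_scores["score"]),
      stringsAsFactors = FALSE)
  }
  out <- list(subjects = subjects, manifest = do.call(rbind, rows),
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a cohort to delimited text files
#'
#' Serializes each subject's time series (`<id>_timeseries.tsv`, T rows x N
#' named columns) and motion trace (`<id>_motion.tsv`, 6 columns), the
#' cohort manifest (`manifest.tsv`), and a machine-readable ground-truth
#' sidecar (`ground_truth.json`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_write <- function(d, path) {
    d <- as.data.frame(d)
    d[] <- lapply(d, function(col) if (is.numeric(col))
      formatC(col, digits = 10, format = "g") else col)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (s in cohort$subjects) {
    id <- s$series$subject_id
    fmt_write(s$series$data, file.path(dir, paste0(id, "_timeseries.tsv")))
    fmt_write(s$motion, file.path(dir, paste0(id, "_motion.tsv")))
  }
  fmt_write(cohort$manifest, file.path(dir, "manifest.tsv"))
  gt <- list(
    spec = unclass(cohort$spec),
    subjects = lapply(cohort$subjects, function(s)
      list(subject_id = s$series$subject_id, group = s$group,
           latent_within = s$ground_truth$latent_within,
           target_within = s$ground_truth$target_within,
           modules = s$ground_truth$modules)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one subject's time series and motion trace from a cohort directory
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time to attach to the series.
#' @return List with `series` ([roi_timeseries()]) and `motion` (matrix).
#' @export
read_subject <- function(dir, subject_id, tr_seconds = 2) {
  d <- as.matrix(read.delim(file.path(
    dir, paste0(subject_id, "_timeseries.tsv")), check.names = FALSE))
  m <- as.matrix(read.delim(file.path(
    dir, paste0(subject_id, "_motion.tsv")), check.names = FALSE))
  list(series = roi_timeseries(d, tr_seconds = tr_seconds,
                               region_names = colnames(d),
                               subject_id = subject_id),
       motion = m)
}

#' Read a cohort manifest
#' @param dir Cohort directory written by [write_cohort()].
#' @return Data frame with one row per subject.
#' @export
read_manifest <- function(dir) {
  read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
}
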
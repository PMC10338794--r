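spec_small <- function(...) {
  cohort_spec(n_group_a = 3, n_group_b = 3, n_rois = 8, n_timepoints = 60,
              n_modules = 2, seed = 5, ...)
}

test_that("block covariance reproduces the requested structure", {
  # zero correlation everywhere -> identity
  sp0 <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 6,
                     within_module_corr_a = 0, within_module_corr_b = 0,
                     between_module_corr = 0, n_modules = 2, seed = 1)
  expect_equal(make_block_covariance(sp0, "A"), diag(6))

  # 2 modules of 2 ROIs: 0.6 within, 0.1 between, PD by eigendecomposition
  sp <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 4, n_modules = 2,
                    within_module_corr_a = 0.6, within_module_corr_b = 0.6,
                    between_module_corr = 0.1, seed = 1)
  sigma <- make_block_covariance(sp, "A")
  expect_equal(diag(sigma), rep(1, 4))
  expect_equal(sigma[1, 2], 0.6)
  expect_equal(sigma[3, 4], 0.6)
  expect_equal(sigma[1, 3], 0.1)
  expect_equal(sigma, t(sigma))
  expect_gt(min(eigen(sigma, symmetric = TRUE)$values), 0)

  # near-degenerate compound-symmetry-like request stays PD
  sp2 <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 10,
                     n_modules = 2, within_module_corr_a = 0.9,
                     within_module_corr_b = 0.9,
                     between_module_corr = 0.89, seed = 1)
  sigma2 <- make_block_covariance(sp2, "B")
  expect_gt(min(eigen(sigma2, symmetric = TRUE)$values), 0)
})

test_that("positive-definiteness repair shrinks a bad matrix minimally", {
  bad <- matrix(0.99, 3, 3)
  bad[1, 2] <- bad[2, 1] <- -0.99
  diag(bad) <- 1 # min eigenvalue is negative
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- cerenet:::repair_pd(bad)
  ev <- eigen(fixed, symmetric = TRUE)$values
  expect_gte(min(ev), 1e-6 - 1e-12)
  # shrinkage is the minimal one: smallest eigenvalue lands on the floor
  expect_lt(min(ev), 1e-4)
  expect_equal(diag(fixed), rep(1, 3))
})

test_that("invalid cohort parameters are rejected and T < N warns", {
  expect_error(cohort_spec(within_module_corr_a = 0.2,
                           between_module_corr = 0.3), "within > between")
  expect_error(cohort_spec(between_module_corr = -0.1))
  expect_warning(cohort_spec(n_rois = 28, n_timepoints = 20, seed = 1),
                 "rank-deficient")
  expect_error(simulate_cohort(cohort_spec(n_group_a = 1, n_group_b = 5)),
               "at least 2")
})

test_that("subject simulation is bit-reproducible from its seeds", {
  sp <- spec_small()
  s1 <- simulate_subject(sp, "B", 1234)
  s2 <- simulate_subject(sp, "B", 1234)
  expect_identical(s1$series$data, s2$series$data)
  expect_identical(s1$motion, s2$motion)
  expect_identical(s1$true_scores, s2$true_scores)
  s3 <- simulate_subject(sp, "B", 1235)
  expect_false(identical(s1$series$data, s3$series$data))
})

test_that("zero motion SD gives an identically-zero trace and zero FD", {
  sp <- spec_small(motion_sd_mm = 0, motion_sd_deg = 0)
  s <- simulate_subject(sp, "A", 99)
  expect_true(all(s$motion == 0))
  fd <- framewise_displacement(s$motion)
  expect_equal(fd$mean_fd, 0)
  expect_false(fd$excluded)
})

test_that("empirical correlations converge to the block target at large T", {
  # unfiltered: plain Gaussian sampling must hit the target entrywise
  sp <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 8,
                    n_timepoints = 10000, n_modules = 2,
                    within_module_corr_a = 0.5, within_module_corr_b = 0.5,
                    between_module_corr = 0.1, band = NULL,
                    subject_corr_sd = 0, seed = 3)
  s <- simulate_subject(sp, "A", 31)
  target <- make_block_covariance(sp, "A")
  expect_lt(max(abs(cor(s$series$data) - target)), 0.05)
})

test_that("filtered series match a Monte-Carlo oracle that includes the filter", {
  # oracle: independent draw + an independently coded DCT band projection
  sp <- cohort_spec(n_group_a = 2, n_group_b = 2, n_rois = 8,
                    n_timepoints = 10000, n_modules = 2,
                    within_module_corr_a = 0.6, within_module_corr_b = 0.6,
                    between_module_corr = 0.0, subject_corr_sd = 0, seed = 3)
  s <- simulate_subject(sp, "A", 7)
  mod <- s$ground_truth$modules
  same <- outer(mod, mod, "==") & upper.tri(diag(8))
  emp_within <- mean(cor(s$series$data)[same])

  set.seed(4242)
  tt <- sp$n_timepoints
  sigma <- make_block_covariance(sp, "A")
  x <- matrix(rnorm(tt * 8), tt, 8) %*% chol(sigma)
  k <- seq_len(tt - 1)
  f <- k / (2 * tt * sp$tr_seconds)
  keep <- k[f >= 0.01 & f <= 0.08]
  grid_t <- seq_len(tt) - 0.5
  basis <- sapply(keep, function(kk) sqrt(2 / tt) * cos(pi * kk * grid_t / tt))
  xf <- basis %*% crossprod(basis, x)
  oracle_within <- mean(cor(xf)[same])
  expect_lt(abs(emp_within - oracle_within), 0.05)
})

test_that("cohort manifest covers both groups with covariates in range", {
  sp <- spec_small()
  co <- simulate_cohort(sp)
  expect_length(co$subjects, 6)
  expect_equal(nrow(co$manifest), 6)
  expect_setequal(unique(co$manifest$group), c("A", "B"))
  expect_true(all(co$manifest$age >= sp$age_range[1] &
                    co$manifest$age <= sp$age_range[2]))
  expect_true(all(co$manifest$sex %in% 0:1))
  expect_true(all(co$manifest$education == round(co$manifest$education)))
})

test_that("written cohorts are byte-identical across reruns and round-trip", {
  sp <- spec_small()
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(simulate_cohort(sp), d1)
  write_cohort(simulate_cohort(sp), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  man <- read_manifest(d1)
  s1 <- read_subject(d1, man$subject_id[1], tr_seconds = sp$tr_seconds)
  orig <- simulate_cohort(sp)$subjects[[1]]
  expect_equal(s1$series$data, orig$series$data, tolerance = 1e-8)
  expect_equal(unname(s1$motion), unname(orig$motion), tolerance = 1e-8)
})

test_that("clinical scores track the latent network strength", {
  sp <- cohort_spec(n_group_a = 30, n_group_b = 30, n_rois = 8,
                    n_timepoints = 40, n_modules = 2, noise_sd = 0.01,
                    seed = 17)
  co <- simulate_cohort(sp)
  latent <- vapply(co$subjects, function(s) s$ground_truth$latent_within,
                   numeric(1))
  score <- co$manifest$score
  expect_gt(cor(latent, score), 0.95)
})
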
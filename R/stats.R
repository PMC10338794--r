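# two-sample T statistics (first level minus second) for a matrix of
# group assignments; pooled-variance by default, Welch optionally.
# values: numeric vector; gmat: logical matrix (n_perm x n), TRUE = group 1
t_stats_for_labels <- function(values, gmat, n1, n2, var_equal = TRUE) {
  s1 <- gmat %*% values
  q1 <- gmat %*% values^2
  st <- sum(values); qt <- sum(values^2)
  m1 <- s1 / n1
  m2 <- (st - s1) / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (qt - q1 - n2 * m2^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  }
}

#' Nonparametric permutation test for a group difference
#'
#' Computes the two-sample T statistic (pooled-variance by default) for the
#' observed labels, then builds its empirical null distribution by randomly
#' reallocating all values into two groups of the observed sizes. The
#' two-tailed p-value is `(#{|T_perm| >= |T_obs|} + 1) / (n_perm + 1)`
#' (the add-one convention keeps p strictly positive), and the reported
#' critical values are +/- the 95th percentile of `|T_perm|`.
#'
#' @param values Per-subject metric values.
#' @param groups Group labels (exactly two levels; the T statistic is
#'   mean(first level) - mean(second level), levels in sorted order unless
#'   `groups` is a factor).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param var_equal Pooled-variance T (default `TRUE`); `FALSE` for Welch.
#' @return Object of class `permutation_result`: `t_observed`, `p_perm`,
#'   `critical_values`, `n_permutations`, `group_levels`.
#' @export
permutation_test <- function(values, groups, n_perm = 10000, seed = NULL,
                             var_equal = TRUE) {
  values <- as.numeric(values)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("exactly two group labels required", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  n <- n1 + n2
  obs <- matrix(groups == levels(groups)[1], nrow = 1)
  t_obs <- as.numeric(t_stats_for_labels(values, obs, n1, n2, var_equal))
  if (!is.finite(t_obs))
    stop("zero pooled variance: T statistic undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gmat <- matrix(FALSE, n_perm, n)
  for (b in seq_len(n_perm))
    gmat[b, sample.int(n, n1)] <- TRUE
  t_perm <- as.numeric(t_stats_for_labels(values, gmat, n1, n2, var_equal))
  t_perm <- t_perm[is.finite(t_perm)]
  crit <- as.numeric(quantile(abs(t_perm), 0.95, type = 1))
  structure(list(t_observed = t_obs,
                 p_perm = (sum(abs(t_perm) >= abs(t_obs)) + 1) /
                   (length(t_perm) + 1),
                 critical_values = c(lower = -crit, upper = crit),
                 n_permutations = n_perm,
                 group_levels = levels(groups)),
            class = "permutation_result")
}

#' Benjamini-Hochberg FDR adjustment for a test family
#'
#' Step-up q-values with significance flags at the given level. Families
#' (e.g. the 4-test global family and the 2 x N nodal family) are
#' corrected separately, exactly as tested.
#'
#' @param p_values Raw p-values in (0, 1].
#' @param family Optional family label carried into the output.
#' @param q_level Significance level on q (default 0.05).
#' @return Data frame of class `fdr_result`: `p`, `q`, `significant`
#'   (plus `family` when given), in input order.
#' @export
fdr_adjust <- function(p_values, family = NULL, q_level = 0.05) {
  if (length(p_values) == 0) stop("empty p-value list", call. = FALSE)
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- p.adjust(p_values, method = "BH")
  out <- data.frame(p = p_values, q = q, significant = q < q_level)
  if (!is.null(family)) out$family <- family
  class(out) <- c("fdr_result", "data.frame")
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariates; the p-value comes from
#' the t distribution with `n - k - 2` degrees of freedom (`k` covariates).
#' With no covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional matrix/data frame of covariates (columns may
#'   include a 0/1 sex indicator, age, education, mean FD, ...).
#' @return Object of class `partial_correlation`: `r`, `p`, `df`,
#'   `n`, `covariates` (names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    z <- as.matrix(covariates)
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    design <- cbind(1, z)
    qr_z <- qr(design)
    if (qr_z$rank < ncol(design))
      warning("collinear covariates; using least-squares projection",
              call. = FALSE)
    rx <- qr.resid(qr_z, x)
    ry <- qr.resid(qr_z, y)
  } else {
    rx <- x - mean(x)
    ry <- y - mean(y)
  }
  if (n <= k + 2)
    stop("need n > number of covariates + 2", call. = FALSE)
  if (sd(rx) <= 1e-10 * max(sd(x), 1e-300) ||
      sd(ry) <= 1e-10 * max(sd(y), 1e-300))
    stop("zero residual variance after removing covariates", call. = FALSE)
  r <- cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p = 2 * pt(-abs(tval), df), df = df, n = n,
                 covariates = colnames(covariates) %||% character(0)),
            class = "partial_correlation")
}

#' Build the per-subject metric table for group analysis
#'
#' Joins subject profiles' AUC summaries (4 global metrics plus per-node
#' degree and betweenness) with the cohort manifest (group, covariates,
#' clinical scores).
#'
#' @param profiles List of [profile_subject()] results, one per subject,
#'   in manifest order.
#' @param manifest Data frame with `subject_id`, `group`, covariates and
#'   clinical scores.
#' @return Data frame: manifest columns followed by `cp_auc`, `lp_auc`,
#'   `gamma_auc`, `lambda_auc` and, when profiles carry nodal metrics,
#'   `degree_<region>` / `betweenness_<region>` columns.
#' @export
metric_table <- function(profiles, manifest) {
  stopifnot(length(profiles) == nrow(manifest))
  glob <- t(vapply(profiles, function(p)
    c(cp_auc = p$auc$cp, lp_auc = p$auc$lp, gamma_auc = p$auc$gamma,
      lambda_auc = p$auc$lambda, sigma_auc = p$auc$sigma), numeric(5)))
  out <- cbind(manifest, as.data.frame(glob))
  if (!is.null(profiles[[1]]$auc$degree)) {
    deg <- t(vapply(profiles, function(p) p$auc$degree,
                    numeric(length(profiles[[1]]$auc$degree))))
    bet <- t(vapply(profiles, function(p) p$auc$betweenness,
                    numeric(length(profiles[[1]]$auc$betweenness))))
    colnames(deg) <- paste0("degree_", colnames(deg))
    colnames(bet) <- paste0("betweenness_", colnames(bet))
    out <- cbind(out, as.data.frame(deg), as.data.frame(bet))
  }
  out
}

#' Group comparison and brain-behavior analysis on a metric table
#'
#' Runs the permutation T test on every metric AUC, corrects the global
#' family (4 tests) and the nodal family (2 x N tests) separately with
#' Benjamini-Hochberg FDR, then computes covariate-adjusted partial
#' correlations between each FDR-significant metric and each clinical
#' variable (mirroring the conditional design of testing behavior only for
#' altered metrics), with a second FDR pass across the correlation grid.
#'
#' @param table A [metric_table()] data frame.
#' @param clinical_vars Character vector of clinical-score column names.
#' @param covariates Covariate column names for the partial correlations
#'   (default age, sex, mean FD, education).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Optional master seed (per-metric seeds are derived from it).
#' @param q_level FDR level (default 0.05).
#' @param correlation_group Optional group label: compute correlations
#'   within this group only (e.g. the patient group); default all subjects.
#' @return List of class `group_analysis`: `permutation` (data frame:
#'   metric, family, t, p, q, significant), `correlations` (data frame:
#'   metric, clinical, r, p, q, significant; zero rows when nothing is
#'   significant), `group_levels`, `n_perm`, `seed`.
#' @export
run_group_analysis <- function(table,
                               clinical_vars = "score",
                               covariates = c("age", "sex", "education",
                                              "mean_fd"),
                               n_perm = 10000, seed = NULL,
                               q_level = 0.05,
                               correlation_group = NULL) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  global_metrics <- intersect(c("cp_auc", "lp_auc", "gamma_auc",
                                "lambda_auc"), names(table))
  nodal_metrics <- grep("^(degree|betweenness)_", names(table), value = TRUE)
  metrics <- c(global_metrics, nodal_metrics)
  if (length(metrics) == 0) stop("no metric columns found", call. = FALSE)
  groups <- as.factor(table$group)
  if (!is.null(seed)) seed <- as.integer(seed)
  perm_rows <- lapply(seq_along(metrics), function(i) {
    m <- metrics[i]
    res <- permutation_test(table[[m]], groups, n_perm = n_perm,
                            seed = if (!is.null(seed))
                              (seed * 1000 + i) %% 2147483647)
    data.frame(metric = m,
               family = if (m %in% global_metrics) "global" else "nodal",
               t = res$t_observed, p = res$p_perm,
               stringsAsFactors = FALSE)
  })
  perm <- do.call(rbind, perm_rows)
  perm$q <- NA_real_
  perm$significant <- FALSE
  for (fam in unique(perm$family)) {
    sel <- perm$family == fam
    adj <- fdr_adjust(perm$p[sel], family = fam, q_level = q_level)
    perm$q[sel] <- adj$q
    perm$significant[sel] <- adj$significant
  }
  sig <- perm$metric[perm$significant]
  sub <- table
  if (!is.null(correlation_group)) sub <- table[table$group ==
                                                  correlation_group, ]
  cor_rows <- list()
  for (m in sig) for (cv in clinical_vars) {
    pc <- partial_correlation(sub[[m]], sub[[cv]],
                              covariates = sub[, covariates, drop = FALSE])
    cor_rows[[length(cor_rows) + 1]] <-
      data.frame(metric = m, clinical = cv, r = pc$r, p = pc$p,
                 stringsAsFactors = FALSE)
  }
  correlations <- if (length(cor_rows) > 0) {
    cc <- do.call(rbind, cor_rows)
    adj <- fdr_adjust(cc$p, family = "correlations", q_level = q_level)
    cc$q <- adj$q
    cc$significant <- adj$significant
    cc
  } else data.frame(metric = character(0), clinical = character(0),
                    r = numeric(0), p = numeric(0), q = numeric(0),
                    significant = logical(0))
  structure(list(permutation = perm, correlations = correlations,
                 group_levels = levels(groups), n_perm = n_perm,
                 seed = seed),
            class = "group_analysis")
}

#' @export
print.group_analysis <- function(x, ...) {
  cat("Group comparison (", x$group_levels[1], " - ", x$group_levels[2],
      "), ", x$n_perm, " permutations\n", sep = "")
  sig <- x$permutation[x$permutation$significant, , drop = FALSE]
  cat(nrow(sig), "FDR-significant metric(s)\n")
  if (nrow(sig) > 0) print(sig, row.names = FALSE)
  invisible(x)
}
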
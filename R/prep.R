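#' Regional time-series container
#'
#' @param data T x N numeric matrix of regional mean signals (T timepoints,
#'   N regions). No missing values allowed.
#' @param tr_seconds Repetition time in seconds.
#' @param region_names Length-N character vector (defaults to column names).
#' @param subject_id Optional identifier.
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds, region_names = colnames(data),
                           subject_id = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || !all(is.finite(data)))
    stop("time series must be finite with no missing values", call. = FALSE)
  if (ncol(data) < 2) stop("need at least 2 regions", call. = FALSE)
  if (nrow(data) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (is.null(region_names))
    region_names <- sprintf("ROI%02d", seq_len(ncol(data)))
  stopifnot(length(region_names) == ncol(data), tr_seconds > 0)
  colnames(data) <- region_names
  structure(list(data = data, tr_seconds = tr_seconds,
                 region_names = region_names, subject_id = subject_id),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series", if (!is.null(x$subject_id)) paste0("(", x$subject_id, ")"),
      ":", nrow(x$data), "timepoints x", ncol(x$data), "regions, TR",
      x$tr_seconds, "s\n")
  invisible(x)
}

#' Convert a rotational displacement to millimeters of arc
#'
#' Rotations are mapped to displacement as arc length on the surface of a
#' sphere (default radius 50 mm, a standard head-size convention), i.e.
#' `radius * angle_in_radians`. Sign is preserved; framewise displacement
#' takes absolute differences downstream.
#'
#' @param angle Rotation angle(s).
#' @param radius_mm Sphere radius in mm.
#' @param units `"degrees"` (default) or `"radians"`.
#' @return Displacement(s) in mm.
#' @examples
#' rotation_to_mm(1) # 50 * pi / 180 = 0.8727 mm
#' @export
rotation_to_mm <- function(angle, radius_mm = 50,
                           units = c("degrees", "radians")) {
  units <- match.arg(units)
  stopifnot(all(is.finite(angle)))
  rad <- if (units == "degrees") angle * pi / 180 else angle
  radius_mm * rad
}

#' Framewise displacement and motion-based exclusion
#'
#' FD at volume t is the sum over the six rigid-body parameters of the
#' absolute volume-to-volume change, with rotations first converted to mm
#' of arc on a 50 mm sphere; FD of the first volume is defined as 0 and
#' included in the mean. A subject is flagged for exclusion when the
#' maximum absolute translation exceeds `max_translation_mm` or the mean
#' FD exceeds `max_mean_fd_mm`.
#'
#' @param motion T x 6 matrix: translations (mm) in columns 1-3, rotations
#'   in columns 4-6.
#' @param radius_mm Sphere radius for the rotation conversion.
#' @param rotation_units Units of columns 4-6 (`"degrees"` default).
#' @param max_translation_mm,max_mean_fd_mm Exclusion thresholds
#'   (defaults 3 mm and 0.5 mm).
#' @return List of class `motion_summary`: `fd_series`, `mean_fd`,
#'   `max_translation`, `excluded`, `exclusion_reason`.
#' @export
framewise_displacement <- function(motion, radius_mm = 50,
                                   rotation_units = "degrees",
                                   max_translation_mm = 3,
                                   max_mean_fd_mm = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion trace must have 6 columns (3 translations, 3 rotations); ",
         "got ", ncol(motion), call. = FALSE)
  stopifnot(all(is.finite(motion)))
  mm <- cbind(motion[, 1:3, drop = FALSE],
              rotation_to_mm(motion[, 4:6, drop = FALSE], radius_mm,
                             rotation_units))
  fd <- if (nrow(mm) > 1)
    c(0, rowSums(abs(diff(mm)))) else 0
  max_trans <- max(abs(motion[, 1:3]))
  mean_fd <- mean(fd)
  reasons <- c(
    if (max_trans > max_translation_mm)
      sprintf("max translation %.3f mm > %g mm", max_trans,
              max_translation_mm),
    if (mean_fd > max_mean_fd_mm)
      sprintf("mean FD %.3f mm > %g mm", mean_fd, max_mean_fd_mm))
  structure(list(fd_series = fd, mean_fd = mean_fd,
                 max_translation = max_trans,
                 excluded = length(reasons) > 0,
                 exclusion_reason = paste(reasons, collapse = "; ")),
            class = "motion_summary")
}

#' Build the joint nuisance + band-pass design matrix
#'
#' Assembles, in one design: the 24-parameter motion expansion (the six
#' rigid-body parameters, their one-volume-back copies with the first row
#' zero-padded, and the squares of both sets), optional tissue signals
#' (white matter, CSF, global), a discrete-cosine basis spanning all
#' frequencies *outside* the passband, and an intercept. Regressing a
#' series on this design in a single linear model removes nuisance
#' variance and band-pass filters simultaneously, so filtering cannot
#' reintroduce regressed-out artifacts.
#'
#' @param motion T x 6 motion trace.
#' @param tissue Optional T x (1-3) matrix of tissue signals.
#' @param t Number of timepoints (checked against `motion`).
#' @param tr Repetition time, seconds.
#' @param band Passband in Hz (default `c(0.01, 0.08)`). Cosine component
#'   `k` has frequency `k / (2 * t * tr)`; components with frequency
#'   inside the band are *excluded* from the design (they survive
#'   cleaning).
#' @return List of class `nuisance_design`: `x` (T x P design matrix) and
#'   a `columns` breakdown.
#' @export
build_nuisance_design <- function(motion, tissue = NULL, t = nrow(motion),
                                  tr, band = c(0.01, 0.08)) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) == t, tr > 0)
  lagged <- rbind(0, motion[-t, , drop = FALSE])
  mot24 <- cbind(motion, lagged, motion^2, lagged^2)
  colnames(mot24) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                       paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag_sq"))
  if (!is.null(tissue)) {
    tissue <- as.matrix(tissue)
    stopifnot(nrow(tissue) == t, ncol(tissue) <= 3)
  }
  k <- seq_len(t - 1)
  f <- k / (2 * t * tr)
  k_out <- k[f < band[1] | f > band[2]]
  filt <- dct_columns(t, k_out)
  if (ncol(filt) > 0)
    colnames(filt) <- paste0("dct", k_out)
  x <- cbind(intercept = rep(1, t), mot24, tissue, filt)
  if (t < ncol(x) + 2)
    stop("underdetermined nuisance design: ", t, " rows for ", ncol(x),
         " columns", call. = FALSE)
  structure(list(x = x,
                 columns = list(motion = colnames(mot24),
                                tissue = colnames(tissue),
                                filter = if (ncol(filt)) colnames(filt)
                                         else character(0),
                                filter_k = k_out),
                 band = band, tr = tr),
            class = "nuisance_design")
}

#' Regress nuisance design out of a regional time series
#'
#' Returns the least-squares residuals of each region's series on the full
#' design of [build_nuisance_design()] — nuisance regression and band-pass
#' filtering in a single linear model. Residuals are orthogonal to every
#' design column. A rank-deficient design proceeds via the pivoted QR
#' least-squares solution with a warning.
#'
#' @param series A [roi_timeseries()].
#' @param design A [build_nuisance_design()] result (or bare matrix).
#' @return A cleaned [roi_timeseries()].
#' @export
clean_timeseries <- function(series, design) {
  x <- if (inherits(design, "nuisance_design")) design$x else as.matrix(design)
  if (nrow(x) != nrow(series$data))
    stop("design has ", nrow(x), " rows but series has ",
         nrow(series$data), call. = FALSE)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x))
    warning("rank-deficient nuisance design (rank ", qr_x$rank, " < ",
            ncol(x), " columns); using least-squares projection",
            call. = FALSE)
  beta <- qr.coef(qr_x, series$data)
  beta[is.na(beta)] <- 0
  resid <- series$data - x %*% beta
  roi_timeseries(resid, tr_seconds = series$tr_seconds,
                 region_names = series$region_names,
                 subject_id = series$subject_id)
}

#' Extract regional mean time series from a 4D image and a label atlas
#'
#' @param image 4D numeric array (x, y, z, t).
#' @param atlas 3D integer array on the same grid; labels `1..N` define the
#'   regions, 0 is background.
#' @param tr_seconds Repetition time for the output series.
#' @param region_names Optional names for labels `1..N`.
#' @return A [roi_timeseries()] whose column `j` is the mean over voxels
#'   with label `j` at each timepoint.
#' @export
extract_roi_timeseries <- function(image, atlas, tr_seconds,
                                   region_names = NULL) {
  di <- dim(image); da <- dim(atlas)
  if (length(di) != 4 || length(da) != 3 || !all(di[1:3] == da))
    stop("image (4D) and atlas (3D) must share the spatial grid",
         call. = FALSE)
  labels <- sort(unique(as.integer(atlas[atlas > 0])))
  n <- max(labels)
  missing <- setdiff(seq_len(n), labels)
  vox <- matrix(image, prod(di[1:3]), di[4])
  lab <- as.integer(atlas)
  counts <- tabulate(lab, nbins = n)
  if (length(missing) > 0 || any(counts == 0))
    stop("atlas labels with zero voxels: ",
         paste(sort(unique(c(missing, which(counts == 0)))), collapse = ", "),
         call. = FALSE)
  keep <- lab > 0
  sums <- rowsum(vox[keep, , drop = FALSE], lab[keep])
  means <- sums / counts
  roi_timeseries(t(means), tr_seconds = tr_seconds,
                 region_names = region_names)
}
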
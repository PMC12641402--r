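#' Quality control for a cleaned BOLD time-series table
#'
#' Computes the temporal signal-to-noise ratio (tSNR: temporal mean divided
#' by temporal standard deviation) per region, the mean framewise
#' displacement (FD) when a motion-parameter table is supplied, and the
#' overall pass flag: mean tSNR above `tsnr_min` and — when FD is
#' available — mean FD below `fd_max_mm`.
#'
#' FD uses the backward-difference formulation: per frame, the sum of
#' absolute differences of the six rigid-body parameters, with the three
#' rotations (radians) converted to millimetres of arc on a 50 mm sphere.
#'
#' @param ts Timepoints-by-regions numeric matrix.
#' @param motion Optional timepoints-by-6 matrix (3 translations in mm,
#'   3 rotations in radians), one row per retained frame.
#' @param tsnr_min tSNR gate (default 100).
#' @param fd_max_mm FD gate in mm (default 0.3).
#' @param rotation_radius_mm Sphere radius converting rotations to mm.
#' @return An object of class `qc_report`: list with `tsnr_per_region`,
#'   `mean_tsnr`, `mean_fd_mm` (`NA` when no motion table), `pass`, and
#'   the gates used. Regions with zero temporal SD get `Inf` tSNR and a
#'   note in `log`.
#' @examples
#' ts <- matrix(rnorm(200, mean = 500, sd = 4), 50, 4)
#' compute_qc(ts)$pass
#' @export
compute_qc <- function(ts, motion = NULL, tsnr_min = 100, fd_max_mm = 0.3,
                       rotation_radius_mm = 50) {
  ts <- as.matrix(ts)
  mu <- colMeans(ts)
  sdv <- apply(ts, 2, stats::sd)
  log_lines <- character(0)
  tsnr <- ifelse(sdv == 0, Inf, mu / sdv)
  if (any(sdv == 0)) {
    log_lines <- c(log_lines, paste0(
      sum(sdv == 0), " region(s) with zero temporal SD; tSNR set to Inf"))
  }
  mean_fd <- NA_real_
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) stop("motion table must have 6 columns")
    if (nrow(motion) != nrow(ts)) {
      stop("motion table must have one row per retained frame")
    }
    mean_fd <- mean(framewise_displacement(motion, rotation_radius_mm))
  }
  mean_tsnr <- mean(tsnr[is.finite(tsnr)])
  pass <- (mean_tsnr > tsnr_min) && (is.na(mean_fd) || mean_fd < fd_max_mm)
  structure(list(tsnr_per_region = tsnr, mean_tsnr = mean_tsnr,
                 mean_fd_mm = mean_fd, pass = pass,
                 tsnr_min = tsnr_min, fd_max_mm = fd_max_mm,
                 fd_formulation = "backward difference, 50 mm sphere",
                 log = log_lines),
            class = "qc_report")
}

#' Framewise displacement from six motion parameters
#'
#' @param motion Timepoints-by-6 matrix: translations (mm) then rotations
#'   (radians), column order irrelevant as long as rotations occupy the
#'   columns named or positioned as the last three.
#' @param rotation_radius_mm Radius of the sphere on which rotations are
#'   expressed as arc length (default 50 mm).
#' @return Numeric vector of length `nrow(motion)`; the first frame is 0.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have 6 columns")
  d <- abs(apply(motion, 2, function(col) c(0, diff(col))))
  d[, 4:6] <- d[, 4:6] * rotation_radius_mm
  rowSums(d)
}

#' Clean a BOLD time-series table
#'
#' Applies, in order: removal of the first `drop_first` frames, per-region
#' linear detrending, zero-phase band-pass filtering (forward-backward
#' Butterworth, order 2 per pass), and per-region standardisation to mean 0
#' and SD 1 (always last, so the output is ready for correlation).
#'
#' @param ts Timepoints-by-regions numeric matrix.
#' @param tr_seconds Repetition time in seconds (needed for the band).
#' @param drop_first Number of leading frames to discard (default 5).
#' @param band Length-2 numeric `(low, high)` in Hz, or `NULL` to skip
#'   filtering. Defaults to 0.01–0.08 Hz.
#' @param detrend Remove a per-region linear trend (default `TRUE`).
#' @return Matrix with `nrow(ts) - drop_first` rows; column names kept.
#' @examples
#' ts <- matrix(rnorm(305 * 3), 305, 3)
#' out <- preprocess_bold(ts, tr_seconds = 2)
#' nrow(out)          # 300
#' round(colMeans(out), 12)
#' @export
preprocess_bold <- function(ts, tr_seconds, drop_first = 5,
                            band = c(0.01, 0.08), detrend = TRUE) {
  ts <- as.matrix(ts)
  stopifnot(tr_seconds > 0, drop_first >= 0)
  if (nrow(ts) <= drop_first + 50) {
    stop("need more than drop_first + 50 frames")
  }
  out <- ts[(drop_first + 1):nrow(ts), , drop = FALSE]
  n <- nrow(out)
  if (detrend) {
    tt <- cbind(1, seq_len(n))
    out <- stats::lm.fit(tt, out)$residuals
  }
  if (!is.null(band)) {
    nyq <- 1 / (2 * tr_seconds)
    if (length(band) != 2 || band[1] <= 0 || band[2] >= nyq ||
        band[1] >= band[2]) {
      stop("band edges must satisfy 0 < low < high < Nyquist = ",
           signif(nyq, 4), " Hz (tr_seconds = ", tr_seconds, ")")
    }
    bf <- signal::butter(2, band / nyq, type = "pass")
    out <- apply(out, 2, function(x) signal::filtfilt(bf, x))
  }
  out <- scale(out)
  # scale() uses the n-1 denominator; that constant is irrelevant for
  # correlations but keep the documented contract of unit SD
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  dimnames(out) <- list(NULL, colnames(ts))
  out
}

#' Hemisphere-wise Fisher-z connectivity matrices
#'
#' Pearson-correlates every within-hemisphere region pair and maps the
#' correlations through `atanh` after clipping to ±(1 - 1e-6) so that
#' duplicated signals stay finite. Cross-hemisphere pairs are never
#' computed; the diagonal is set to 0.
#'
#' @param ts Timepoints-by-regions matrix with region ids as column names.
#' @param meta Region metadata with columns `region_id` and `hemisphere`
#'   (`"L"`/`"R"`); every column of `ts` must be assigned.
#' @return Named list with elements `L` and `R`, each a symmetric
#'   region-by-region Fisher-z matrix with region-id dimnames.
#' @examples
#' meta <- data.frame(region_id = c("L1", "L2", "R1", "R2"),
#'                    hemisphere = c("L", "L", "R", "R"))
#' ts <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, meta$region_id))
#' z <- fisher_z_connectivity(ts, meta)
#' z$L
#' @export
fisher_z_connectivity <- function(ts, meta) {
  ts <- as.matrix(ts)
  ids <- colnames(ts)
  if (is.null(ids)) stop("ts must carry region ids as column names")
  hemi <- meta$hemisphere[match(ids, meta$region_id)]
  if (anyNA(hemi)) {
    stop("regions without hemisphere assignment: ",
         paste(ids[is.na(hemi)], collapse = ", "))
  }
  out <- list()
  for (h in c("L", "R")) {
    cols <- which(hemi == h)
    if (length(cols) < 2) {
      stop("hemisphere ", h, " has fewer than 2 regions")
    }
    r <- stats::cor(ts[, cols, drop = FALSE])
    r <- pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6)
    z <- atanh(r)
    diag(z) <- 0
    out[[h]] <- z
  }
  out
}
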
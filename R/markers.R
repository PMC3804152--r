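# Marker trajectory I/O and segment-based centre-of-mass estimation.
#
# Marker TSV dialect: header `time<TAB><name>_x<TAB><name>_y<TAB><name>_z ...`,
# one frame per row, coordinates in metres (x anterior, y lateral, z up).

#' Read / write marker trajectories (TSV)
#'
#' @param path Path to a tab-separated marker file.
#' @return `read_marker_tsv()` returns a data.frame with a `time` column and
#'   `<marker>_x`, `<marker>_y`, `<marker>_z` columns (metres).
#' @export
read_marker_tsv <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(d)) stop("marker file ", path, " has no 'time' column")
  if (is.unsorted(d$time, strictly = TRUE))
    stop("marker file ", path, ": time must be strictly increasing")
  d
}

#' @param frames Marker data.frame as returned by `read_marker_tsv()`.
#' @rdname read_marker_tsv
#' @export
write_marker_tsv <- function(frames, path) {
  utils::write.table(frames, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Average the (possibly comma-separated, bilateral) markers named in `spec`
# and return an n x 2 matrix of sagittal (x, z) coordinates.
.marker_xy <- function(frames, spec) {
  names <- strsplit(spec, ",", fixed = TRUE)[[1]]
  xs <- matrix(0, nrow(frames), length(names))
  zs <- matrix(0, nrow(frames), length(names))
  for (j in seq_along(names)) {
    cx <- paste0(names[j], "_x"); cz <- paste0(names[j], "_z")
    if (!cx %in% colnames(frames) || !cz %in% colnames(frames))
      stop("marker '", names[j], "' not present in frames")
    xs[, j] <- frames[[cx]]
    zs[, j] <- frames[[cz]]
  }
  cbind(rowMeans(xs), rowMeans(zs))
}

# Per-frame segment CM positions (midpoint of proximal/distal markers).
# Returns list(u = n x nseg, h = n x nseg) in ankle-relative coordinates.
.segment_cm <- function(frames, subject, ankle_marker = "ankle_l,ankle_r") {
  st <- subject$segment_table
  ank <- .marker_xy(frames, ankle_marker)
  # the support foot is motionless by model assumption, so the ankle
  # reference is time-averaged: this keeps marker noise on the ankle
  # markers from leaking into every ankle-relative CM sample
  ank[, 1] <- mean(ank[, 1], na.rm = TRUE)
  ank[, 2] <- mean(ank[, 2], na.rm = TRUE)
  n <- nrow(frames); ns <- nrow(st)
  U <- matrix(NA_real_, n, ns); H <- matrix(NA_real_, n, ns)
  for (s in seq_len(ns)) {
    p <- .marker_xy(frames, st$proximal[s])
    d <- .marker_xy(frames, st$distal[s])
    U[, s] <- (p[, 1] + d[, 1]) / 2 - ank[, 1]
    H[, s] <- (p[, 2] + d[, 2]) / 2 - ank[, 2]
  }
  list(u = U, h = H)
}

#' Estimate the body centre of mass from marker frames
#'
#' Each segment's CM is the midpoint of its proximal and distal markers
#' (uniform segment density); the body CM is the mass-fraction-weighted mean
#' of segment CMs, expressed relative to the ankle joint (sagittal plane:
#' `u` anterior, `h` vertical, metres). Frames with any missing (non-finite)
#' required marker are flagged and excluded; more than `max_gap_fraction`
#' excluded frames is an error.
#'
#' @param frames Marker data.frame (see [read_marker_tsv()]).
#' @param subject An `sts_subject` whose segment table names the markers.
#' @param max_gap_fraction Maximum tolerated fraction of gap frames.
#' @return A data.frame `time`, `u`, `h` for the retained frames, with
#'   attribute `gaps` (integer vector of excluded frame indices).
#' @examples
#' # a one-segment subject recovers the marker midpoint exactly
#' @export
estimate_cm <- function(frames, subject, max_gap_fraction = 0.2) {
  validate_subject(subject)
  seg <- .segment_cm(frames, subject)
  f <- subject$segment_table$fraction
  u <- as.numeric(seg$u %*% f)
  h <- as.numeric(seg$h %*% f)
  bad <- which(!is.finite(u) | !is.finite(h))
  if (length(bad) > 0) {
    if (length(bad) / nrow(frames) > max_gap_fraction)
      stop("marker gaps in ", length(bad), "/", nrow(frames),
           " frames exceed the ", max_gap_fraction * 100, "% limit")
    message("estimate_cm: excluding ", length(bad),
            " frame(s) with missing markers")
  }
  keep <- setdiff(seq_len(nrow(frames)), bad)
  out <- data.frame(time = frames$time[keep], u = u[keep], h = h[keep])
  attr(out, "gaps") <- bad
  out
}

#' Horizontal CM position uncertainty from mass-distribution SDs
#'
#' First-order propagation of the segment mass-fraction standard deviations
#' to the horizontal body-CM position: at each posture the CM sensitivity to
#' fraction i is the segment's horizontal offset from the body CM, so
#' `sd(u_cm) = sqrt(sum_i sd_i^2 * (u_i - u_cm)^2)`. The returned half-width
#' is the worst case over the trial's frames. A fixed `override` (e.g.
#' 0.015 m) bypasses the propagation.
#'
#' @param subject An `sts_subject` (its segment table carries the SDs).
#' @param frames Marker data.frame.
#' @param override Optional fixed half-width, m.
#' @return Half-width of the horizontal CM uncertainty, m.
#' @export
cm_position_error <- function(subject, frames, override = NULL) {
  if (!is.null(override)) return(override)
  validate_subject(subject)
  seg <- .segment_cm(frames, subject)
  f <- subject$segment_table$fraction
  sds <- subject$segment_table$fraction_sd
  ucm <- as.numeric(seg$u %*% f)
  dev <- sweep(seg$u, 1, ucm, "-")
  per_frame <- sqrt((dev^2) %*% (sds^2))
  m <- suppressWarnings(max(per_frame, na.rm = TRUE))
  if (!is.finite(m)) stop("no complete frames to propagate CM uncertainty")
  m
}

#' Convert an ankle-relative CM series to polar pendulum coordinates
#'
#' `l = sqrt(u^2 + h^2)`; `theta = atan2(h, u)` (angle from the anterior
#' horizontal axis: pi/2 when the CM is directly above the ankle, > pi/2
#' posterior). The angular velocity is computed by central differences,
#' optionally smoothed with a zero-phase 2nd-order Butterworth low-pass
#' (default cutoff 6 Hz).
#'
#' @param cm Data.frame `time`, `u`, `h` from [estimate_cm()].
#' @param cutoff_hz Low-pass cutoff for the velocity, Hz; `NULL` or `Inf`
#'   disables smoothing.
#' @return Data.frame `time`, `theta` (rad), `omega` (rad/s), `l` (m).
#' @export
kinematics_to_polar <- function(cm, cutoff_hz = 6) {
  u <- cm$u; h <- cm$h; t <- cm$time
  if (any(!is.finite(u)) || any(!is.finite(h)))
    stop("CM series contains non-finite values")
  l <- sqrt(u^2 + h^2)
  if (any(l == 0)) stop("degenerate geometry: CM coincides with the ankle")
  theta <- atan2(h, u)
  n <- length(t)
  if (n < 3L) stop("need at least 3 frames for velocity estimation")
  omega <- numeric(n)
  omega[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  omega[1] <- (theta[2] - theta[1]) / (t[2] - t[1])
  omega[n] <- (theta[n] - theta[n - 1]) / (t[n] - t[n - 1])
  if (!is.null(cutoff_hz) && is.finite(cutoff_hz)) {
    fs <- 1 / stats::median(diff(t))
    if (cutoff_hz < fs / 2 && n > 12L) {
      bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
      omega <- as.numeric(signal::filtfilt(bf, omega))
    }
  }
  data.frame(time = t, theta = theta, omega = omega, l = l)
}
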
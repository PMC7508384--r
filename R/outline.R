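# Outline processing: pixel calibration, equal-height resampling,
# zero-phase low-pass smoothing, and mirroring of right-half profiles
# into closed full outlines.

#' Pixel-to-centimetre calibration
#'
#' Per-axis scale factors obtained from a digitized reference object of
#' known dimensions (the field protocol used an inverted-T calibration
#' object, 36 cm high by 42 cm wide). Per-axis factors accommodate
#' anisotropic pixels; pass equal factors for a single scalar calibration.
#'
#' @param px_per_cm_x,px_per_cm_y positive pixels-per-centimetre factors.
#' @param reference optional free-form description of the reference object.
#' @return An object of class `calibration`.
#' @export
calibration <- function(px_per_cm_x, px_per_cm_y = px_per_cm_x,
                        reference = NULL) {
  if (!is.finite(px_per_cm_x) || px_per_cm_x <= 0 ||
      !is.finite(px_per_cm_y) || px_per_cm_y <= 0)
    stop("calibration factors must be positive", call. = FALSE)
  structure(list(px_per_cm_x = px_per_cm_x, px_per_cm_y = px_per_cm_y,
                 reference = reference),
            class = "calibration")
}

#' Convert digitized pixel coordinates to a centimetre profile
#'
#' @param points_px data frame or matrix with pixel columns `x`, `y`,
#'   ordered base to rim.
#' @param cal a [calibration()].
#' @return A `vessel_profile` in centimetres, ordering preserved.
#' @examples
#' cal <- calibration(20, 20)  # 720 px for a 36 cm reference
#' calibrate(data.frame(x = 100, y = 360), cal)  # (5, 18) cm
#' @export
calibrate <- function(points_px, cal) {
  stopifnot(inherits(cal, "calibration"))
  points_px <- as.data.frame(points_px)
  if (nrow(points_px) == 0)
    stop("calibrate: empty point set", call. = FALSE)
  new_profile(points_px$x / cal$px_per_cm_x,
              points_px$y / cal$px_per_cm_y)
}

#' Resample a profile at regular height intervals
#'
#' Returns `n_points` points at equally spaced heights from the profile's
#' lowest to highest point, with radii obtained by linear interpolation;
#' the two endpoints are preserved exactly. Input points are stably sorted
#' by height first; truly re-entrant profiles (distinct radii at the same
#' height) are not supported.
#'
#' @param p a `vessel_profile` (>= 2 points, positive height range).
#' @param n_points number of output points (default 256).
#' @return A `vessel_profile` with exactly `n_points` points and strictly
#'   increasing y.
#' @export
resample_profile <- function(p, n_points = 256L) {
  validate_profile(p)
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  ord <- order(p$y)            # stable sort
  x <- p$x[ord]; y <- p$y[ord]
  if (max(y) - min(y) <= 0)
    stop("degenerate profile: zero height range", call. = FALSE)
  dup <- duplicated(y)
  if (any(dup)) {
    # identical heights are only mergeable when radii agree
    for (yy in unique(y[dup])) {
      xs <- x[y == yy]
      if (diff(range(xs)) > 1e-9 * max(1, max(xs)))
        stop("unsupported geometry: re-entrant profile (multiple radii at height ",
             format(yy), ")", call. = FALSE)
    }
    x <- x[!dup]; y <- y[!dup]
  }
  y_out <- seq(min(y), max(y), length.out = n_points)
  x_out <- stats::approx(y, x, xout = y_out)$y
  # guard the exact-endpoint contract against interpolation rounding
  x_out[1] <- x[1]; x_out[n_points] <- x[length(x)]
  new_profile(x_out, y_out)
}

#' Smooth a resampled profile with a zero-phase low-pass filter
#'
#' Applies a 2nd-order Butterworth filter forward and backward
#' (zero phase) to the radius sequence; heights are unchanged. The
#' endpoint-to-endpoint linear trend is removed first and restored
#' afterwards, and the residual is padded by odd reflection before
#' filtering, so constant and linearly tapering walls pass through
#' unchanged and endpoint radii are preserved to well within 1%.
#'
#' @param p a resampled `vessel_profile` (uniform height steps).
#' @param cutoff cutoff as a fraction of the spatial Nyquist frequency,
#'   strictly in (0, 1); default 0.15.
#' @return The smoothed `vessel_profile`.
#' @export
smooth_profile <- function(p, cutoff = 0.15) {
  validate_profile(p, strict = TRUE)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly in (0, 1)", call. = FALSE)
  x <- p$x
  n <- length(x)
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - trend
  bf <- signal::butter(2, cutoff, type = "low")
  # odd-reflection padding of the zero-anchored residual absorbs the
  # filter's startup transients
  pad <- min(n - 1, max(32L, ceiling(6 / cutoff)))
  rp <- c(-rev(r[2:(pad + 1)]), r, -rev(r[(n - pad):(n - 1)]))
  rs <- signal::filtfilt(bf, rp)[(pad + 1):(pad + n)]
  new_profile(pmax(rs + trend, 0), p$y)
}

#' Mirror a right-half profile into a closed full outline
#'
#' Exploits axisymmetry: the left edge is the right edge with x negated.
#' The outline is traversed counterclockwise (y up, rotation axis at
#' x = 0): right edge base to rim, straight chord across the rim to the
#' mirrored rim point, mirrored left edge rim to base, straight chord
#' across the base back to the start; the first point is appended again to
#' close the contour explicitly. Points lying on the axis (x = 0) are not
#' duplicated, so fully closed vessels yield a single smooth curve with no
#' chords.
#'
#' @param p a `vessel_profile`.
#' @return A `vessel_outline`: data frame with columns `x`, `y`, first row
#'   equal to last row, counterclockwise orientation.
#' @export
mirror_to_outline <- function(p) {
  validate_profile(p)
  x <- p$x; y <- p$y
  n <- length(x)
  left_idx <- rev(seq_len(n))
  # drop on-axis rim/base points from the mirrored edge (they would
  # duplicate the right-edge points exactly)
  if (x[n] == 0) left_idx <- left_idx[-1]
  if (x[1] == 0 && length(left_idx) > 0 &&
      left_idx[length(left_idx)] == 1)
    left_idx <- left_idx[-length(left_idx)]
  xo <- c(x, -x[left_idx])
  yo <- c(y, y[left_idx])
  xo <- c(xo, xo[1]); yo <- c(yo, yo[1])  # explicit closure
  structure(data.frame(x = xo, y = yo),
            class = c("vessel_outline", "data.frame"))
}

#' @export
print.vessel_outline <- function(x, ...) {
  cat(sprintf("vessel_outline: %d points (closed), height %.3f cm, width %.3f cm\n",
              nrow(x) - 1, max(x$y) - min(x$y), diff(range(x$x))))
  invisible(x)
}

# Signed polygon area (shoelace); positive for counterclockwise outlines.
outline_area <- function(o) {
  x <- o$x; y <- o$y
  n <- length(x)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}
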
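# Elliptical Fourier analysis of closed outlines (Kuhl-Giardina).
#
# A closed contour (x(t), y(t)), parametrized by cumulative arc length t
# over perimeter T, is decomposed into per-harmonic quadruples
# (a_n, b_n, c_n, d_n) plus bias terms (A0, C0):
#   x(t) = A0 + sum_n a_n cos(2 pi n t / T) + b_n sin(2 pi n t / T)
#   y(t) = C0 + sum_n c_n cos(2 pi n t / T) + d_n sin(2 pi n t / T)
# The coefficients are evaluated in closed form from the chain of segment
# increments, which is exact for a polygonal contour. No rotation or
# start-point normalization is applied: all outlines in this package share
# the vessel coordinate frame (axis at x = 0, y up, start point at the
# base on the right edge), so only size normalization is needed for
# comparability.

#' Elliptical Fourier coefficients of a closed outline
#'
#' @param o a closed `vessel_outline` (first point = last point) or any
#'   two-column data frame/matrix of closed-contour coordinates with >= 3
#'   distinct points.
#' @param n_harmonics number of harmonics N (>= 1; default 20).
#' @return An `efa_coefficients` object: list with `harmonics` (N x 4
#'   matrix, columns `a`, `b`, `c`, `d`), `A0`, `C0`, `n_harmonics`, and
#'   `normalized` flag.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)
#' circ <- data.frame(x = 3 * cos(th), y = 3 * sin(th))
#' efa_coefficients(circ, 2)$harmonics[1, ]  # ~ (3, 0, 0, 3)
#' @export
efa_coefficients <- function(o, n_harmonics = 20L) {
  xy <- as.matrix(as.data.frame(o)[, c("x", "y")])
  storage.mode(xy) <- "double"
  if (nrow(xy) < 4)
    stop("outline needs at least 3 distinct points plus closure", call. = FALSE)
  if (any(abs(xy[1, ] - xy[nrow(xy), ]) > 1e-9))
    stop("outline is not closed (first point must equal last point)", call. = FALSE)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)

  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0                       # drop zero-length segments
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3 || sum(dt) <= 0)
    stop("degenerate contour: zero perimeter", call. = FALSE)
  t1 <- cumsum(dt)                     # arc length at segment ends
  t0 <- c(0, t1[-length(t1)])          # arc length at segment starts
  T <- t1[length(t1)]

  n <- seq_len(n_harmonics)
  w <- 2 * pi * outer(n, t1, "*") / T      # N x S phase at segment ends
  w0 <- 2 * pi * outer(n, t0, "*") / T     # N x S phase at segment starts
  dcos <- cos(w) - cos(w0)
  dsin <- sin(w) - sin(w0)
  const <- T / (2 * n^2 * pi^2)
  vx <- dx / dt; vy <- dy / dt
  a <- const * as.vector(dcos %*% vx)
  b <- const * as.vector(dsin %*% vx)
  cc <- const * as.vector(dcos %*% vy)
  d <- const * as.vector(dsin %*% vy)

  # bias terms: exact integral of the piecewise-linear x(t), y(t)
  xi <- cumsum(c(0, dx))[seq_along(dx)] - vx * t0
  A0 <- unname(sum(vx / 2 * (t1^2 - t0^2) + xi * (t1 - t0)) / T + xy[1, 1])
  delta <- cumsum(c(0, dy))[seq_along(dy)] - vy * t0
  C0 <- unname(sum(vy / 2 * (t1^2 - t0^2) + delta * (t1 - t0)) / T + xy[1, 2])

  structure(list(harmonics = cbind(a = a, b = b, c = cc, d = d),
                 A0 = A0, C0 = C0, n_harmonics = n_harmonics,
                 normalized = FALSE),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("efa_coefficients: %d harmonics%s, first harmonic (a,b,c,d) = (%.4g, %.4g, %.4g, %.4g)\n",
              x$n_harmonics, if (x$normalized) " (size-normalized)" else "",
              x$harmonics[1, 1], x$harmonics[1, 2],
              x$harmonics[1, 3], x$harmonics[1, 4]))
  invisible(x)
}

# Semi-axes of the first-harmonic ellipse: singular values of the 2x2
# coefficient matrix [[a1, b1], [c1, d1]].
first_harmonic_axes <- function(coef) {
  M <- matrix(coef$harmonics[1, ], 2, 2, byrow = TRUE)
  svd(M, nu = 0, nv = 0)$d
}

#' Size-normalize elliptical Fourier coefficients
#'
#' Divides every harmonic coefficient by the size measure of the first
#' harmonic and zeroes the bias terms, yielding scale-invariant pure-shape
#' descriptors: the same outline at any magnification maps to the same
#' normalized coefficients.
#'
#' @param coef an `efa_coefficients` object.
#' @param method `"semi_major"` (default) divides by the semi-major axis
#'   length of the first-harmonic ellipse (its largest singular value);
#'   `"a1"` divides by `|a1|`.
#' @return The normalized `efa_coefficients` (`normalized = TRUE`,
#'   `A0 = C0 = 0`).
#' @export
normalize_size <- function(coef, method = c("semi_major", "a1")) {
  stopifnot(inherits(coef, "efa_coefficients"))
  method <- match.arg(method)
  scale <- switch(method,
                  semi_major = first_harmonic_axes(coef)[1],
                  a1 = abs(coef$harmonics[1, 1]))
  if (!is.finite(scale) || scale <= 1e-12)
    stop("degenerate shape: first-harmonic size is zero", call. = FALSE)
  coef$harmonics <- coef$harmonics / scale
  coef$A0 <- 0
  coef$C0 <- 0
  coef$normalized <- TRUE
  coef
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` uniformly spaced
#' parameter values on \[0, T); the first point is appended again to close
#' the contour.
#'
#' @param coef an `efa_coefficients` object.
#' @param n_points number of distinct points (>= 3).
#' @return A closed `vessel_outline`.
#' @export
reconstruct <- function(coef, n_points = 256L) {
  stopifnot(inherits(coef, "efa_coefficients"))
  n_points <- as.integer(n_points)
  if (n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  n <- seq_len(coef$n_harmonics)
  C <- cos(outer(t, n))                # P x N
  S <- sin(outer(t, n))
  h <- coef$harmonics
  x <- coef$A0 + C %*% h[, "a"] + S %*% h[, "b"]
  y <- coef$C0 + C %*% h[, "c"] + S %*% h[, "d"]
  structure(data.frame(x = c(x, x[1]), y = c(y, y[1])),
            class = c("vessel_outline", "data.frame"))
}

#' Flatten coefficients to a fixed-order vector
#'
#' Fixed ordering `a1, b1, c1, d1, a2, ..., dN` (harmonic-major), the
#' layout used for coefficient matrices, PCA and permutation tests.
#'
#' @param coef an `efa_coefficients` object.
#' @return Named numeric vector of length `4 * n_harmonics`.
#' @export
coeff_vector <- function(coef) {
  stopifnot(inherits(coef, "efa_coefficients"))
  v <- as.vector(t(coef$harmonics))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), coef$n_harmonics),
                     rep(seq_len(coef$n_harmonics), each = 4))
  v
}

#' Size-normalized coefficient matrix for every stage of a study
#'
#' Runs the outline pipeline (resample, optional smoothing, mirror, EFA,
#' size normalization) on every stage of every trial and returns the
#' flattened coefficient rows with their trial keys.
#'
#' @param study a `vessel_study`.
#' @param n_harmonics harmonics per outline.
#' @param smooth_cutoff low-pass cutoff passed to [smooth_profile()];
#'   `NULL` disables smoothing (synthetic profiles are already smooth).
#' @param n_points resampling density before mirroring.
#' @param normalize_method passed to [normalize_size()].
#' @return Data frame: `trial_id`, `potter_id`, `community`,
#'   `vessel_type`, `stage_index`, `stage` (`"pre_formed"`,
#'   `"intermediate"` or `"final"`), then columns `a1 ... dN`.
#' @export
study_coefficients <- function(study, n_harmonics = 20L,
                               smooth_cutoff = NULL, n_points = 256L,
                               normalize_method = "semi_major") {
  stopifnot(inherits(study, "vessel_study"))
  rows <- list()
  for (tr in study$trials) {
    n_stage <- length(tr$stages)
    for (i in seq_len(n_stage)) {
      st <- tr$stages[[i]]
      prof <- resample_profile(st$profile, n_points)
      if (!is.null(smooth_cutoff)) prof <- smooth_profile(prof, smooth_cutoff)
      cf <- normalize_size(
        efa_coefficients(mirror_to_outline(prof), n_harmonics),
        method = normalize_method)
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = tr$trial_id, potter_id = tr$potter_id,
        community = tr$community, vessel_type = tr$vessel_type,
        stage_index = st$gesture_index,
        stage = if (i == 1) "pre_formed"
                else if (i == n_stage) "final" else "intermediate",
        t(coeff_vector(cf)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: coefficient columns of a study_coefficients table
coeff_columns <- function(tab) {
  grep("^[abcd][0-9]+$", names(tab), value = TRUE)
}
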
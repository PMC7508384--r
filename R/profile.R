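#' Construct a vessel profile from shape parameters
#'
#' Evaluates the parametric radius function r(y) of an axisymmetric vessel
#' at `n_points` equally spaced heights from base (y = 0) to rim
#' (y = height). The wall is a superelliptic blend: below the belly the
#' radius rises from the base radius to the maximal radius, above it it
#' falls to the aperture radius, with curvature set by the bulge exponent
#' (exponent 2 gives circular arcs, so a sphere-like body is represented
#' exactly). An optional rim bulge flares the wall outward over the top
#' tenth of the height, vanishing at the rim itself.
#'
#' @param params a [vessel_params()] object.
#' @param n_points number of profile points (>= 16).
#' @return A `vessel_profile`: a data frame with columns `x` (radial cm,
#'   >= 0) and `y` (vertical cm, strictly increasing), ordered base to rim.
#' @examples
#' p <- make_profile(vessel_params(16, 14, 0.5, 3, 3), 64)
#' max(p$x)  # = 7, the maximal radius
#' @export
make_profile <- function(params, n_points = 256L) {
  validate_vessel_params(params)
  n_points <- as.integer(n_points)
  if (n_points < 16L)
    stop("n_points must be >= 16", call. = FALSE)
  H <- params$height_cm
  y <- seq(0, H, length.out = n_points)
  new_profile(profile_radius(y, params), y)
}

# radius function r(y) of the superelliptic vessel wall
profile_radius <- function(y, params) {
  H <- params$height_cm
  R <- params$max_diameter_cm / 2
  ym <- params$max_diameter_rel_height * H
  k <- params$bulge_exponent
  r <- numeric(length(y))
  lo <- y <= ym
  u <- (ym - y[lo]) / ym
  r[lo] <- params$base_radius_cm +
    (R - params$base_radius_cm) * (1 - u^k)^(1 / k)
  u <- (y[!lo] - ym) / (H - ym)
  r[!lo] <- params$aperture_radius_cm +
    (R - params$aperture_radius_cm) * (1 - u^k)^(1 / k)
  if (params$rim_depth_cm > 0) {
    y_r <- 0.9 * H
    in_rim <- y >= y_r
    u <- (y[in_rim] - y_r) / (H - y_r)
    r[in_rim] <- r[in_rim] + params$rim_depth_cm * sin(pi * u)^2
  }
  pmax(r, 0)
}

new_profile <- function(x, y) {
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            class = c("vessel_profile", "data.frame"))
}

#' Validate a vessel profile
#'
#' Checks the profile contract: at least two points, radial coordinate
#' nonnegative, heights nondecreasing (strictly increasing when
#' `strict = TRUE`, the post-resampling invariant).
#'
#' @param p a `vessel_profile` or a data frame with columns `x`, `y`.
#' @param strict require strictly increasing y.
#' @return `p`, invisibly; errors describe the violated invariant.
#' @export
validate_profile <- function(p, strict = FALSE) {
  if (!all(c("x", "y") %in% names(p)))
    stop("profile must have columns x and y", call. = FALSE)
  if (nrow(p) < 2)
    stop("degenerate profile: fewer than 2 points", call. = FALSE)
  if (any(!is.finite(p$x)) || any(!is.finite(p$y)))
    stop("profile contains non-finite coordinates", call. = FALSE)
  if (any(p$x < 0))
    stop("profile x (radial) coordinates must be >= 0", call. = FALSE)
  dy <- diff(p$y)
  if (strict && any(dy <= 0))
    stop("profile y must be strictly increasing", call. = FALSE)
  invisible(p)
}

#' @export
print.vessel_profile <- function(x, ...) {
  cat(sprintf("vessel_profile: %d points, height %.3f cm, max radius %.3f cm\n",
              nrow(x), max(x$y) - min(x$y), max(x$x)))
  invisible(x)
}
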
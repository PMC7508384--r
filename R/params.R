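#' Vessel shape parameters
#'
#' A compact parametric description of an axisymmetric vessel: the radius
#' of its right-half profile as a function of height is determined by the
#' base radius, the maximal diameter (and the relative height at which it
#' occurs), the aperture radius, and a bulge exponent controlling how
#' sharply the wall curves between these anchor radii. An optional rim
#' depth adds an outward rim bulge just below the aperture.
#'
#' @param height_cm total vessel height (cm), > 0.
#' @param max_diameter_cm maximal diameter (cm), > 0.
#' @param max_diameter_rel_height fraction of `height_cm` at which the
#'   diameter is maximal; strictly inside (0, 1).
#' @param aperture_radius_cm outer radius at the aperture (cm);
#'   at most `max_diameter_cm / 2`.
#' @param base_radius_cm radius at the base (cm); at most
#'   `max_diameter_cm / 2`.
#' @param bulge_exponent positive shape exponent; 2 gives circular
#'   (superelliptic) arcs, larger values give fuller, boxier walls.
#' @param rim_depth_cm nonnegative outward rim bulge (cm) applied over the
#'   top tenth of the wall; 0 disables the rim.
#'
#' @return An object of class `vessel_params` (a named list).
#' @examples
#' vessel_params(16, 14, 0.45, 2.5, 3)
#' @export
vessel_params <- function(height_cm, max_diameter_cm, max_diameter_rel_height,
                          aperture_radius_cm, base_radius_cm,
                          bulge_exponent = 2, rim_depth_cm = 0) {
  p <- structure(list(
    height_cm = as.numeric(height_cm),
    max_diameter_cm = as.numeric(max_diameter_cm),
    max_diameter_rel_height = as.numeric(max_diameter_rel_height),
    aperture_radius_cm = as.numeric(aperture_radius_cm),
    base_radius_cm = as.numeric(base_radius_cm),
    bulge_exponent = as.numeric(bulge_exponent),
    rim_depth_cm = as.numeric(rim_depth_cm)
  ), class = "vessel_params")
  validate_vessel_params(p)
  p
}

validate_vessel_params <- function(p) {
  if (!is.finite(p$height_cm) || p$height_cm <= 0)
    stop("invalid vessel_params: height_cm must be > 0", call. = FALSE)
  if (!is.finite(p$max_diameter_cm) || p$max_diameter_cm <= 0)
    stop("invalid vessel_params: max_diameter_cm must be > 0", call. = FALSE)
  if (p$max_diameter_rel_height <= 0 || p$max_diameter_rel_height >= 1)
    stop("invalid vessel_params: max_diameter_rel_height must lie strictly in (0, 1)",
         call. = FALSE)
  if (p$aperture_radius_cm < 0 ||
      p$aperture_radius_cm > p$max_diameter_cm / 2 + 1e-12)
    stop("invalid vessel_params: aperture_radius_cm must lie in [0, max_diameter_cm/2]",
         call. = FALSE)
  if (p$base_radius_cm < 0 ||
      p$base_radius_cm > p$max_diameter_cm / 2 + 1e-12)
    stop("invalid vessel_params: base_radius_cm must lie in [0, max_diameter_cm/2]",
         call. = FALSE)
  if (!is.finite(p$bulge_exponent) || p$bulge_exponent <= 0)
    stop("invalid vessel_params: bulge_exponent must be > 0", call. = FALSE)
  if (p$rim_depth_cm < 0)
    stop("invalid vessel_params: rim_depth_cm must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.vessel_params <- function(x, ...) {
  cat(sprintf(
    "vessel_params: H %.2f cm, MD %.2f cm (at %.0f%% height), aperture r %.2f, base r %.2f, k %.2f, rim %.2f\n",
    x$height_cm, x$max_diameter_cm, 100 * x$max_diameter_rel_height,
    x$aperture_radius_cm, x$base_radius_cm, x$bulge_exponent, x$rim_depth_cm))
  invisible(x)
}

# internal: vessel_params <-> numeric vector, for route interpolation
PARAM_FIELDS <- c("height_cm", "max_diameter_cm", "max_diameter_rel_height",
                  "aperture_radius_cm", "base_radius_cm", "bulge_exponent",
                  "rim_depth_cm")

params_to_vector <- function(p) {
  vapply(PARAM_FIELDS, function(f) p[[f]], numeric(1))
}

# Clamp a parameter vector back into the valid domain (used after noise).
vector_to_params <- function(v) {
  v <- as.numeric(v)
  names(v) <- PARAM_FIELDS
  v["height_cm"] <- max(v["height_cm"], 1e-3)
  v["max_diameter_cm"] <- max(v["max_diameter_cm"], 1e-3)
  v["max_diameter_rel_height"] <- min(max(v["max_diameter_rel_height"], 0.02), 0.98)
  r_max <- v["max_diameter_cm"] / 2
  v["aperture_radius_cm"] <- min(max(v["aperture_radius_cm"], 0), r_max)
  v["base_radius_cm"] <- min(max(v["base_radius_cm"], 0), r_max)
  v["bulge_exponent"] <- max(v["bulge_exponent"], 0.1)
  v["rim_depth_cm"] <- max(v["rim_depth_cm"], 0)
  vessel_params(v["height_cm"], v["max_diameter_cm"],
                v["max_diameter_rel_height"], v["aperture_radius_cm"],
                v["base_radius_cm"], v["bulge_exponent"], v["rim_depth_cm"])
}

#' Potter archetype for the synthetic-data generator
#'
#' Describes one simulated individual: an idiosyncratic pre-formed shape,
#' an optional sequence of intermediate waypoint shapes (the individual's
#' morphogenetic route), the number and timing of fashioning gestures, a
#' small individual signature applied to the shared final form, and the
#' trial-to-trial noise level.
#'
#' @param potter_id label identifying the individual.
#' @param community label of the individual's community of practice.
#' @param preform_params [vessel_params()] of the pre-formed shape (the
#'   clay body at the end of centring/opening, stage at t = 0).
#' @param route_waypoints list of [vessel_params()] giving intermediate
#'   targets between pre-form and final shape; may be empty.
#' @param n_gestures_range integer vector `c(min, max)` of fashioning
#'   gestures per trial; must lie within \[3, 20\].
#' @param gesture_interval_s `c(shape, scale)` of the gamma distribution
#'   of inter-gesture intervals, seconds.
#' @param final_offset_scale relative scale of the potter's persistent
#'   signature on the shared final form (multiplicative, per parameter).
#' @param trial_noise_scale relative scale of per-stage multiplicative
#'   Gaussian noise on shape parameters.
#'
#' @return An object of class `potter_archetype`.
#' @export
potter_archetype <- function(potter_id, community, preform_params,
                             route_waypoints = list(),
                             n_gestures_range = c(6L, 9L),
                             gesture_interval_s = c(4, 3),
                             final_offset_scale = 0.02,
                             trial_noise_scale = 0.03) {
  stopifnot(length(n_gestures_range) == 2, length(gesture_interval_s) == 2)
  n_gestures_range <- as.integer(round(n_gestures_range))
  if (n_gestures_range[1] < 3L || n_gestures_range[2] > 20L ||
      n_gestures_range[1] > n_gestures_range[2])
    stop("n_gestures_range must be an increasing interval within [3, 20]",
         call. = FALSE)
  if (final_offset_scale < 0 || trial_noise_scale < 0)
    stop("noise scales must be >= 0", call. = FALSE)
  if (any(gesture_interval_s <= 0))
    stop("gesture_interval_s (shape, scale) must be positive", call. = FALSE)
  validate_vessel_params(preform_params)
  lapply(route_waypoints, validate_vessel_params)
  structure(list(
    potter_id = as.character(potter_id),
    community = as.character(community),
    preform_params = preform_params,
    route_waypoints = route_waypoints,
    n_gestures_range = n_gestures_range,
    gesture_interval_s = as.numeric(gesture_interval_s),
    final_offset_scale = as.numeric(final_offset_scale),
    trial_noise_scale = as.numeric(trial_noise_scale)
  ), class = "potter_archetype")
}

#' Study configuration for the synthetic-data generator
#'
#' @param vessel_types named list: one shared final [vessel_params()] per
#'   vessel-type label.
#' @param archetypes list of [potter_archetype()] (unique ids, >= 2).
#' @param n_trials_per_type trials thrown per potter and type (>= 2).
#' @param seed master integer seed; all per-trial seeds derive from it.
#'
#' @return An object of class `study_config`.
#' @seealso [default_study_config()] for the packaged study conditions.
#' @export
study_config <- function(vessel_types, archetypes, n_trials_per_type = 5L,
                         seed = 1L) {
  if (length(archetypes) < 2)
    stop("at least 2 archetypes are required", call. = FALSE)
  ids <- vapply(archetypes, function(a) a$potter_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate potter_id in archetypes: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (is.null(names(vessel_types)) || any(names(vessel_types) == ""))
    stop("vessel_types must be a named list of vessel_params", call. = FALSE)
  lapply(vessel_types, validate_vessel_params)
  n_trials_per_type <- as.integer(n_trials_per_type)
  if (n_trials_per_type < 2)
    stop("n_trials_per_type must be >= 2", call. = FALSE)
  structure(list(
    vessel_types = vessel_types,
    archetypes = archetypes,
    n_trials_per_type = n_trials_per_type,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Default synthetic study conditions
#'
#' Seven expert potters in two communities of practice (four in the first
#' workshop, three in the second), each throwing five specimens of a
#' money-bank-like vessel: a rounded, nearly closed final form roughly
#' 16 cm high and 14 cm in maximal diameter. Pre-formed shapes differ
#' markedly across potters (cylindrical, barrel-like, sphere-like with a
#' wide aperture, ...), gesture counts per trial span 5 to 12 depending on
#' the potter, and inter-gesture intervals are gamma distributed so trial
#' durations fall in roughly 60 to 160 seconds. The shared final form
#' carries a small per-potter signature (`final_offset_scale = 0.02`)
#' against substantial pre-form spread, so among-potter shape variation
#' shrinks from the pre-formed to the final stage.
#'
#' @param seed master seed for the study.
#' @param n_trials_per_type trials per potter and vessel type.
#' @return A [study_config()].
#' @export
default_study_config <- function(seed = 1L, n_trials_per_type = 5L) {
  final_bank <- vessel_params(16, 14, 0.45, 2.5, 3.0, 2.2, 0.3)
  pre <- list(
    # near-cylindrical pre-form, rimmed wide aperture
    P1 = potter_archetype("P1", "workshop1",
      vessel_params(11, 10, 0.50, 4.6, 4.8, 6.0, 0.4),
      n_gestures_range = c(6, 9)),
    # elongated barrel
    P2 = potter_archetype("P2", "workshop1",
      vessel_params(13, 9, 0.55, 3.6, 3.4, 2.8, 0.2),
      n_gestures_range = c(6, 9)),
    # squat open bowl-like pre-form, slow and variable worker
    P3 = potter_archetype("P3", "workshop1",
      vessel_params(8, 12, 0.35, 5.2, 4.0, 1.6, 0.2),
      n_gestures_range = c(8, 12), gesture_interval_s = c(5, 3.2),
      trial_noise_scale = 0.05),
    # narrows the aperture early: pre-form already close to final
    P4 = potter_archetype("P4", "workshop1",
      vessel_params(12, 11, 0.45, 3.2, 3.2, 2.2, 0.3),
      n_gestures_range = c(5, 6), gesture_interval_s = c(16, 0.75)),
    # wide barrel with sharp belly curve
    P5 = potter_archetype("P5", "workshop2",
      vessel_params(10, 12, 0.40, 4.8, 4.2, 3.5, 0.3),
      n_gestures_range = c(6, 9), gesture_interval_s = c(9, 1.0)),
    # small, less pronounced cylinder
    P6 = potter_archetype("P6", "workshop2",
      vessel_params(9, 8, 0.50, 3.4, 3.2, 4.0, 0.2),
      n_gestures_range = c(6, 9)),
    # large sphere-like pre-form, wide rimmed aperture, many gestures
    P7 = potter_archetype("P7", "workshop2",
      vessel_params(12, 13, 0.42, 5.5, 3.6, 2.0, 0.5),
      n_gestures_range = c(10, 11))
  )
  study_config(vessel_types = list(money_bank = final_bank),
               archetypes = unname(pre),
               n_trials_per_type = n_trials_per_type, seed = seed)
}
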
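# Staged-trial simulation: each simulated throw interpolates a potter's
# idiosyncratic route through vessel-parameter space, from the pre-formed
# shape via optional waypoints to the shared final form carrying a small
# persistent per-potter signature, with multiplicative per-stage noise.

# Deterministic 31-bit seed from arbitrary labels (FNV-style fold).
hash_seed <- function(...) {
  parts <- paste(vapply(list(...), as.character, character(1)),
                 collapse = "\x1f")
  h <- 0
  for (c in utf8ToInt(parts)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Run code under a local RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Piecewise-linear interpolation through route control points (rows) at
# fractional position s in [0, 1].
route_interpolate <- function(ctrl, s) {
  K <- nrow(ctrl)
  if (K == 1) return(ctrl[1, ])
  pos <- seq(0, 1, length.out = K)
  apply(ctrl, 2, function(col) stats::approx(pos, col, xout = s)$y)
}

#' Simulate one staged vessel throw
#'
#' Generates a complete trial for one potter archetype: the stage-0
#' pre-formed shape, intermediate stages interpolating the potter's route
#' (pre-form, waypoints, final form plus the potter's signature offset) in
#' parameter space with per-stage multiplicative Gaussian noise, and
#' cumulative gamma-distributed gesture times. The potter's final-form
#' signature is derived deterministically from the potter id, so it is
#' consistent across trials and studies. Identical seeds give identical
#' trials.
#'
#' @param arch a [potter_archetype()].
#' @param final shared final-form [vessel_params()] for the vessel type.
#' @param seed integer seed for this trial.
#' @param n_points profile points per stage.
#' @return A `vessel_trial`: list with `potter_id`, `community`,
#'   `vessel_type` (NA here; filled by [simulate_study()]) and `stages`, a
#'   list of `(gesture_index, time_s, profile)` with gesture index 0 (the
#'   pre-form, t = 0) through the final gesture.
#' @export
simulate_trial <- function(arch, final, seed, n_points = 256L) {
  validate_vessel_params(final)
  with_local_seed(as.integer(seed), {
    n_g <- if (arch$n_gestures_range[1] == arch$n_gestures_range[2])
      arch$n_gestures_range[1]
    else sample(arch$n_gestures_range[1]:arch$n_gestures_range[2], 1)

    final_vec <- params_to_vector(final)
    if (arch$final_offset_scale > 0) {
      z <- with_local_seed(hash_seed("signature", arch$potter_id),
                           stats::rnorm(length(final_vec)))
      final_vec <- final_vec * (1 + arch$final_offset_scale * z)
    }
    ctrl <- rbind(params_to_vector(arch$preform_params))
    for (w in arch$route_waypoints) ctrl <- rbind(ctrl, params_to_vector(w))
    ctrl <- rbind(ctrl, final_vec)

    times <- cumsum(c(0, stats::rgamma(n_g, shape = arch$gesture_interval_s[1],
                                       scale = arch$gesture_interval_s[2])))
    stages <- vector("list", n_g + 1)
    for (j in 0:n_g) {
      theta <- route_interpolate(ctrl, j / n_g)
      if (arch$trial_noise_scale > 0)
        theta <- theta * (1 + arch$trial_noise_scale * stats::rnorm(length(theta)))
      stages[[j + 1]] <- list(
        gesture_index = j,
        time_s = times[j + 1],
        profile = make_profile(vector_to_params(theta), n_points))
    }
    structure(list(potter_id = arch$potter_id, community = arch$community,
                   vessel_type = NA_character_, trial_id = NA_character_,
                   stages = stages),
              class = "vessel_trial")
  })
}

#' @export
print.vessel_trial <- function(x, ...) {
  cat(sprintf("vessel_trial %s: potter %s (%s), type %s, %d stages over %.1f s\n",
              x$trial_id, x$potter_id, x$community, x$vessel_type,
              length(x$stages), x$stages[[length(x$stages)]]$time_s))
  invisible(x)
}

#' Simulate a full staged-throwing study
#'
#' Produces the full factorial dataset: every archetype throws
#' `n_trials_per_type` specimens of every vessel type. Per-trial seeds are
#' derived deterministically from the master seed and the (potter, type,
#' trial) labels, so any subset of the study is reproducible in isolation.
#'
#' @param config a [study_config()].
#' @param n_points profile points per stage.
#' @return A `vessel_study`: list with `trials` (list of `vessel_trial`),
#'   the `config`, and `provenance` (seed, generator version).
#' @examples
#' study <- simulate_study(default_study_config(seed = 7, n_trials_per_type = 2),
#'                         n_points = 64)
#' length(study$trials)  # 7 potters x 1 type x 2 trials
#' @export
simulate_study <- function(config, n_points = 256L) {
  stopifnot(inherits(config, "study_config"))
  trials <- list()
  for (type in names(config$vessel_types)) {
    final <- config$vessel_types[[type]]
    for (arch in config$archetypes) {
      for (i in seq_len(config$n_trials_per_type)) {
        seed_i <- hash_seed(config$seed, arch$potter_id, type, i)
        tr <- simulate_trial(arch, final, seed_i, n_points = n_points)
        tr$vessel_type <- type
        tr$trial_id <- sprintf("%s_%s_t%02d", type, arch$potter_id, i)
        trials[[length(trials) + 1]] <- tr
      }
    }
  }
  structure(list(trials = trials, config = config,
                 provenance = list(seed = config$seed,
                                   generator = "vesselmorph",
                                   version = "0.1.0")),
            class = "vessel_study")
}

#' @export
print.vessel_study <- function(x, ...) {
  cat(sprintf("vessel_study: %d trials (%d potters x %d types x %d trials), seed %d\n",
              length(x$trials), length(x$config$archetypes),
              length(x$config$vessel_types), x$config$n_trials_per_type,
              x$provenance$seed))
  invisible(x)
}
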
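# Size metrics of staged profiles, coefficients of variation, and the
# 20-bin normalized-time representation of trials.

#' Size metrics of a vessel profile
#'
#' Height, maximal diameter and exterior surface area (ESA) of the
#' axisymmetric solid generated by revolving the profile about the
#' vertical axis. ESA is the lateral area of the surface of revolution,
#' accumulated as the sum of frustum lateral areas
#' `pi * (x_i + x_{i+1}) * slant_i` over consecutive profile points; the
#' base and rim discs are excluded. ESA serves as the overall measure of
#' vessel size.
#'
#' @param p a resampled `vessel_profile` (>= 2 points).
#' @return A one-row data frame with `height_cm`, `max_diameter_cm`,
#'   `esa_cm2`.
#' @examples
#' cyl <- data.frame(x = rep(2, 50), y = seq(0, 10, length.out = 50))
#' size_metrics(cyl)$esa_cm2  # 2 * pi * 2 * 10
#' @export
size_metrics <- function(p) {
  validate_profile(p)
  x <- p$x; y <- p$y
  n <- length(x)
  slant <- sqrt(diff(x)^2 + diff(y)^2)
  esa <- sum(pi * (x[-n] + x[-1]) * slant)
  data.frame(height_cm = max(y) - min(y),
             max_diameter_cm = 2 * max(x),
             esa_cm2 = esa)
}

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample (n - 1) standard deviation, in
#' percent.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(8, 10, 12))  # 20
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2)
    stop("coefficient_of_variation needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0)
    stop("coefficient of variation undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Assign trial stages to normalized time bins
#'
#' Divides the span between the first and last fashioning gesture of a
#' trial into `n_bins` equally spaced bins and maps each stage to the bin
#' its time falls in: for stage time s,
#' `bin = min(n_bins, floor(n_bins * (s - t_first) / (t_last - t_first)) + 1)`.
#' Intervals are left-closed; the last stage is clamped into the final
#' bin, so the first stage always lands in bin 1 and the last in
#' `n_bins`.
#'
#' @param trial a `vessel_trial` (>= 2 stages, strictly increasing times).
#' @param n_bins number of bins (default 20).
#' @return Data frame with `trial_id`, `stage_index`, `time_s`, `bin`, and
#'   the stage's size metrics (`height_cm`, `max_diameter_cm`, `esa_cm2`).
#' @export
assign_time_bins <- function(trial, n_bins = 20L) {
  stopifnot(inherits(trial, "vessel_trial"))
  times <- vapply(trial$stages, function(s) s$time_s, numeric(1))
  if (length(times) < 2)
    stop("trial has fewer than 2 stages", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("stage times must be strictly increasing", call. = FALSE)
  span <- times[length(times)] - times[1]
  if (span <= 0)
    stop("degenerate trial: zero duration", call. = FALSE)
  bins <- pmin(n_bins, floor(n_bins * (times - times[1]) / span) + 1L)
  metrics <- do.call(rbind, lapply(trial$stages,
                                   function(s) size_metrics(s$profile)))
  cbind(data.frame(trial_id = trial$trial_id,
                   stage_index = vapply(trial$stages,
                                        function(s) s$gesture_index,
                                        numeric(1)),
                   time_s = times, bin = as.integer(bins)),
        metrics)
}

#' Size metrics and time bins for every stage of a study
#'
#' @param study a `vessel_study`.
#' @param n_bins number of time bins per trial.
#' @return Tidy data frame: one row per stage with trial keys (`trial_id`,
#'   `potter_id`, `community`, `vessel_type`), `stage_index`, `time_s`,
#'   `bin`, and the size metrics.
#' @export
study_size_table <- function(study, n_bins = 20L) {
  stopifnot(inherits(study, "vessel_study"))
  rows <- lapply(study$trials, function(tr) {
    b <- assign_time_bins(tr, n_bins)
    cbind(data.frame(potter_id = tr$potter_id, community = tr$community,
                     vessel_type = tr$vessel_type), b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("trial_id", "potter_id", "community", "vessel_type",
          "stage_index", "time_s", "bin",
          "height_cm", "max_diameter_cm", "esa_cm2")]
}

#' Per-potter means and coefficients of variation of final dimensions
#'
#' Summarizes final-stage vessel dimensions across a potter's trials,
#' one row per potter x vessel type x metric, in the conventional
#' mean (CV) layout of vessel-standardization tables.
#'
#' @param study a `vessel_study`.
#' @return Data frame with `vessel_type`, `community`, `potter_id`,
#'   `metric`, `mean`, `cv_pct`, `n_trials`.
#' @export
final_dimension_table <- function(study) {
  tab <- study_size_table(study)
  fin <- do.call(rbind, lapply(split(tab, tab$trial_id), function(d)
    d[which.max(d$stage_index), ]))
  out <- list()
  for (m in c("height_cm", "max_diameter_cm", "esa_cm2")) {
    agg <- stats::aggregate(fin[[m]],
      by = list(vessel_type = fin$vessel_type, community = fin$community,
                potter_id = fin$potter_id),
      FUN = function(v) c(mean = mean(v),
                          cv = coefficient_of_variation(v), n = length(v)))
    out[[m]] <- data.frame(agg[1:3], metric = m,
                           mean = agg$x[, "mean"], cv_pct = agg$x[, "cv"],
                           n_trials = as.integer(agg$x[, "n"]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$vessel_type, res$community, res$potter_id, res$metric), ]
}
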
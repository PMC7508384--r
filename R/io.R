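# Serialization of staged studies: one CSV of profile points per stage
# plus one JSON metadata file. The CSV dialect (trial_id, stage_index,
# time_s, point_index, x_cm, y_cm) is shared by the generator and the
# pipeline reader.

fmt_num <- function(v) sprintf("%.17g", v)

#' Write a study to a points CSV and a metadata JSON
#'
#' @param study a `vessel_study`.
#' @param points_csv path of the profile-points CSV.
#' @param meta_json path of the metadata JSON (potters, communities,
#'   types, seed, provenance).
#' @return Invisibly, the two paths.
#' @export
write_study <- function(study, points_csv, meta_json) {
  stopifnot(inherits(study, "vessel_study"))
  rows <- lapply(study$trials, function(tr) {
    do.call(rbind, lapply(tr$stages, function(st) {
      data.frame(trial_id = tr$trial_id,
                 stage_index = st$gesture_index,
                 time_s = fmt_num(st$time_s),
                 point_index = seq_len(nrow(st$profile)) - 1L,
                 x_cm = fmt_num(st$profile$x),
                 y_cm = fmt_num(st$profile$y))
    }))
  })
  utils::write.csv(do.call(rbind, rows), points_csv, row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    trials = lapply(study$trials, function(tr)
      list(trial_id = tr$trial_id, potter_id = tr$potter_id,
           community = tr$community, vessel_type = tr$vessel_type)),
    seed = study$provenance$seed,
    generator = study$provenance$generator,
    version = study$provenance$version)
  jsonlite::write_json(meta, meta_json, auto_unbox = TRUE, digits = NA)
  invisible(c(points_csv, meta_json))
}

#' Read a study from a points CSV and a metadata JSON
#'
#' Inverse of [write_study()]; validates the trial invariants (strictly
#' increasing stage times, >= 2 stages, profile geometry) and reports the
#' offending trial on failure.
#'
#' @param points_csv,meta_json paths written by [write_study()], or any
#'   files in the same dialect.
#' @return A `vessel_study`.
#' @export
read_outlines <- function(points_csv, meta_json) {
  pts <- utils::read.csv(points_csv, stringsAsFactors = FALSE,
                         na.strings = character(0))
  need <- c("trial_id", "stage_index", "time_s", "point_index",
            "x_cm", "y_cm")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop("schema error: points CSV is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(pts) == 0)
    stop("empty input: points CSV contains no rows", call. = FALSE)
  meta <- jsonlite::read_json(meta_json, simplifyVector = FALSE)
  trials <- list()
  for (m in meta$trials) {
    d <- pts[pts$trial_id == m$trial_id, , drop = FALSE]
    if (nrow(d) == 0)
      stop("trial ", m$trial_id, " has no points in the CSV", call. = FALSE)
    stage_ids <- sort(unique(d$stage_index))
    if (length(stage_ids) < 2)
      stop("trial ", m$trial_id, " has fewer than 2 stages", call. = FALSE)
    stages <- lapply(stage_ids, function(si) {
      s <- d[d$stage_index == si, , drop = FALSE]
      s <- s[order(s$point_index), , drop = FALSE]
      prof <- new_profile(as.numeric(s$x_cm), as.numeric(s$y_cm))
      tryCatch(validate_profile(prof),
               error = function(e) stop("trial ", m$trial_id, ", stage ",
                                        si, ": ", conditionMessage(e),
                                        call. = FALSE))
      list(gesture_index = si, time_s = as.numeric(s$time_s[1]),
           profile = prof)
    })
    times <- vapply(stages, function(s) s$time_s, numeric(1))
    if (any(diff(times) <= 0))
      stop("validation error: non-monotone stage times in trial ",
           m$trial_id, call. = FALSE)
    trials[[length(trials) + 1]] <- structure(
      list(potter_id = m$potter_id, community = m$community,
           vessel_type = m$vessel_type, trial_id = m$trial_id,
           stages = stages),
      class = "vessel_trial")
  }
  if (length(trials) == 0)
    stop("empty input: metadata lists no trials", call. = FALSE)
  structure(list(trials = trials, config = NULL,
                 provenance = list(seed = meta$seed,
                                   generator = meta$generator,
                                   version = meta$version)),
            class = "vessel_study")
}

#' Published final-dimension summary table
#'
#' Means and coefficients of variation (percent, across five trials per
#' potter) of final vessel height, maximal diameter and exterior surface
#' area, for seven expert potters from two traditional workshops (four
#' Prajapati, three Multani Kumhar potters) throwing five traditional
#' vessel types. Shipped as a plain-text table; used to reconstruct
#' summary-level ANOVAs.
#'
#' @param vessel_type optional filter (e.g. `"money_bank"`).
#' @return Data frame with `vessel_type`, `community`, `potter_id`,
#'   `metric`, `mean`, `cv_pct`, `n_trials`.
#' @export
final_dimension_summary <- function(vessel_type = NULL) {
  path <- system.file("extdata", "final_dimension_summary.csv",
                      package = "vesselmorph", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  if (!is.null(vessel_type)) tab <- tab[tab$vessel_type %in% vessel_type, ]
  tab
}
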
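# End-to-end orchestration: simulate or ingest a staged study, process
# outlines, run EFA and the shape-space construction, and produce the
# full battery of statistics as a structured report.

#' Run the full morphogenesis analysis pipeline
#'
#' Executes, in order: study acquisition (synthetic simulation from a
#' [study_config()], or a pre-loaded `vessel_study`), per-stage size
#' metrics and 20-bin time normalization, elliptical Fourier analysis
#' with first-harmonic size normalization, PCA shape-space construction
#' over all stages pooled, trajectory projection, per-vessel-type
#' permutation tests on the pre-formed and final coefficients (pooled and
#' per community), the growth-model comparison chain on exterior surface
#' area, and the Stage linear mixed model on shape-space distances.
#' Deterministic for a fixed config and seed.
#'
#' @param config a [study_config()] (simulated input) or a
#'   `vessel_study` (pre-loaded input).
#' @param out_dir optional directory; when given, intermediate CSVs and
#'   the JSON report are written there via [write_report()].
#' @param n_points profile resampling density (default 256).
#' @param n_harmonics EFA harmonics (default 20).
#' @param smooth_cutoff low-pass cutoff for [smooth_profile()], or `NULL`
#'   to skip smoothing (synthetic profiles are already smooth).
#' @param k shape-space components retained (default 3).
#' @param n_permutations permutations per test (default 9999).
#' @param seed seed for the permutation streams; defaults to the config
#'   seed (or 1 for pre-loaded studies).
#' @return An `analysis_report`: list with `dimensions` (per-potter final
#'   means/CVs), `permanova` (per type x stage x grouping), `growth`
#'   (model chain per type), `stage_lmm` (per type x grouping),
#'   `variance_explained`, `scores`, `distances`, `provenance`.
#' @export
run_pipeline <- function(config = default_study_config(), out_dir = NULL,
                         n_points = 256L, n_harmonics = 20L,
                         smooth_cutoff = NULL, k = 3L,
                         n_permutations = 9999L, seed = NULL) {
  if (inherits(config, "vessel_study")) {
    study <- config
    if (is.null(seed)) seed <- 1L
  } else {
    study <- simulate_study(config, n_points = n_points)
    if (is.null(seed)) seed <- config$seed
  }
  if (length(study$trials) == 0)
    stop("empty input: study contains no trials", call. = FALSE)

  size_tab <- study_size_table(study)
  dims <- final_dimension_table(study)
  coefs <- study_coefficients(study, n_harmonics = n_harmonics,
                              smooth_cutoff = smooth_cutoff,
                              n_points = n_points)
  cc <- coeff_columns(coefs)
  space <- fit_shape_space(coefs[, cc], n_components = k)
  scores <- study_scores(space, coefs, k = k)

  types <- unique(coefs$vessel_type)
  perm <- list(); lmm <- list(); growth <- list(); dists <- list()
  for (ty in types) {
    sub <- coefs[coefs$vessel_type == ty, , drop = FALSE]
    for (st in c("pre_formed", "final")) {
      ss <- sub[sub$stage == st, , drop = FALSE]
      groupings <- c(list(pooled = rep(TRUE, nrow(ss))),
                     stats::setNames(lapply(unique(ss$community),
                                            function(cm) ss$community == cm),
                                     unique(ss$community)))
      for (g in names(groupings)) {
        rows <- ss[groupings[[g]], , drop = FALSE]
        if (length(unique(rows$potter_id)) < 2) next
        perm[[paste(ty, st, g, sep = ".")]] <- permanova(
          rows[, cc], rows$potter_id,
          n_permutations = n_permutations,
          seed = hash_seed(seed, ty, st, g))
      }
    }
    growth[[ty]] <- growth_model_chain(
      size_tab[size_tab$vessel_type == ty, , drop = FALSE])

    sc_ty <- scores[scores$vessel_type == ty, , drop = FALSE]
    d_pool <- rbind(stage_distances(sc_ty, "pre_formed"),
                    stage_distances(sc_ty, "final"))
    d_comm <- rbind(stage_distances(sc_ty, "pre_formed",
                                    grouping = sc_ty$community),
                    stage_distances(sc_ty, "final",
                                    grouping = sc_ty$community))
    dists[[ty]] <- list(pooled = d_pool, per_community = d_comm)
    lmm[[paste(ty, "pooled", sep = ".")]] <- stage_lmm(d_pool)
    lmm[[paste(ty, "per_community", sep = ".")]] <- stage_lmm(d_comm)
  }

  report <- structure(list(
    dimensions = dims,
    permanova = perm,
    growth = growth,
    stage_lmm = lmm,
    variance_explained = space$var_explained,
    size_table = size_tab,
    coefficients = coefs,
    scores = scores,
    distances = dists,
    shape_space = space,
    provenance = list(seed = seed, n_points = n_points,
                      n_harmonics = n_harmonics, k = k,
                      n_permutations = n_permutations,
                      smooth_cutoff = smooth_cutoff,
                      n_trials = length(study$trials))),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  cat(sprintf("  %d trials; PC1-3 variance: %s\n",
              x$provenance$n_trials,
              paste(sprintf("%.1f%%", 100 * x$variance_explained[1:3]),
                    collapse = ", ")))
  for (nm in names(x$permanova)) {
    p <- x$permanova[[nm]]
    cat(sprintf("  permanova %-32s R2 = %.3f, p = %.4g\n", nm,
                p$r_squared_among, p$p_value))
  }
  for (nm in names(x$stage_lmm)) {
    l <- x$stage_lmm[[nm]]
    cat(sprintf("  stage LMM %-32s F(%d,%d) = %.4g, p = %.4g\n", nm,
                l$df_num, l$df_den, l$F, l$p_value))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes tidy CSVs of every stage output (size table, coefficients,
#' scores, distances, dimension summary) plus a JSON report of the test
#' results and provenance.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$size_table, "size_table.csv")
  wr(report$dimensions, "final_dimensions.csv")
  wr(report$coefficients, "coefficients.csv")
  wr(report$scores, "scores.csv")
  for (ty in names(report$distances)) {
    wr(report$distances[[ty]]$pooled,
       paste0("distances_", ty, "_pooled.csv"))
    wr(report$distances[[ty]]$per_community,
       paste0("distances_", ty, "_per_community.csv"))
  }
  json <- list(
    variance_explained = report$variance_explained[1:min(10,
      length(report$variance_explained))],
    permanova = lapply(report$permanova, function(p)
      p[c("pseudo_F", "r_squared_among", "r_squared_residual", "p_value",
          "df_among", "df_residual", "n_permutations", "exact")]),
    growth = lapply(report$growth, function(g) list(
      log_lik = lapply(g$models, function(m) m$log_lik),
      tests = lapply(g$tests, function(t)
        list(chi_square = t$chi_square, df = t$df, p_value = t$p_value)))),
    stage_lmm = lapply(report$stage_lmm, function(l)
      list(estimate = l$estimate, F = l$F, df_num = l$df_num,
           df_den = l$df_den, p_value = l$p_value,
           potter_intercept_sd = l$potter_intercept_sd,
           stratum_residual_sd = as.list(l$stratum_residual_sd))),
    provenance = report$provenance)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p))
}
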
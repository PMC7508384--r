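# Linear mixed model on shape-space distances: fixed Stage effect
# (pre-formed vs final), random per-potter intercept, heteroscedastic
# residual variance per stratum.

#' Stage effect on shape-space distances
#'
#' Fits `distance ~ stage` with a random intercept per potter and, by
#' default, a separate residual variance per potter stratum
#' (`nlme::varIdent`), by maximum likelihood. The reported F-test for
#' Stage uses the within-group denominator degrees of freedom convention
#' of `nlme` (N - potters - 1 for the two-stage design).
#'
#' @param distances data frame with columns `distance`, `stage` (exactly
#'   2 levels) and `potter_id`; typically rows of [stage_distances()] at
#'   the two stages bound together.
#' @param stratum which stratum carries its own residual SD: `"potter"`
#'   (default), `"stage"`, `"potter_stage"`, or `"none"` for a single
#'   residual variance.
#' @param random_intercept include the per-potter random intercept;
#'   disabling it together with `stratum = "none"` reduces the model to
#'   the classical two-sample linear model.
#' @return A `stage_lmm_result`: `estimate` (stage contrast), `F`,
#'   `df_num`, `df_den`, `p_value`, `potter_intercept_sd`,
#'   `stratum_residual_sd` (named vector), `fit`.
#' @export
stage_lmm <- function(distances, stratum = c("potter", "stage",
                                             "potter_stage", "none"),
                      random_intercept = TRUE) {
  stratum <- match.arg(stratum)
  need <- c("distance", "stage", "potter_id")
  miss <- setdiff(need, names(distances))
  if (length(miss))
    stop("distances data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data.frame(distance = distances$distance,
                  stage = factor(distances$stage),
                  potter = factor(distances$potter_id))
  if (nlevels(d$stage) != 2)
    stop("stage must have exactly 2 levels", call. = FALSE)
  per_stage <- table(d$potter, d$stage)
  if (any(per_stage == 0))
    warning("unbalanced design: some potters observed at only one stage")
  d$potter_stage <- interaction(d$potter, d$stage, drop = TRUE)

  if (!random_intercept && stratum == "none") {
    fit <- stats::lm(distance ~ stage, data = d)
    an <- stats::anova(fit)
    res <- list(estimate = unname(stats::coef(fit)[2]),
                F = an[["F value"]][1], df_num = an$Df[1], df_den = an$Df[2],
                p_value = an[["Pr(>F)"]][1],
                potter_intercept_sd = NA_real_,
                stratum_residual_sd = c(all = stats::sigma(fit)),
                fit = fit)
    return(structure(res, class = "stage_lmm_result"))
  }
  weights <- switch(stratum,
    none = NULL,
    potter = nlme::varIdent(form = ~ 1 | potter),
    stage = nlme::varIdent(form = ~ 1 | stage),
    potter_stage = nlme::varIdent(form = ~ 1 | potter_stage))
  args <- list(fixed = distance ~ stage, data = d,
               random = ~ 1 | potter, method = "ML",
               control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                          opt = "optim"))
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(nlme::lme, args)
  an <- stats::anova(fit)
  i <- rownames(an) == "stage"
  sds <- stats::sigma(fit)
  if (!is.null(weights)) {
    w <- nlme::varWeights(fit$modelStruct$varStruct)
    lv <- attr(fit$modelStruct$varStruct, "groups")
    sds <- stats::sigma(fit) / vapply(split(w, lv), function(v) v[1],
                                      numeric(1))
  } else sds <- c(all = sds)
  structure(list(
    estimate = unname(nlme::fixef(fit)[2]),
    F = an$`F-value`[i], df_num = an$numDF[i], df_den = an$denDF[i],
    p_value = an$`p-value`[i],
    potter_intercept_sd = sqrt(as.numeric(nlme::VarCorr(fit)[1, "Variance"])),
    stratum_residual_sd = sds, fit = fit),
    class = "stage_lmm_result")
}

#' @export
print.stage_lmm_result <- function(x, ...) {
  cat(sprintf("stage LMM: F(%d,%d) = %.4g, p = %.4g; stage contrast %.4g; potter intercept SD %.4g\n",
              x$df_num, x$df_den, x$F, x$p_value, x$estimate,
              x$potter_intercept_sd))
  invisible(x)
}
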
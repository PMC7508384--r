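# Growth-curve models of vessel size over normalized time: third-order
# orthogonal-polynomial fixed effects with optional per-potter random
# intercept / random time slopes, fitted by maximum likelihood so nested
# models can be compared with likelihood-ratio tests.

#' Fit a growth-curve model of size over time bins
#'
#' Models `esa_cm2` against an orthogonal polynomial (degree 3) of the
#' time bin, by maximum likelihood. The orthogonal basis is built by
#' [stats::poly()] (Gram-Schmidt on the observed bin values), so the
#' linear, quadratic and cubic trends are separable. Random-effects
#' structures, in increasing order of complexity: `"none"` (plain least
#' squares), `"intercept"` (per-potter random intercept), `"slopes"`
#' (random intercept plus random slopes on the three time terms, with an
#' unstructured 4x4 covariance). `community = TRUE` adds a community main
#' effect and its interactions with the three time terms (4 fixed-effect
#' parameters).
#'
#' @param binned data frame with columns `esa_cm2`, `bin`, `potter_id`
#'   and (if `community = TRUE`) `community`; typically from
#'   [study_size_table()].
#' @param random `"none"`, `"intercept"` or `"slopes"`.
#' @param community include community fixed effects.
#' @param degree polynomial degree (default 3).
#' @return A `growth_model`: list with the fitted model (`fit`),
#'   `log_lik`, `n_params`, `fixed` coefficients, `random`, `community`,
#'   `converged`.
#' @export
fit_growth_model <- function(binned, random = c("none", "intercept", "slopes"),
                             community = FALSE, degree = 3L) {
  random <- match.arg(random)
  need <- c("esa_cm2", "bin", "potter_id", if (community) "community")
  miss <- setdiff(need, names(binned))
  if (length(miss))
    stop("binned data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(binned$potter_id)) < 2)
    stop("need >= 2 potters", call. = FALSE)
  n_bins <- length(unique(binned$bin))
  if (degree > n_bins - 1)
    stop(sprintf("design error: degree %d needs > %d distinct bins",
                 degree, degree), call. = FALSE)
  d <- data.frame(esa = binned$esa_cm2,
                  potter = factor(binned$potter_id))
  P <- stats::poly(binned$bin, degree)
  colnames(P) <- paste0("ot", seq_len(degree))
  d <- cbind(d, as.data.frame(unclass(P)[, , drop = FALSE]))
  time_terms <- paste0("ot", seq_len(degree))
  fixed <- paste(time_terms, collapse = " + ")
  if (community) {
    d$community <- factor(binned$community)
    fixed <- paste0("community * (", fixed, ")")
  }
  converged <- TRUE
  if (random == "none") {
    fit <- stats::lm(stats::as.formula(paste("esa ~", fixed)), data = d)
    ll <- stats::logLik(fit)
  } else {
    re <- if (random == "intercept") "(1 | potter)"
          else paste0("(1 + ", paste(time_terms, collapse = " + "),
                      " | potter)")
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(paste("esa ~", fixed, "+", re)),
                 data = d, REML = FALSE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   calc.derivs = FALSE))))
    ll <- stats::logLik(fit)
    conv <- fit@optinfo$conv$opt
    converged <- is.null(conv) || conv == 0
  }
  structure(list(fit = fit, log_lik = as.numeric(ll),
                 n_params = attr(ll, "df"),
                 fixed = if (random == "none") stats::coef(fit)
                         else lme4::fixef(fit),
                 random = random, community = community,
                 degree = degree, converged = converged),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("growth_model: degree %d, random = %s%s; logLik %.2f (%d params)%s\n",
              x$degree, x$random,
              if (x$community) " + community fixed effects" else "",
              x$log_lik, x$n_params,
              if (x$converged) "" else " [did not converge]"))
  invisible(x)
}

#' Likelihood-ratio test between nested growth models
#'
#' Treats the change in deviance (-2 log likelihood) between two nested
#' maximum-likelihood fits of the same data as a chi-square statistic
#' with degrees of freedom equal to the difference in parameter counts.
#'
#' @param reduced,full `growth_model` fits, reduced nested in full.
#' @return An `lrt_result`: `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "growth_model"), inherits(full, "growth_model"))
  chi <- 2 * (full$log_lik - reduced$log_lik)
  if (chi < -1e-6)
    stop(sprintf("fit-quality error: full model log-likelihood (%.4f) is below the reduced model's (%.4f)",
                 full$log_lik, reduced$log_lik), call. = FALSE)
  chi <- max(chi, 0)
  df <- full$n_params - reduced$n_params
  if (df < 1) stop("models are not nested: full has no extra parameters",
                   call. = FALSE)
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("likelihood ratio test: chi-square(%d) = %.4g, p = %.4g\n",
              x$df, x$chi_square, x$p_value))
  invisible(x)
}

#' Growth-model comparison chain
#'
#' Fits the standard model sequence (no random effects, random potter
#' intercept, random intercept + time slopes, + community fixed effects)
#' and the likelihood-ratio test between each consecutive pair.
#'
#' @param binned as in [fit_growth_model()].
#' @return List with `models` and `tests` (named `intercept`, `slopes`,
#'   `community`).
#' @export
growth_model_chain <- function(binned) {
  m0 <- fit_growth_model(binned, "none")
  m1 <- fit_growth_model(binned, "intercept")
  m2 <- fit_growth_model(binned, "slopes")
  m3 <- fit_growth_model(binned, "slopes", community = TRUE)
  list(models = list(none = m0, intercept = m1, slopes = m2,
                     community = m3),
       tests = list(intercept = likelihood_ratio_test(m0, m1),
                    slopes = likelihood_ratio_test(m1, m2),
                    community = likelihood_ratio_test(m2, m3)))
}
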
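# Community comparisons of final vessel dimensions: mixed-design
# (Community x Trial) ANOVA with generalized eta-squared, one-way ANOVA
# reconstruction from published summary statistics, and Pearson
# correlations with Fisher-z confidence intervals.

#' Community effect on final vessel dimensions
#'
#' Mixed-design ANOVA with the between-subject factor Community (subjects
#' are potters) and repeated measures over Trial. The Community F uses
#' the potters-within-community mean square as its error term, so with
#' balanced trials it equals the one-way F computed on potter means. The
#' effect size is generalized eta-squared: effect SS over effect SS plus
#' all error SS (subjects within community, and the trial-by-subject
#' residual).
#'
#' When each potter contributes a single value (potter means), the
#' between-subject part alone is computed and `eta_squared_generalized`
#' uses the subject SS as the only error term.
#'
#' @param data data frame with columns `value`, `community`, `potter_id`,
#'   and `trial` (trial index within potter; optional for the means-based
#'   analysis).
#' @return An `anova_result`: `F`, `df_num`, `df_den`, `p_value`,
#'   `eta_squared_generalized`.
#' @export
community_anova <- function(data) {
  need <- c("value", "community", "potter_id")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  comm <- factor(data$community)
  if (nlevels(comm) < 2)
    stop("design error: need >= 2 communities", call. = FALSE)
  potter <- factor(data$potter_id)
  y <- data$value
  n_per <- table(potter)
  means_based <- all(n_per == 1)
  if (!means_based && length(unique(n_per)) > 1) {
    warning("unbalanced trials per potter: falling back to potter means")
    agg <- stats::aggregate(y, list(potter = potter), mean)
    cm <- stats::aggregate(as.integer(comm), list(potter = potter),
                           function(v) v[1])
    y <- agg$x
    potter <- factor(agg$potter)
    comm <- factor(levels(comm)[cm$x])
    means_based <- TRUE
  }
  if (means_based) {
    gm <- mean(y)
    pc <- tapply(as.integer(comm), potter, function(v) v[1])
    cmn <- tapply(y, comm, mean)
    C <- nlevels(comm); P <- nlevels(potter)
    ss_comm <- sum(as.vector(table(comm)) * (cmn - gm)^2)
    ss_subj <- sum((y - cmn[comm])^2)
    df_comm <- C - 1; df_subj <- P - C
    F <- (ss_comm / df_comm) / (ss_subj / df_subj)
    eta <- ss_comm / (ss_comm + ss_subj)
  } else {
    d <- data.frame(y = y, comm = comm, potter = potter,
                    trial = factor(data$trial))
    fit <- stats::aov(y ~ comm * trial + Error(potter / trial), data = d)
    s <- summary(fit)
    between <- as.data.frame(s[["Error: potter"]][[1]])
    within <- as.data.frame(s[["Error: potter:trial"]][[1]])
    rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))
    ss_comm <- between[rn_b == "comm", "Sum Sq"]
    ss_subj <- between[rn_b == "Residuals", "Sum Sq"]
    df_comm <- between[rn_b == "comm", "Df"]
    df_subj <- between[rn_b == "Residuals", "Df"]
    ss_err_w <- within[rn_w == "Residuals", "Sum Sq"]
    F <- (ss_comm / df_comm) / (ss_subj / df_subj)
    eta <- ss_comm / (ss_comm + ss_subj + ss_err_w)
  }
  structure(list(F = F, df_num = df_comm, df_den = df_subj,
                 p_value = stats::pf(F, df_comm, df_subj, lower.tail = FALSE),
                 eta_squared_generalized = eta),
            class = "anova_result")
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Recovers the classical one-way F from per-group means and dispersions
#' with a common group size n: the between-group sum of squares from the
#' means, the within-group sum of squares from the per-group standard
#' deviations (SD = CV x mean / 100 when CVs are supplied).
#'
#' @param means per-group means.
#' @param dispersions per-group CVs (percent) or SDs.
#' @param n_per_group common group size (>= 2).
#' @param type `"cv"` (default) or `"sd"`.
#' @return An `anova_result` with `F`, `df_num = a - 1`,
#'   `df_den = a (n - 1)`, `p_value`, `eta_squared_generalized`;
#'   `infinite_F` flags zero within-group variance.
#' @examples
#' oneway_anova_from_summary(c(10, 12, 20), c(5, 5, 5), 5)
#' @export
oneway_anova_from_summary <- function(means, dispersions, n_per_group,
                                      type = c("cv", "sd")) {
  type <- match.arg(type)
  a <- length(means)
  if (a < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(dispersions) != a)
    stop("means and dispersions must have equal length", call. = FALSE)
  n <- as.integer(n_per_group)
  if (n < 2) stop("n_per_group must be >= 2", call. = FALSE)
  sds <- if (type == "cv") dispersions * means / 100 else dispersions
  ssb <- n * sum((means - mean(means))^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- a - 1L; df2 <- a * (n - 1L)
  if (ssw == 0) {
    return(structure(list(F = Inf, df_num = df1, df_den = df2, p_value = 0,
                          eta_squared_generalized = 1, infinite_F = TRUE),
                     class = "anova_result"))
  }
  F <- (ssb / df1) / (ssw / df2)
  structure(list(F = F, df_num = df1, df_den = df2,
                 p_value = stats::pf(F, df1, df2, lower.tail = FALSE),
                 eta_squared_generalized = ssb / (ssb + ssw),
                 infinite_F = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("ANOVA: F(%d,%d) = %.4g, p = %.4g, generalized eta-squared = %.3f\n",
              x$df_num, x$df_den, x$F, x$p_value,
              x$eta_squared_generalized))
  invisible(x)
}

#' Pearson correlation with 95% confidence interval
#'
#' Sample Pearson r, two-sided t-test p-value, and the 95% confidence
#' interval from the Fisher z-transform.
#'
#' @param x,y numeric vectors, n >= 4, finite, nonzero variance.
#' @return List with `r`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("need paired vectors of length >= 4", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, conf.level = 0.95)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
       n = length(x))
}
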
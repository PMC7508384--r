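# Distance-based permutation test (PERMANOVA) on multivariate features,
# implemented from the sums-of-squares decomposition of pairwise
# distances. With one group factor on Euclidean distances this is the
# one-way special case of the distance-based MANOVA framework; the
# univariate Euclidean case reduces exactly to the classical one-way
# ANOVA F.

# SS_within for a grouping, from the squared distance matrix
permanova_ss_within <- function(D2, groups) {
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ssw <- ssw + sum(D2[i, i]) / (2 * length(i))
  }
  ssw
}

# enumerate all distinct assignments of a multiset of labels (count first
# with multinomial coefficient; caller guards the size)
enumerate_label_permutations <- function(labels) {
  tab <- table(labels)
  lev <- names(tab)
  out <- list()
  recurse <- function(remaining, acc) {
    if (sum(remaining) == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (k in seq_along(lev)) {
      if (remaining[k] > 0) {
        remaining[k] <- remaining[k] - 1
        recurse(remaining, c(acc, lev[k]))
        remaining[k] <- remaining[k] + 1
      }
    }
  }
  recurse(as.vector(tab), character(0))
  out
}

n_distinct_relabelings <- function(labels) {
  tab <- table(labels)
  exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

#' Permutation test on multivariate shape coefficients
#'
#' Partitions the total sum of squared pairwise Euclidean distances into
#' among- and within-group components and tests the among-group fraction
#' by permuting group labels:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo_F = (SS_among / (a-1)) / (SS_within / (N-a))`,
#' `R^2 = SS_among / SS_total`. The p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_permutations)` for random
#' permutations, or the exact proportion over all distinct relabelings
#' when these number at most `exact_limit` (the observed labeling is one
#' of them).
#'
#' @param features numeric matrix/data frame of feature rows, or a
#'   symmetric distance matrix / `dist` object (then used as-is).
#' @param labels group labels, one per row; >= 2 groups with >= 2 members
#'   each.
#' @param n_permutations random permutations when enumeration is not used
#'   (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param exact_limit enumerate all relabelings when their count is at
#'   most this (default 1e5); set 0 to force random permutations.
#' @return A `permanova_result`: list with `pseudo_F`, `r_squared_among`,
#'   `r_squared_residual`, `p_value`, `df_among`, `df_residual`,
#'   `n_permutations`, `exact` flag.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' x[1:10, 1] <- x[1:10, 1] + 3
#' permanova(x, rep(c("A", "B"), each = 10), n_permutations = 199, seed = 1)
#' @export
permanova <- function(features, labels, n_permutations = 9999L, seed = 1L,
                      exact_limit = 1e5) {
  labels <- as.character(labels)
  if (inherits(features, "dist")) {
    D <- as.matrix(features)
  } else if (is.matrix(features) && isSymmetric(unname(features)) &&
             all(abs(diag(features)) < 1e-12) && nrow(features) == length(labels)) {
    D <- unname(features)
  } else {
    D <- as.matrix(stats::dist(as.matrix(features)))
  }
  N <- nrow(D)
  if (N != length(labels))
    stop("labels length must match the number of observations", call. = FALSE)
  tab <- table(labels)
  a <- length(tab)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2))
    stop("each group needs >= 2 members (df error for group of 1)", call. = FALSE)
  D2 <- D^2
  ss_total <- sum(D2) / (2 * N)
  df_among <- a - 1L
  df_resid <- N - a
  stat <- function(gr) {
    ssw <- permanova_ss_within(D2, gr)
    ssa <- ss_total - ssw
    (ssa / df_among) / (ssw / df_resid)
  }
  F_obs <- stat(labels)
  ssw_obs <- permanova_ss_within(D2, labels)
  r2 <- (ss_total - ssw_obs) / ss_total

  n_total <- n_distinct_relabelings(labels)
  exact <- n_total <= exact_limit
  if (exact) {
    perms <- enumerate_label_permutations(labels)
    Fs <- vapply(perms, stat, numeric(1))
    p <- mean(Fs >= F_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    Fs <- with_local_seed(as.integer(seed), {
      vapply(seq_len(n_permutations), function(i) stat(sample(labels)),
             numeric(1))
    })
    p <- (1 + sum(Fs >= F_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- as.integer(n_permutations)
  }
  structure(list(pseudo_F = F_obs, r_squared_among = r2,
                 r_squared_residual = 1 - r2, p_value = p,
                 df_among = df_among, df_residual = df_resid,
                 n_permutations = n_perm, exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("permanova: pseudo-F(%d,%d) = %.4g, R2 = %.3f, p = %.4g (%s, %d permutations)\n",
              x$df_among, x$df_residual, x$pseudo_F, x$r_squared_among,
              x$p_value, if (x$exact) "exact enumeration" else "random",
              x$n_permutations))
  invisible(x)
}
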
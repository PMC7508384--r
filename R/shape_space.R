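# PCA shape space over size-normalized coefficient vectors, trajectory
# projection, and per-trial distances from group mean shapes.

#' Fit the PCA shape space
#'
#' Centered principal component analysis of the coefficient matrix via
#' spectral decomposition of the covariance matrix (coefficients share
#' units after size normalization, so no correlation scaling is applied).
#' Components are ordered by decreasing variance; each basis vector's sign
#' is fixed so its largest-magnitude loading is positive, making scores
#' reproducible across runs and platforms.
#'
#' @param coeff_matrix numeric matrix or data frame of flattened
#'   coefficient rows (>= 2 rows, equal lengths).
#' @param n_components components retained for scores (default 3).
#' @return A `shape_space`: list with `center`, `rotation` (full
#'   orthonormal basis, one column per component), `var_explained`
#'   (fractions summing to 1 over all components), `sdev`, and
#'   `n_components`.
#' @export
fit_shape_space <- function(coeff_matrix, n_components = 3L) {
  X <- as.matrix(coeff_matrix)
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("need at least 2 coefficient rows", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / (nrow(X) - 1)
  if (sum(diag(S)) <= 1e-14)
    stop("degenerate input: coefficient matrix is constant", call. = FALSE)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rot <- eig$vectors
  for (j in seq_len(ncol(rot))) {           # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = ctr, rotation = rot,
                 var_explained = ev / sum(ev), sdev = sqrt(ev),
                 n_components = as.integer(n_components)),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  k <- min(3, length(x$var_explained))
  cat(sprintf("shape_space: %d dims; first %d PCs explain %s (total %.1f%%)\n",
              length(x$center), k,
              paste(sprintf("%.1f%%", 100 * x$var_explained[1:k]),
                    collapse = ", "),
              100 * sum(x$var_explained[1:k])))
  invisible(x)
}

#' Project coefficient vectors into the shape space
#'
#' @param space a `shape_space`.
#' @param coeffs a coefficient vector or a matrix/data frame of rows whose
#'   length matches the space.
#' @param k number of leading components to return (default the space's
#'   `n_components`).
#' @return Matrix of scores, one row per input row, columns `PC1..PCk`.
#' @export
project_shapes <- function(space, coeffs, k = space$n_components) {
  stopifnot(inherits(space, "shape_space"))
  X <- if (is.null(dim(coeffs))) matrix(as.numeric(coeffs), nrow = 1)
       else as.matrix(coeffs)
  if (ncol(X) != length(space$center))
    stop(sprintf("dimension mismatch: coefficients have length %d, space expects %d",
                 ncol(X), length(space$center)), call. = FALSE)
  k <- min(as.integer(k), ncol(space$rotation))
  sc <- sweep(X, 2, space$center) %*% space$rotation[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' Shape-space scores for every stage of a study
#'
#' @param space a `shape_space` fitted to the study's coefficients.
#' @param coeff_table output of [study_coefficients()].
#' @param k components retained.
#' @return The key columns of `coeff_table` plus `PC1..PCk`.
#' @export
study_scores <- function(space, coeff_table, k = space$n_components) {
  cc <- coeff_columns(coeff_table)
  sc <- project_shapes(space, coeff_table[, cc], k = k)
  cbind(coeff_table[, setdiff(names(coeff_table), cc)], sc)
}

#' Euclidean distances from group mean shapes at one stage
#'
#' For each trial's shape point at the given stage, the Euclidean distance
#' (in the retained score dimensions) from the mean score of the trial's
#' group at that stage. The grouping may be the pooled set of all potters
#' or, e.g., each community separately; the group mean is recomputed per
#' group, so distances are relative to the pertinent group mean shape.
#'
#' @param score_table output of [study_scores()].
#' @param stage stage label to select (`"pre_formed"` or `"final"`).
#' @param grouping vector of group labels, one per row of `score_table`
#'   (recycled names such as a single shared label give the pooled
#'   analysis). Default: one pooled group per vessel type.
#' @return Data frame `trial_id`, `potter_id`, `community`,
#'   `vessel_type`, `stage`, `group`, `distance`.
#' @export
stage_distances <- function(score_table, stage,
                            grouping = score_table$vessel_type) {
  keep <- score_table$stage == stage
  if (!any(keep))
    stop("no rows at stage '", stage, "'", call. = FALSE)
  d <- score_table[keep, , drop = FALSE]
  grouping <- as.character(grouping)[keep]
  pc_cols <- grep("^PC[0-9]+$", names(d), value = TRUE)
  sc <- as.matrix(d[, pc_cols, drop = FALSE])
  dist <- numeric(nrow(d))
  for (g in unique(grouping)) {
    i <- grouping == g
    ctr <- colMeans(sc[i, , drop = FALSE])
    dist[i] <- sqrt(rowSums(sweep(sc[i, , drop = FALSE], 2, ctr)^2))
  }
  data.frame(trial_id = d$trial_id, potter_id = d$potter_id,
             community = d$community, vessel_type = d$vessel_type,
             stage = stage, group = grouping, distance = dist)
}
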
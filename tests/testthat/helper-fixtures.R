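# Shared fixtures and independent oracles for the test suite.

# closed circle outline, counterclockwise, n distinct points
circle_outline <- function(r = 1, n = 256, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

# closed axis-aligned ellipse outline
ellipse_outline <- function(A, B, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  data.frame(x = A * cos(th), y = B * sin(th))
}

# unit square outline, counterclockwise, closed
square_outline <- function(side = 2, pts_per_edge = 25) {
  s <- side / 2
  u <- seq(-s, s, length.out = pts_per_edge + 1)
  data.frame(
    x = c(u, rep(s, pts_per_edge), rev(u)[-1], rep(-s, pts_per_edge - 1), -s),
    y = c(rep(-s, pts_per_edge + 1), u[-1], rep(s, pts_per_edge),
          rev(u)[-1]))
}

# Independent EFA oracle: brute-force trapezoid quadrature of the Fourier
# integrals over a dense arc-length parametrization of the polygon. Kept
# deliberately naive (dense linear resampling + trapezoid rule), so it
# shares no code with the closed-form implementation under test.
efa_quadrature_oracle <- function(xy, n_harmonics, subdiv = 2000L) {
  xy <- as.matrix(xy[, c("x", "y")])
  seg <- cbind(diff(xy[, 1]), diff(xy[, 2]))
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  starts <- xy[-nrow(xy), , drop = FALSE][keep, , drop = FALSE]
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  t0 <- c(0, cumsum(len))[seq_along(len)]
  # dense parametrization, quadrature nodes aligned with vertices
  u <- seq(0, 1, length.out = subdiv + 1)
  tt <- as.vector(t(outer(t0, rep(1, subdiv + 1)) + outer(len, u)))
  xx <- as.vector(t(starts[, 1] + outer(seg[, 1], u)))
  yy <- as.vector(t(starts[, 2] + outer(seg[, 2], u)))
  o <- order(tt); tt <- tt[o]; xx <- xx[o]; yy <- yy[o]
  dup <- c(FALSE, diff(tt) == 0)
  tt <- tt[!dup]; xx <- xx[!dup]; yy <- yy[!dup]
  T <- sum(len)
  trapz <- function(f) sum(diff(tt) * (f[-1] + f[-length(f)]) / 2)
  h <- t(vapply(seq_len(n_harmonics), function(n) {
    w <- 2 * pi * n * tt / T
    c(a = 2 / T * trapz(xx * cos(w)), b = 2 / T * trapz(xx * sin(w)),
      c = 2 / T * trapz(yy * cos(w)), d = 2 / T * trapz(yy * sin(w)))
  }, numeric(4)))
  list(harmonics = h, A0 = trapz(xx) / T, C0 = trapz(yy) / T, T = T)
}

# small convergent study: 4 potters, tight final signature, wide preforms
convergent_config <- function(seed = 1, n_trials = 2, n_gestures = c(3, 3),
                              final_offset = 0.02, noise = 0.03) {
  finals <- list(pot = vessel_params(16, 14, 0.45, 2.5, 3, 2.2, 0.3))
  pre <- list(
    vessel_params(11, 10, 0.50, 4.6, 4.8, 6.0, 0.4),
    vessel_params(13, 9, 0.55, 3.6, 3.4, 2.8, 0.2),
    vessel_params(8, 12, 0.35, 5.2, 4.0, 1.6, 0.2),
    vessel_params(12, 13, 0.42, 5.5, 3.6, 2.0, 0.5))
  arch <- lapply(seq_along(pre), function(i)
    potter_archetype(paste0("S", i), if (i <= 2) "c1" else "c2", pre[[i]],
                     n_gestures_range = n_gestures,
                     final_offset_scale = final_offset,
                     trial_noise_scale = noise))
  study_config(finals, arch, n_trials_per_type = n_trials, seed = seed)
}

# between-potter dispersion of normalized coefficient rows at one stage:
# mean distance of potter-mean vectors from their grand mean
between_potter_dispersion <- function(coefs, stage) {
  cc <- grep("^[abcd][0-9]+$", names(coefs), value = TRUE)
  rows <- coefs[coefs$stage == stage, , drop = FALSE]
  pm <- stats::aggregate(rows[, cc], list(potter = rows$potter_id), mean)
  M <- as.matrix(pm[, cc])
  ctr <- colMeans(M)
  mean(sqrt(rowSums(sweep(M, 2, ctr)^2)))
}

# mean distance from reconstructed points to the original polygon,
# measured point-to-segment (the outline's rim/base chords have no
# intermediate vertices)
mean_dist_to_polygon <- function(rec, o) {
  px <- rec$x[-nrow(rec)]; py <- rec$y[-nrow(rec)]
  ax <- o$x[-nrow(o)]; ay <- o$y[-nrow(o)]
  bx <- o$x[-1]; by <- o$y[-1]
  ex <- bx - ax; ey <- by - ay
  len2 <- pmax(ex^2 + ey^2, 1e-300)
  mean(vapply(seq_along(px), function(i) {
    t <- pmin(pmax(((px[i] - ax) * ex + (py[i] - ay) * ey) / len2, 0), 1)
    min(sqrt((ax + t * ex - px[i])^2 + (ay + t * ey - py[i])^2))
  }, numeric(1)))
}
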
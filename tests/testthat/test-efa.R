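test_that("circle coefficients match the analytic Fourier series", {
  r <- 3
  cf <- efa_coefficients(circle_outline(r, 4000), 6)
  expect_lt(max(abs(cf$harmonics[1, ] - c(r, 0, 0, r))), 1e-6 * r)
  expect_lt(max(abs(cf$harmonics[-1, ])), 1e-6 * r)
  expect_lt(max(abs(c(cf$A0, cf$C0))), 1e-9)

  expect_error(efa_coefficients(data.frame(x = c(0, 1, 1, 0),
                                           y = c(0, 0, 1, 1)), 2),
               "not closed")
  deg <- data.frame(x = rep(1, 5), y = rep(2, 5))
  expect_error(efa_coefficients(deg, 2), "perimeter|distinct")
})

test_that("ellipse coefficients respect arc-length parametrization symmetries", {
  # under arc length an eccentric ellipse is not band-limited, but its
  # half-turn symmetry (t -> t + T/2 maps (x, y) -> (-x, -y)) kills all
  # even harmonics exactly, and the first harmonic dominates
  A <- 5; B <- 2
  ce <- efa_coefficients(ellipse_outline(A, B, 4000), 5)
  expect_lt(max(abs(ce$harmonics[c(2, 4), ])), 1e-8 * A)
  pow <- rowSums(ce$harmonics^2)
  expect_gt(pow[1] / sum(pow), 0.99)
  # and the coefficients agree with the independent quadrature oracle
  or <- efa_quadrature_oracle(ellipse_outline(A, B, 500), 5, subdiv = 500)
  ce2 <- efa_coefficients(ellipse_outline(A, B, 500), 5)
  expect_lt(max(abs(ce2$harmonics - or$harmonics)), 1e-6)
})

test_that("closed-form coefficients agree with dense-quadrature integration", {
  sq <- square_outline(2, 25)
  cf <- efa_coefficients(sq, 10)
  or <- efa_quadrature_oracle(sq, 10, subdiv = 20000)
  expect_lt(max(abs(cf$harmonics - or$harmonics)), 1e-8)
  expect_lt(abs(cf$A0 - or$A0), 1e-8)
  expect_lt(abs(cf$C0 - or$C0), 1e-8)

  # and on an asymmetric vessel outline
  p <- make_profile(vessel_params(16, 14, 0.45, 2.5, 3, 2.2, 0.3), 64)
  o <- mirror_to_outline(p)
  cf <- efa_coefficients(o, 8)
  or <- efa_quadrature_oracle(o, 8, subdiv = 8000)
  expect_lt(max(abs(cf$harmonics - or$harmonics)), 1e-7)
})

test_that("first-harmonic size normalization is exactly scale invariant", {
  cf <- normalize_size(efa_coefficients(circle_outline(7, 512), 3))
  expect_equal(cf$harmonics[1, ], c(a = 1, b = 0, c = 0, d = 1),
               tolerance = 1e-9)
  expect_true(cf$normalized)
  expect_equal(c(cf$A0, cf$C0), c(0, 0))

  p <- make_profile(vessel_params(16, 14, 0.45, 2.5, 3, 2.2, 0.3), 128)
  o <- mirror_to_outline(p)
  o2 <- data.frame(x = 3.7 * o$x, y = 3.7 * o$y)
  n1 <- normalize_size(efa_coefficients(o, 12))
  n2 <- normalize_size(efa_coefficients(o2, 12))
  expect_lt(max(abs(n1$harmonics - n2$harmonics)), 1e-10)

  # semi-major axis equals the eigenvalue route on the 2x2 first-harmonic
  # coefficient matrix
  cf <- efa_coefficients(o, 12)
  M <- matrix(cf$harmonics[1, ], 2, 2, byrow = TRUE)
  e1_eigen <- sqrt(max(eigen(M %*% t(M), symmetric = TRUE)$values))
  expect_equal(vesselmorph:::first_harmonic_axes(cf)[1], e1_eigen,
               tolerance = 1e-12)

  # normalized first-harmonic semi-major axis is exactly 1
  nf <- normalize_size(cf)
  expect_equal(vesselmorph:::first_harmonic_axes(nf)[1], 1,
               tolerance = 1e-9)

  # the |a1| variant is also scale invariant but differently scaled
  na <- normalize_size(cf, method = "a1")
  expect_equal(unname(abs(na$harmonics[1, "a"])), 1, tolerance = 1e-12)
})

test_that("reconstruction inverts the transform with monotone truncation error", {
  # exact one-harmonic circle coefficients reconstruct a perfect circle
  cf <- structure(list(
    harmonics = cbind(a = c(2, 0), b = c(0, 0), c = c(0, 0), d = c(2, 0)),
    A0 = 1, C0 = -3, n_harmonics = 2L, normalized = FALSE),
    class = "efa_coefficients")
  rec <- reconstruct(cf, 100)
  d <- sqrt((rec$x - cf$A0)^2 + (rec$y - cf$C0)^2)
  expect_lt(max(abs(d - 2)), 1e-9)

  # translation moves only the bias terms
  o <- mirror_to_outline(make_profile(vessel_params(16, 14, 0.45, 2.5, 3,
                                                    2.2, 0.3), 128))
  ot <- data.frame(x = o$x + 11, y = o$y - 4)
  c0 <- efa_coefficients(o, 10); c1 <- efa_coefficients(ot, 10)
  expect_lt(max(abs(c0$harmonics - c1$harmonics)), 1e-9)
  expect_equal(c1$A0 - c0$A0, 11, tolerance = 1e-9)
  expect_equal(c1$C0 - c0$C0, -4, tolerance = 1e-9)

  # L2 error nonincreasing in the number of harmonics
  ob <- mirror_to_outline(make_profile(vessel_params(16, 14, 0.45, 2.5, 3,
                                                     2.2, 0.3), 512))
  l2err <- function(N)
    mean_dist_to_polygon(reconstruct(efa_coefficients(ob, N), 512), ob)
  errs <- vapply(c(5, 10, 20, 40), l2err, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  # 20 harmonics reconstruct a vessel outline to < 0.5% of its height
  expect_lt(errs[3], 0.005 * 16)

  # round trip on a constant-speed band-limited contour (circle) is exact
  # to within the polygonal sampling error
  cc <- efa_coefficients(circle_outline(2, 2048), 5)
  back <- efa_coefficients(reconstruct(cc, 2048), 5)
  expect_lt(max(abs(back$harmonics - cc$harmonics)) / 2, 1e-4)
  # a vessel outline drifts slightly under arc-length reparametrization
  cf <- efa_coefficients(o, 10)
  backv <- efa_coefficients(reconstruct(cf, 2048), 10)
  expect_lt(max(abs(backv$harmonics - cf$harmonics)) /
              max(abs(cf$harmonics)), 0.01)

  expect_error(reconstruct(cf, 2), "n_points")
})

test_that("flattened coefficient vectors follow the documented a1 b1 c1 d1 ... order", {
  cf <- efa_coefficients(circle_outline(3, 128), 2)
  v <- coeff_vector(cf)
  expect_named(v, c("a1", "b1", "c1", "d1", "a2", "b2", "c2", "d2"))
  expect_equal(unname(v[1:4]), unname(cf$harmonics[1, ]))
})
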
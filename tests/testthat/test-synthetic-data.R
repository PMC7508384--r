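test_that("invalid vessel parameters are rejected with the violated invariant named", {
  expect_error(vessel_params(-1, 14, 0.5, 2, 3), "height_cm")
  expect_error(vessel_params(16, 14, 1.2, 2, 3), "max_diameter_rel_height")
  expect_error(vessel_params(16, 14, 0.5, 8, 3), "aperture_radius_cm")
  expect_error(vessel_params(16, 14, 0.5, 2, 9), "base_radius_cm")
  expect_error(vessel_params(16, 14, 0.5, 2, 3, bulge_exponent = 0), "bulge_exponent")
  expect_error(make_profile(vessel_params(16, 14, 0.5, 2, 3), 8), "n_points")
})

test_that("profile family covers the degenerate and analytic cases", {
  # cylinder: base = aperture = max radius, any exponent
  cyl <- make_profile(vessel_params(10, 8, 0.5, 4, 4, 3), 64)
  expect_equal(cyl$x, rep(4, 64), tolerance = 1e-12)

  # mid-belly with narrower ends: radius unimodal with max at mid-height
  p <- make_profile(vessel_params(10, 8, 0.5, 2, 3, 2.5), 101)
  i_max <- which.max(p$x)
  expect_equal(p$y[i_max], 5)
  expect_true(all(diff(p$x[1:i_max]) >= -1e-12))
  expect_true(all(diff(p$x[i_max:101]) <= 1e-12))
  expect_equal(max(p$x), 4)
  expect_equal(p$x[101], 2)

  # sphere-like closed form: exponent 2 reproduces the circle arc
  r <- 5
  sp <- make_profile(vessel_params(2 * r, 2 * r, 0.5, 0, 0, 2), 256)
  arc <- sqrt(pmax(r^2 - (sp$y - r)^2, 0))
  rel_l2 <- sqrt(sum((sp$x - arc)^2) / sum(arc^2))
  expect_lt(rel_l2, 0.01)
})

test_that("trial simulation honours the zero-noise linear-route limit", {
  pre <- vessel_params(10, 10, 0.5, 4, 4, 3)
  fin <- vessel_params(16, 14, 0.45, 2.5, 3, 2.2)
  arch <- potter_archetype("Z", "c", pre, n_gestures_range = c(4, 4),
                          final_offset_scale = 0, trial_noise_scale = 0)
  tr <- simulate_trial(arch, fin, seed = 5, n_points = 64)
  expect_length(tr$stages, 5)
  v0 <- vesselmorph:::params_to_vector(pre)
  v1 <- vesselmorph:::params_to_vector(fin)
  for (j in 0:4) {
    expected <- vesselmorph:::vector_to_params(v0 + (v1 - v0) * j / 4)
    expect_equal(tr$stages[[j + 1]]$profile,
                 make_profile(expected, 64), tolerance = 1e-12)
  }
  times <- vapply(tr$stages, function(s) s$time_s, numeric(1))
  expect_equal(times[1], 0)
  expect_true(all(diff(times) > 0))
})

test_that("simulation is deterministic in the seed and sensitive to changing it", {
  arch <- default_study_config()$archetypes[[1]]
  fin <- vessel_params(16, 14, 0.45, 2.5, 3, 2.2, 0.3)
  expect_identical(simulate_trial(arch, fin, 42, 32),
                   simulate_trial(arch, fin, 42, 32))
  expect_false(identical(simulate_trial(arch, fin, 42, 32),
                         simulate_trial(arch, fin, 43, 32)))

  cfg <- convergent_config(seed = 9)
  expect_identical(simulate_study(cfg, n_points = 32),
                   simulate_study(cfg, n_points = 32))
  s2 <- simulate_study(convergent_config(seed = 10), n_points = 32)
  expect_false(identical(simulate_study(cfg, n_points = 32), s2))
  expect_length(s2$trials, length(simulate_study(cfg, n_points = 32)$trials))
})

test_that("the full factorial study has the expected structure", {
  cfg <- default_study_config(seed = 3, n_trials_per_type = 5)
  study <- simulate_study(cfg, n_points = 32)
  expect_length(study$trials, 7 * 1 * 5)
  n_gestures <- vapply(study$trials, function(tr)
    length(tr$stages) - 1L, integer(1))
  expect_true(all(n_gestures >= 5 & n_gestures <= 12))
  # all generated profiles satisfy the profile invariants
  for (tr in study$trials) for (st in tr$stages) {
    expect_true(all(st$profile$x >= 0))
    expect_true(all(diff(st$profile$y) > 0))
  }
})

test_that("duplicate potter ids are a configuration error", {
  pre <- vessel_params(10, 10, 0.5, 4, 4)
  a <- potter_archetype("A", "c", pre)
  expect_error(study_config(list(t = pre), list(a, a)), "duplicate potter_id")
})

test_that("wide preforms with a tight final signature converge: stage-0 dispersion exceeds final dispersion", {
  # dispersion of potter means in normalized-coefficient space, replicated
  wins <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    study <- simulate_study(convergent_config(seed = 1000 + r), n_points = 48)
    coefs <- study_coefficients(study, n_harmonics = 8, n_points = 48)
    d0 <- between_potter_dispersion(coefs, "pre_formed")
    d1 <- between_potter_dispersion(coefs, "final")
    wins <- wins + (d0 > d1)
  }
  expect_gte(wins / n_rep, 0.95)
})
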
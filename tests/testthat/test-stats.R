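test_that("permanova recovers the classical F in the univariate Euclidean case", {
  set.seed(31)
  y <- rnorm(24) + rep(c(0, 0.5, 1), each = 8)
  g <- rep(c("A", "B", "C"), each = 8)
  pr <- permanova(matrix(y), g, n_permutations = 49, seed = 1,
                  exact_limit = 0)
  cl <- anova(lm(y ~ g))
  expect_equal(pr$pseudo_F, cl$`F value`[1], tolerance = 1e-8)
  expect_equal(pr$r_squared_among,
               cl$`Sum Sq`[1] / sum(cl$`Sum Sq`), tolerance = 1e-8)
  expect_equal(pr$r_squared_among + pr$r_squared_residual, 1,
               tolerance = 1e-10)
  expect_equal(c(pr$df_among, pr$df_residual), c(2L, 21L))
})

test_that("permanova agrees with an independent distance-based implementation", {
  skip_if_not_installed("vegan")
  set.seed(32)
  X <- matrix(rnorm(30 * 4), 30, 4)
  X[1:10, 1] <- X[1:10, 1] + 2
  g <- rep(c("a", "b", "c"), each = 10)
  pr <- permanova(X, g, n_permutations = 99, seed = 5, exact_limit = 0)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 99)
  expect_equal(pr$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(pr$r_squared_among, ad$R2[1], tolerance = 1e-10)
})

test_that("exhaustive enumeration reproduces the exact permutation distribution", {
  y <- c(1.2, 2.1, 2.9, 9.5, 11.1, 12.4)
  g <- rep(c("A", "B"), each = 3)
  pr <- permanova(matrix(y), g)
  expect_true(pr$exact)
  expect_equal(pr$n_permutations, 20L)
  # independent oracle: enumerate the 20 choose(6,3) relabelings directly
  Fstat <- function(lab) {
    m <- tapply(y, lab, mean); n <- tapply(y, lab, length)
    ssb <- sum(n * (m - mean(y))^2)
    ssw <- sum((y - m[lab])^2)
    (ssb / 1) / (ssw / 4)
  }
  combos <- combn(6, 3)
  Fs <- apply(combos, 2, function(i) {
    lab <- rep("B", 6); lab[i] <- "A"; Fstat(lab)
  })
  p_exact <- mean(Fs >= Fstat(g) - 1e-12)
  expect_equal(pr$p_value, p_exact)
})

test_that("permanova degenerate and invariance properties hold", {
  # identical points within groups, groups far apart
  X <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  g <- rep(c("A", "B"), each = 10)
  pr <- permanova(X, g, n_permutations = 199, seed = 2, exact_limit = 0)
  expect_equal(pr$r_squared_among, 1)
  expect_equal(pr$p_value, 1 / 200)

  # R2 invariant to global feature scaling
  set.seed(33)
  X <- matrix(rnorm(40), 20, 2)
  g <- rep(c("A", "B"), each = 10)
  r1 <- permanova(X, g, n_permutations = 9, seed = 1, exact_limit = 0)
  r2 <- permanova(1000 * X, g, n_permutations = 9, seed = 1, exact_limit = 0)
  expect_equal(r1$r_squared_among, r2$r_squared_among, tolerance = 1e-10)

  expect_error(permanova(X, rep("A", 20)), "2 groups")
  expect_error(permanova(X, c(rep("A", 19), "B")), "2 members")
})

test_that("growth model recovers a noiseless cubic exactly and respects nesting", {
  potters <- paste0("P", 1:4)
  d <- expand.grid(potter_id = potters, bin = 1:20)
  P <- poly(d$bin, 3)
  truth <- c(500, 300, -120, 40)
  d$esa_cm2 <- truth[1] + P %*% truth[2:4]
  d$community <- "c1"
  m0 <- fit_growth_model(d, "none")
  expect_lt(sum(residuals(m0$fit)^2), 1e-8)
  expect_equal(unname(m0$fixed), truth, tolerance = 1e-6)

  set.seed(41)
  d$esa_cm2 <- d$esa_cm2 + rep(rnorm(4, sd = 50), 20) + rnorm(80, sd = 10)
  m0 <- fit_growth_model(d, "none")
  m1 <- fit_growth_model(d, "intercept")
  m2 <- fit_growth_model(d, "slopes")
  expect_gte(m1$log_lik, m0$log_lik - 1e-6)
  expect_gte(m2$log_lik, m1$log_lik - 1e-6)

  # parameter-count bookkeeping drives the likelihood-ratio df
  expect_equal(likelihood_ratio_test(m0, m1)$df, 1L)
  expect_equal(likelihood_ratio_test(m1, m2)$df, 9L)
})

test_that("likelihood-ratio test handles identical models and guards misfits", {
  d <- expand.grid(potter_id = paste0("P", 1:4), bin = 1:10)
  set.seed(42)
  d$esa_cm2 <- 100 + rnorm(40)
  m <- fit_growth_model(d, "none")
  m_same <- m; m_same$n_params <- m$n_params + 1L
  out <- likelihood_ratio_test(m, m_same)
  expect_equal(out$chi_square, 0)
  expect_equal(out$p_value, 1)
  m_bad <- m; m_bad$log_lik <- m$log_lik - 5; m_bad$n_params <- m$n_params + 1L
  expect_error(likelihood_ratio_test(m, m_bad), "fit-quality")
})

test_that("random-intercept LRT at the null keeps type-I error near nominal", {
  # variance-component test on the boundary: chi-square(1) reference is
  # conservative, so rejections at 0.05 land between 0.01 and 0.10
  set.seed(43)
  n_sims <- 500
  rej <- 0L
  d0 <- expand.grid(potter_id = paste0("P", 1:7), bin = 1:5)
  for (i in seq_len(n_sims)) {
    d0$esa_cm2 <- 200 + 10 * d0$bin + rnorm(35, sd = 15)  # no potter effect
    m0 <- fit_growth_model(d0, "none")
    m1 <- fit_growth_model(d0, "intercept")
    rej <- rej + (likelihood_ratio_test(m0, m1)$p_value < 0.05)
  }
  expect_gte(rej / n_sims, 0.01)
  expect_lte(rej / n_sims, 0.10)
})

test_that("stage LMM detects no effect when stages are identical and reduces to the classical F", {
  d <- data.frame(distance = rep(c(1, 2, 3, 4, 5, 6), 2),
                  stage = rep(c("pre_formed", "final"), each = 6),
                  potter_id = rep(paste0("P", 1:3), 4))
  fit <- stage_lmm(d)
  expect_lt(abs(fit$estimate), 1e-8)
  expect_lt(fit$F, 1e-10)

  set.seed(44)
  d2 <- data.frame(distance = c(rnorm(20, 1), rnorm(20, 0.4)),
                   stage = rep(c("pre_formed", "final"), each = 20),
                   potter_id = rep(paste0("P", 1:4), 10))
  plain <- stage_lmm(d2, stratum = "none", random_intercept = FALSE)
  cl <- anova(lm(distance ~ stage, data = d2))
  expect_equal(plain$F, cl$`F value`[1], tolerance = 1e-6)
})

test_that("stage LMM recovers heteroscedastic per-stratum residual SDs", {
  set.seed(45)
  potters <- paste0("P", 1:2)
  sds <- c(P1 = 1, P2 = 5)
  d <- expand.grid(potter_id = potters, rep = 1:50,
                   stage = c("pre_formed", "final"))
  d$distance <- 2 + (d$stage == "pre_formed") * 1.5 +
    rnorm(nrow(d), sd = sds[d$potter_id])
  fit <- stage_lmm(d, stratum = "potter")
  est <- fit$stratum_residual_sd[potters]
  expect_true(all(abs(est - sds) / sds < 0.25))
  expect_equal(fit$df_num, 1L)
})

test_that("community ANOVA matches its potter-means form and flags bad designs", {
  set.seed(46)
  d <- expand.grid(potter_id = paste0("P", 1:6), trial = 1:5)
  d$community <- ifelse(d$potter_id %in% paste0("P", 1:3), "c1", "c2")
  d$value <- rnorm(30, 100, 5) + (d$community == "c2") * 3
  full <- community_anova(d)
  means <- aggregate(value ~ potter_id + community, d, mean)
  means_based <- community_anova(data.frame(value = means$value,
                                            community = means$community,
                                            potter_id = means$potter_id))
  expect_equal(full$F, means_based$F, tolerance = 1e-8)
  expect_equal(c(full$df_num, full$df_den), c(1L, 4L))
  expect_true(full$eta_squared_generalized >= 0 &&
                full$eta_squared_generalized <= 1)

  # identical community means with potter spread: no community effect
  d2 <- data.frame(value = c(9, 11, 10, 9, 11, 10),
                   community = rep(c("c1", "c2"), each = 3),
                   potter_id = paste0("Q", 1:6))
  expect_equal(community_anova(d2)$F, 0)
  expect_error(community_anova(data.frame(value = 1:4, community = "c1",
                                          potter_id = paste0("P", 1:4))),
               "2 communities")
})

test_that("summary-statistic ANOVA reconstruction matches trial-level computation", {
  # construct samples with exactly the stated means and SDs
  z <- as.vector(scale(c(-2, -1, 0, 1, 2)))
  means <- c(10, 14, 20, 11)
  sds <- c(1, 2, 0.5, 1.5)
  y <- as.vector(vapply(1:4, function(i) means[i] + sds[i] * z, numeric(5)))
  g <- rep(letters[1:4], each = 5)
  recon <- oneway_anova_from_summary(means, sds, 5, type = "sd")
  cl <- anova(lm(y ~ g))
  expect_equal(recon$F, cl$`F value`[1], tolerance = 1e-8)
  expect_equal(c(recon$df_num, recon$df_den), c(3L, 16L))

  expect_equal(oneway_anova_from_summary(c(5, 5, 5), c(10, 10, 10), 5)$F, 0)
  inf <- oneway_anova_from_summary(c(5, 6), c(0, 0), 5)
  expect_true(inf$infinite_F)
})

test_that("Pearson correlation intervals behave at the extremes and under reversal", {
  x <- 1:10
  perfect <- pearson_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$ci_high, 1)

  set.seed(47)
  a <- rnorm(35); b <- 0.5 * a + rnorm(35)
  fwd <- pearson_ci(a, b)
  rev <- pearson_ci(-a, b)
  expect_equal(rev$r, -fwd$r)
  expect_equal(rev$ci_low, -fwd$ci_high)
  expect_equal(rev$ci_high, -fwd$ci_low)
  expect_equal(rev$p_value, fwd$p_value)

  expect_error(pearson_ci(1:3, 1:3), "length >= 4")
  expect_error(pearson_ci(rep(1, 5), 1:5), "zero variance")
})

test_that("Fisher-z intervals cover the null at their nominal rate", {
  set.seed(48)
  cover <- 0L
  n_sims <- 2000
  for (i in seq_len(n_sims)) {
    ci <- pearson_ci(rnorm(35), rnorm(35))
    cover <- cover + (ci$ci_low <= 0 && ci$ci_high >= 0)
  }
  expect_gte(cover / n_sims, 0.93)
  expect_lte(cover / n_sims, 0.97)
})
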
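test_that("incidence frequencies tally occupancy, uniques and duplicates", {
  full <- incidence_matrix(matrix(1L, 3, 4,
                                  dimnames = list(paste0("u", 1:3),
                                                  paste0("g", 1:4))))
  f <- incidence_freqs(full)
  expect_equal(f$T, 3L)
  expect_equal(f$S_obs, 4L)
  expect_equal(f$Y, rep(3L, 4))
  expect_equal(c(f$Q1, f$Q2), c(0L, 0L))

  m <- toy_incidence(list(u1 = c("a", "c"), u2 = c("b", "c"),
                          u3 = "c", u4 = "c"))
  f2 <- incidence_freqs(m)  # occupancies: a once, b once, c in all four
  expect_equal(sort(f2$Y), c(1L, 1L, 4L))

  f3 <- toy_freqs(4, c(1L, 2L, 4L))
  expect_equal(f3$Q1, 1L)
  expect_equal(f3$Q2, 1L)
  expect_equal(f3$S_obs, 3L)
})

test_that("rarefaction matches closed forms at the boundary sizes", {
  f <- toy_freqs(4, c(1L, 2L, 4L))
  expect_identical(rarefy_incidence(f, 4), 3)          # t = T -> S_obs
  expect_equal(rarefy_incidence(f, 1), sum(f$Y) / f$T) # t = 1 -> mean/unit
  expect_equal(rarefy_incidence(f, 2), 7 / 3, tolerance = 1e-12)
  expect_error(rarefy_incidence(f, 5), "1..T")
  expect_error(rarefy_incidence(f, 0), "1..T")
})

test_that("rarefaction equals exhaustive subset enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    m <- random_incidence(sample(2:6, 1), sample(3:12, 1), runif(1, 0.2, 0.7))
    if (is.null(m)) next
    f <- incidence_freqs(m)
    for (t in seq_len(nrow(m))) {
      expect_equal(rarefy_incidence(f, t), enum_rarefy(m, t),
                   tolerance = 1e-9)
    }
  }
})

test_that("rarefaction agrees with vegan's exact species accumulation", {
  library(vegan)
  set.seed(21)
  m <- random_incidence(12, 60, 0.25)
  ours <- rarefy_incidence(incidence_freqs(m), 1:12)
  ref <- specaccum(unclass(m), method = "exact")$richness
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Chao2 follows the corrected formulas on both branches", {
  # no uniques -> no estimated undetected richness
  f0 <- toy_freqs(5, c(3L, 3L, 2L))
  expect_equal(chao2(f0)$S_est, 3)

  e1 <- chao2(toy_freqs(10, c(rep(1L, 3), rep(2L, 2), rep(5L, 5))))
  expect_equal(e1$Q0_hat, 0.9 * 9 / 4)   # (T-1)/T * Q1^2 / (2 Q2)
  expect_equal(e1$S_est, 12.025)

  e2 <- chao2(toy_freqs(10, c(rep(1L, 3), rep(5L, 7))))  # Q2 = 0 branch
  expect_equal(e2$Q0_hat, 0.9 * 3 * 2 / 2)
  expect_equal(e2$S_est, 12.7)

  expect_error(chao2(toy_freqs(1, 1L)), "at least 2")
})

test_that("Chao2 matches vegan's specpool estimate", {
  library(vegan)
  set.seed(33)
  for (rep in 1:10) {
    m <- random_incidence(8, 40, 0.15)
    if (is.null(m)) next
    ref <- specpool(unclass(m))
    expect_equal(chao2(incidence_freqs(m))$S_est, ref$chao,
                 tolerance = 1e-10)
  }
})

test_that("extrapolation is continuous, bounded and correct on a fixture", {
  f <- toy_freqs(10, c(rep(1L, 3), rep(2L, 2), rep(5L, 5)))
  est <- chao2(f)
  expect_identical(extrapolate_richness(f, 0), 10)        # continuity
  expect_equal(extrapolate_richness(f, 5), 11.0100716608746,
               tolerance = 1e-12)                         # frozen stepwise value
  expect_lt(extrapolate_richness(f, 100), est$S_est)      # approaches from below
  expect_equal(extrapolate_richness(f, 1e6), est$S_est, tolerance = 1e-9)

  # Q1 = 0 -> flat curve at S_obs, not an error
  flat <- toy_freqs(5, c(3L, 3L, 2L))
  expect_equal(extrapolate_richness(flat, 10), 3)
  expect_error(extrapolate_richness(f, -1), "non-negative")
})

test_that("point curves are monotone with correctly labelled regimes", {
  set.seed(7)
  m <- random_incidence(10, 50, 0.2)
  fit <- gcf_rarefaction(m, t_max = 30, n_boot = 5, seed = 99)
  cv <- fit$curve
  expect_equal(cv$regime,
               c(rep("interpolated", 9), "observed", rep("extrapolated", 20)))
  expect_true(all(diff(cv$richness) >= -1e-12))
  expect_equal(cv$richness[cv$t == 10], incidence_freqs(m)$S_obs)
  expect_gte(fit$estimate$S_est, fit$estimate$S_obs)
})

test_that("bootstrap curves are deterministic given the seed", {
  set.seed(13)
  m <- random_incidence(8, 30, 0.3)
  a <- gcf_rarefaction(m, t_max = 16, n_boot = 40, seed = 5)
  b <- gcf_rarefaction(m, t_max = 16, n_boot = 40, seed = 5)
  expect_identical(a$curve, b$curve)
  expect_identical(a$estimate, b$estimate)
  c <- gcf_rarefaction(m, t_max = 16, n_boot = 40, seed = 6)
  expect_false(identical(a$curve$ci_high, c$curve$ci_high))
})

test_that("a single bootstrap replicate gives a degenerate interval", {
  set.seed(17)
  m <- random_incidence(6, 20, 0.3)
  fit <- gcf_rarefaction(m, t_max = 12, n_boot = 1, seed = 3)
  expect_identical(fit$curve$ci_low, fit$curve$ci_high)
})

test_that("the fitted object predicts, prints and plots", {
  set.seed(19)
  m <- random_incidence(10, 40, 0.25)
  fit <- gcf_rarefaction(m, t_max = 25, n_boot = 10, seed = 2)
  # predict evaluates analytically, matching the fitted grid
  expect_equal(predict(fit, c(3, 10, 20)),
               fit$curve$richness[fit$curve$t %in% c(3, 10, 20)])
  expect_output(print(fit), "Chao2 total richness")
  expect_output(summary(fit), "Curve endpoints")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("richness_at extrapolates to a target sample size with a CI", {
  set.seed(23)
  m <- random_incidence(10, 40, 0.2)
  f <- incidence_freqs(m)
  at_T <- richness_at(m, nrow(m), n_boot = 10, seed = 1)
  expect_equal(at_T$S_est, f$S_obs)
  at_30 <- richness_at(m, 30, n_boot = 10, seed = 1)
  expect_equal(at_30$S_est,
               extrapolate_richness(f, 20))
  expect_true(at_30$ci_low <= at_30$S_est && at_30$S_est <= at_30$ci_high)
  expect_error(richness_at(m, 5, n_boot = 10, seed = 1), "n_target < T")
})

test_that("Chao2 recovers true richness under a homogeneous occupancy model", {
  # Bernoulli presence: S_true species, each occupying each of T units
  # independently with probability p.  Chao2 is designed for exactly this
  # regime; the acceptance band [0.8, 1.3] x S_true was pre-registered from
  # a pilot run at other seeds (lower-bound estimator, asymmetric band).
  S_true <- 300; T <- 40; p <- 0.05
  set.seed(2024)
  hits <- 0L
  for (rep in 1:10) {
    m <- matrix(rbinom(T * S_true, 1, p), nrow = T,
                dimnames = list(paste0("u", 1:T), paste0("g", 1:S_true)))
    m <- m[, colSums(m) > 0, drop = FALSE]
    est <- chao2(incidence_freqs(incidence_matrix(m)))
    expect_gt(est$S_est, est$S_obs)
    if (est$S_est >= 0.8 * S_true && est$S_est <= 1.3 * S_true) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)
})
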
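test_that("regionwide contribution is the population-weighted mean", {
  w <- population_weights(0.5)
  # invariance when both strata agree, for any weights
  expect_equal(regionwide_contribution(0.37, 0.37, population_weights(0.81)),
               0.37)
  expect_equal(regionwide_contribution(0.4, 0.6, w), 0.5)
  # sum over sources preserved when the strata fractions each sum to 1
  fu <- c(0.3, 0.3, 0.2, 0.2)
  fn <- c(0.4, 0, 0.35, 0.25)
  F <- regionwide_contribution(fu, fn, population_weights(0.62))
  expect_equal(sum(F), 1)
  # audit-only product rule
  expect_equal(regionwide_contribution(0.4, 0.6, w, rule = "product"),
               0.4 * 0.5 * 0.6 * 0.5)
  expect_error(population_weights(0.7, 0.6), "sum to 1")
  expect_error(regionwide_contribution(1.2, 0.5, w), "\\[0, 1\\]")
})

test_that("fossil/non-fossil split sums the right sources", {
  expect_equal(fossil_nonfossil_split(0.25, 0.25, 0.25, 0.25),
               c(fossil = 0.5, non_fossil = 0.5))
  sp <- fossil_nonfossil_split(0.2, 0.23, 0.3, 0.27)
  expect_equal(sp, c(fossil = 0.43, non_fossil = 0.57))
  expect_equal(sum(sp), 1)
  # three-source region: vehicle term zero
  expect_equal(fossil_nonfossil_split(0.3, 0, 0.4, 0.3),
               c(fossil = 0.3, non_fossil = 0.7))
  expect_error(fossil_nonfossil_split(0.6, 0.6), "more than 1")
})

test_that("emission budget identities hold exactly", {
  # all-fossil limit
  b1 <- emission_budget(10, 1)
  expect_equal(b1$a_total, 10)
  expect_equal(b1$a_non_fossil, 0)

  b <- emission_budget(16.297, 0.43)
  expect_equal(b$a_total, 16.297 / 0.43)
  expect_equal(b$a_non_fossil, b$a_total - b$a_fossil)
  # equivalent route: a_total * (1 - f_fossil), exactly
  expect_equal(b$a_non_fossil, b$a_total * (1 - 0.43))
  expect_equal(b$f_fossil + b$f_non_fossil, 1)

  expect_error(emission_budget(10, 0), "validity")
  expect_error(emission_budget(-1, 0.5), ">= 0")

  # monotonicity: non-fossil amount strictly decreases in the fossil share
  ff <- seq(0.2, 0.9, by = 0.1)
  anf <- vapply(ff, function(f) emission_budget(10, f)$a_non_fossil,
                numeric(1))
  expect_true(all(diff(anf) < 0))
})

test_that("Monte Carlo propagation is conservative, truncated and deterministic", {
  # degenerate: zero SDs reproduce the central budget with zero spread
  mc0 <- propagate_uncertainty(10, 0, 0.5, 0, n_draws = 1000, seed = 1)
  expect_equal(unname(mc0$sd), rep(0, 5))
  expect_equal(mc0$mean[["a_total"]], 20)
  expect_equal(mc0$mean[["a_non_fossil"]], mc0$central$a_non_fossil)

  mc <- propagate_uncertainty(10, 2, 0.5, 0.1, n_draws = 5000, seed = 7,
                              keep_draws = TRUE)
  # conservation per draw and on the means
  expect_equal(mc$draws[, "a_fossil"] + mc$draws[, "a_non_fossil"],
               mc$draws[, "a_total"])
  expect_equal(mc$mean[["a_fossil"]] + mc$mean[["a_non_fossil"]],
               mc$mean[["a_total"]])
  # truncation safety in every retained draw
  expect_true(all(mc$draws[, "f_fossil"] > 0 & mc$draws[, "f_fossil"] <= 1))
  expect_true(all(mc$draws[, "a_fossil"] >= 0))
  expect_true(all(mc$draws[, "a_non_fossil"] >= 0))

  # seed determinism
  mc2 <- propagate_uncertainty(10, 2, 0.5, 0.1, n_draws = 5000, seed = 7)
  expect_equal(mc$mean, mc2$mean)
  expect_equal(mc$sd, mc2$sd)

  # posterior-draw passthrough bypasses the truncated-normal sampling
  f_draws <- c(0.4, 0.5, 0.6)
  mcd <- propagate_uncertainty(10, 0, 0.5, 0.1, f_draws = f_draws,
                               a_draws = rep(10, 3), seed = 1)
  expect_equal(mcd$mean[["a_total"]], mean(10 / f_draws))
  expect_error(propagate_uncertainty(10, 0, 0.5, 0.1, f_draws = c(0.5, 0.5),
                                     a_draws = rep(10, 3), seed = 1),
               "equal length")
})
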
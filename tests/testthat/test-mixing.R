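test_that("symmetric two-source data splits 50/50 and hits the end-member limit", {
  # two sources at +/-10 (sd 1), 50 observations at 0, no offset
  fit <- nox_mix(rep(0, 50), test_sources2(), frac_offset(0, 0),
                 mcmc_settings(n_iter = 6000, burn_in = 3000, thin = 2,
                               n_chains = 2, seed = 1))
  expect_true(all(abs(coef(fit) - 0.5) < 0.05))

  # observations clustered at mu_S1 + offset with tiny source SDs
  src <- test_sources2(sd = 0.2)
  fit1 <- nox_mix(rnorm(50, -10 + 2, 0.2), src, frac_offset(2, 0.1),
                  quick_settings(seed = 2))
  expect_gt(coef(fit1)[["neg"]], 0.9)
})

test_that("posterior draws stay on the simplex and fits are seed-deterministic", {
  src <- test_sources3()
  obs <- simulate_mixture(
    mixture_spec(c(0.5, 0.3, 0.2), src, offset_mean = 3.9, offset_sd = 1.8,
                 residual_sd = 1, n_obs = 60), seed = 4)
  fit <- nox_mix(obs, src, frac_offset(3.9, 1.8), quick_settings(seed = 5))
  expect_true(all(fit$draws >= 0 & fit$draws <= 1))
  expect_true(all(abs(rowSums(fit$draws) - 1) < 1e-9))
  expect_gt(nrow(fit$draws), 0)

  refit <- nox_mix(obs, src, frac_offset(3.9, 1.8), quick_settings(seed = 5))
  expect_identical(fit$draws, refit$draws)
  expect_identical(fit$sigma_res, refit$sigma_res)
  refit2 <- nox_mix(obs, src, frac_offset(3.9, 1.8), quick_settings(seed = 6))
  expect_false(identical(fit$draws, refit2$draws))
})

test_that("summary agrees with brute-force statistics on the stored draws", {
  src <- test_sources4()
  obs <- simulate_mixture(
    mixture_spec(c(0.3, 0.3, 0.2, 0.2), src, offset_mean = 3.9,
                 offset_sd = 1.8, residual_sd = 1, n_obs = 50), seed = 8)
  fit <- nox_mix(obs, src, frac_offset(3.9, 1.8), quick_settings(seed = 9))
  sm <- summary(fit)
  K <- ncol(fit$draws)
  # oracle: direct column statistics
  expect_equal(sm$mean[seq_len(K)], unname(colMeans(fit$draws)))
  expect_equal(sm$sd[seq_len(K)], unname(apply(fit$draws, 2, sd)))
  expect_equal(sm$lower[seq_len(K)],
               unname(apply(fit$draws, 2, quantile, probs = 0.025)))
  expect_equal(sum(sm$mean[seq_len(K)]), 1, tolerance = 1e-6)
  expect_equal(coef(fit), colMeans(fit$draws))

  # degenerate posterior: identical draws give SD 0 and a point interval
  fake <- fit
  fake$draws <- matrix(rep(c(0.5, 0.2, 0.2, 0.1), each = 40), ncol = 4,
                       dimnames = list(NULL, colnames(fit$draws)))
  fake$sigma_res <- rep(1, 40)
  fake$chain <- rep(1:2, each = 20)
  sm0 <- summary(fake)
  expect_equal(sm0$sd[1:4], rep(0, 4))
  expect_equal(sm0$lower[1:4], sm0$upper[1:4])
})

test_that("posterior mean matches the closed-form two-source inversion", {
  expect_equal(closed_form_two_source(0, c(-10, 1), c(10, 1)), 0.5)
  expect_equal(closed_form_two_source(2 + 3, c(2, 1), c(-6, 1),
                                      offset_mean = 3), 1.0)
  # hand arithmetic with the compiled coal/microbial means
  expect_equal(closed_form_two_source(-8.15, c(13.7, 3.9), c(-30.2, 6.7), 3.9),
               (-8.15 - 3.9 + 30.2) / (13.7 + 30.2))
  expect_error(closed_form_two_source(0, c(1, 1), c(1, 2)), "equal")

  # MCMC vs oracle: narrow sources, many observations
  src <- test_sources2(sd = 0.5)
  set.seed(31)
  obs <- rnorm(300, -2 + 1.5, 0.5)   # true f_neg = 0.6 with offset 1.5
  fit <- nox_mix(obs, src, frac_offset(1.5, 0.1),
                 mcmc_settings(n_iter = 6000, burn_in = 3000, n_chains = 2,
                               seed = 13))
  oracle <- closed_form_two_source(mean(obs), c(-10, 0.5), c(10, 0.5), 1.5)
  expect_lt(abs(coef(fit)[["neg"]] - oracle), 0.03)
})

test_that("permuting source order permutes the posterior (statistically)", {
  src <- test_sources3()
  obs <- simulate_mixture(
    mixture_spec(c(0.5, 0.3, 0.2), src, offset_mean = 3.9, offset_sd = 1.8,
                 residual_sd = 1, n_obs = 100), seed = 21)
  st <- mcmc_settings(n_iter = 20000, burn_in = 10000, n_chains = 2,
                      seed = 3)
  fit <- nox_mix(obs, src, frac_offset(3.9, 1.8), st)
  perm <- c(3, 1, 2)
  fit_p <- nox_mix(obs, src[perm, ], frac_offset(3.9, 1.8), st)
  # the ALR reference coordinate differs, so draws are not byte-identical;
  # posterior means must agree within Monte Carlo error
  expect_lt(max(abs(unname(coef(fit_p)) - unname(coef(fit)[perm]))), 0.03)
  expect_identical(colnames(fit_p$draws), colnames(fit$draws)[perm])
})

test_that("identifiability and input validation are enforced", {
  degen <- data.frame(name = c("a", "b", "c"), mean = c(1, 1, 1),
                      sd = c(0, 0, 0))
  expect_warning(nox_mix(rnorm(10, 1), degen, settings = quick_settings()),
                 "identifiable")
  expect_error(nox_mix(numeric(0), test_sources3()), "non-empty")
  expect_error(nox_mix(rnorm(5), test_sources3(), offset = 3.9),
               "frac_offset")
  expect_error(mcmc_settings(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("Gelman-Rubin diagnostic flags shifted chains and matches brute force", {
  src <- test_sources3()
  obs <- simulate_mixture(
    mixture_spec(c(0.4, 0.4, 0.2), src, offset_mean = 3.9, offset_sd = 1.8,
                 residual_sd = 1, n_obs = 80), seed = 2)
  fit <- nox_mix(obs, src, frac_offset(3.9, 1.8),
                 mcmc_settings(n_iter = 6000, burn_in = 3000, n_chains = 3,
                               seed = 17))
  cv <- check_convergence(fit)
  # stationary chains: statistic near 1
  expect_true(all(cv$rhat < 1.1))

  # brute-force recomputation of the statistic from the stored draws
  j <- 1L
  per <- split(fit$draws[, j], fit$chain)
  nmin <- min(lengths(per))
  per <- lapply(per, function(v) v[seq_len(nmin)])
  W <- mean(vapply(per, var, numeric(1)))
  B_over_n <- var(vapply(per, mean, numeric(1)))
  expect_equal(cv$rhat[[j]], sqrt((nmin - 1) / nmin + B_over_n / W))

  # one chain shifted by a constant must blow up the statistic
  shifted <- fit
  shifted$draws[shifted$chain == 1L, ] <-
    pmin(shifted$draws[shifted$chain == 1L, ] + 0.3, 1)
  expect_false(check_convergence(shifted, quiet = TRUE)$ok)

  # single chain: diagnostic unavailable
  one <- nox_mix(obs, src, frac_offset(3.9, 1.8),
                 mcmc_settings(n_iter = 1000, burn_in = 500, n_chains = 1,
                               seed = 1))
  expect_error(check_convergence(one), "2 chains")
})
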
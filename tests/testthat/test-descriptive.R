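make_obs <- function(regions, classes, means, n_sites = 10, sd = 2,
                     seed = 1) {
  strata <- mapply(function(r, cl, m)
    stratum_spec(r, cl, m, sd, n_sites = n_sites, replicates_per_site = 3),
    regions, classes, means, SIMPLIFY = FALSE)
  simulate_observations(strata, seed = seed)
}

test_that("group comparisons behave at the null and under strong separation", {
  # same-valued groups: F = 0, p = 1, not significant
  obs <- data.frame(site_id = rep(sprintf("s%d", 1:6), each = 2),
                    region = rep(c("A", "B"), each = 6),
                    site_class = "urban",
                    year = 2005L,
                    delta15N = rep(rep(c(-1, 0, 1), each = 2), 2))
  # (each region has only urban sites, so the within-region class contrast
  # is skipped with a warning)
  res <- suppressWarnings(compare_groups(obs))
  aov_row <- res[res$test == "anova_regions", ]
  expect_equal(aov_row$p_value, 1)
  expect_false(aov_row$significant)

  # two classes 10 SDs apart, 30 sites each: significant at alpha = 0.1
  obs2 <- make_obs(c("East Asia", "East Asia"), c("urban", "non-urban"),
                   c(0, 20), n_sites = 30, seed = 2)
  res2 <- suppressWarnings(compare_groups(obs2, alpha = 0.1))  # 1 region
  tt <- res2[res2$test == "urban_vs_nonurban", ]
  expect_true(tt$significant)
  expect_lt(tt$p_value, 1e-6)

  # group order does not change the p-value
  obs2_flipped <- obs2[rev(seq_len(nrow(obs2))), ]
  res2b <- suppressWarnings(compare_groups(obs2_flipped, alpha = 0.1))
  expect_equal(res2b[res2b$test == "urban_vs_nonurban", "p_value"],
               tt$p_value)

  # degenerate groups are skipped with warnings; with nothing testable the
  # call errors
  lone <- make_obs("Europe", "urban", 0, n_sites = 1, seed = 3)
  w <- capture_warnings(try(compare_groups(lone), silent = TRUE))
  expect_true(all(grepl("skipping", w)) && length(w) >= 1)
  expect_error(suppressWarnings(compare_groups(lone)), "no testable")
})

test_that("simulated regional strata separate in the expected direction", {
  # East Asia urban 1.7 +/- 5.4 vs North America urban -0.5 +/- 1.9:
  # the East Asia mean is higher in expectation; with the printed site
  # counts the single-draw test is underpowered, so check the direction of
  # the mean difference across repeated simulation.
  diffs <- vapply(1:20, function(s) {
    obs <- simulate_observations(list(
      stratum_spec("East Asia", "urban", 1.7, 5.4, n_sites = 25),
      stratum_spec("North America", "urban", -0.5, 1.9, n_sites = 10)),
      seed = s)
    sm <- aggregate(delta15N ~ region, obs, mean)
    sm$delta15N[sm$region == "East Asia"] -
      sm$delta15N[sm$region == "North America"]
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.8)
  expect_gt(mean(diffs), 1)
})

test_that("trend fit matches the direct least-squares formulas", {
  # perfectly linear data: r = 1, zero-width band
  d <- data.frame(year = 2000:2009, delta15N = 2000:2009 * 0.3 - 600)
  tr <- fit_trend(d)
  expect_equal(tr$pearson_r, 1)
  expect_equal(tr$slope, 0.3)
  expect_lt(max(tr$band$upr - tr$band$lwr), 1e-8)

  # noisy slope-0 data: r near 0
  set.seed(4)
  d0 <- data.frame(year = rep(2000:2015, each = 3),
                   delta15N = rnorm(48))
  tr0 <- fit_trend(d0)
  expect_lt(abs(tr0$pearson_r), 0.3)

  # brute-force oracle: slope = cov/var, r = cor
  set.seed(9)
  d1 <- data.frame(year = rep(2000:2010, 2),
                   delta15N = rnorm(22, seq(-1, 1, length.out = 22), 0.5))
  tr1 <- fit_trend(d1)
  expect_equal(tr1$slope, cov(d1$year, d1$delta15N) / var(d1$year))
  expect_equal(tr1$pearson_r, cor(d1$year, d1$delta15N))
  expect_equal(tr1$p_value, cor.test(d1$year, d1$delta15N)$p.value)

  # shift equivariance: adding a constant moves intercept only
  d2 <- d1
  d2$delta15N <- d2$delta15N + 5
  tr2 <- fit_trend(d2)
  expect_equal(tr2$slope, tr1$slope)
  expect_equal(tr2$intercept, tr1$intercept + 5)
  expect_equal(tr2$pearson_r, tr1$pearson_r)

  expect_error(fit_trend(data.frame(year = c(2000, 2000, 2001),
                                    delta15N = 1:3)), "3 distinct years")
})

test_that("trend fitting aggregates replicate observations to site-year means", {
  obs <- make_obs("Europe", "urban", 0, n_sites = 6, seed = 5)
  obs$year <- rep(2000:2005, length.out = nrow(obs))
  tr <- fit_trend(obs)
  manual <- aggregate(delta15N ~ site_id + region + site_class + year, obs,
                      mean)
  expect_equal(tr$slope, cov(manual$year, manual$delta15N) / var(manual$year))
})
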
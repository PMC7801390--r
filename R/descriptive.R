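# Descriptive statistics on the observation table: spatial group
# comparisons (regions, urban vs non-urban) and temporal trends.

# Site-level means: tests operate on the mean of replicate measurements per
# site (optionally per site-year), not on raw replicates, so heavily
# replicated sites do not dominate.
#' @noRd
site_means <- function(observations, by_year = FALSE) {
  need <- c("site_id", "region", "site_class", "year", "delta15N")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    stopf("observation table needs columns: %s", paste(need, collapse = ", "))
  keys <- if (by_year) c("site_id", "region", "site_class", "year")
          else c("site_id", "region", "site_class")
  out <- stats::aggregate(observations["delta15N"], observations[keys], mean)
  out
}

#' Compare d15N between site classes and among regions
#'
#' Runs the descriptive comparison battery on site-level mean d15N values:
#' a one-way analysis of variance across regions within each site class, and
#' a Welch two-sample test between urban and non-urban sites within each
#' region. Because regional site counts are small and precipitation-nitrate
#' d15N is highly variable, the conventional significance level for these
#' spatial contrasts is alpha = 0.1.
#'
#' @param observations observation table (`site_id`, `region`, `site_class`,
#'   `year`, `delta15N`).
#' @param alpha significance level (default 0.1).
#' @return data.frame with one row per test: `test`, `site_class` or
#'   `region`, group summary columns, `statistic`, `p_value`, `significant`.
#'   Degenerate groups (fewer than 2 sites) are skipped with a warning.
#' @export
compare_groups <- function(observations, alpha = 0.1) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  sm <- site_means(observations)
  rows <- list()

  for (cls in unique(sm$site_class)) {
    d <- sm[sm$site_class == cls, ]
    counts <- table(d$region)
    ok <- names(counts)[counts >= 2]
    if (length(ok) < 2) {
      warning(sprintf("skipping ANOVA for %s sites: need >= 2 regions with >= 2 sites", cls),
              call. = FALSE)
    } else {
      d <- d[d$region %in% ok, ]
      fit <- stats::aov(delta15N ~ region, data = d)
      tab <- summary(fit)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        test = "anova_regions", group = cls,
        n = nrow(d), statistic = tab[1, "F value"],
        p_value = tab[1, "Pr(>F)"], stringsAsFactors = FALSE)
    }
  }

  for (reg in unique(sm$region)) {
    d <- sm[sm$region == reg, ]
    nu <- sum(d$site_class == "urban")
    nn <- sum(d$site_class == "non-urban")
    if (nu < 2 || nn < 2) {
      warning(sprintf("skipping urban/non-urban test in %s: need >= 2 sites per class", reg),
              call. = FALSE)
      next
    }
    tt <- stats::t.test(delta15N ~ site_class, data = d)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "urban_vs_nonurban", group = reg,
      n = nu + nn, statistic = unname(tt$statistic),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }

  if (!length(rows)) stopf("no testable group structure in the observations")
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Temporal trend of site-year mean d15N
#'
#' Ordinary least-squares fit of site-year mean d15N on sampling year, with
#' the Pearson correlation, its two-sided p-value, and a pointwise 95%
#' confidence band for the mean response.
#'
#' @param site_year_means data.frame with columns `year` and `delta15N`
#'   (e.g. from an observation table aggregated per site-year), or a full
#'   observation table, which is aggregated first.
#' @return list of class `"nox_trend"`: `slope` (permil/yr), `intercept`,
#'   `pearson_r`, `p_value`, `band` (data.frame year/fit/lwr/upr over the
#'   distinct years), and the underlying `lm` fit.
#' @export
fit_trend <- function(site_year_means) {
  d <- site_year_means
  if (all(c("site_id", "site_class") %in% names(d)))
    d <- site_means(d, by_year = TRUE)
  if (!all(c("year", "delta15N") %in% names(d)))
    stopf("need columns 'year' and 'delta15N'")
  if (length(unique(d$year)) < 3L)
    stopf("trend fitting needs at least 3 distinct years")
  fit <- stats::lm(delta15N ~ year, data = d)
  ct <- stats::cor.test(d$year, d$delta15N)
  yrs <- sort(unique(d$year))
  band <- stats::predict(fit, newdata = data.frame(year = yrs),
                         interval = "confidence", level = 0.95)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = unname(ct$estimate), p_value = ct$p.value,
    band = data.frame(year = yrs, fit = band[, "fit"],
                      lwr = band[, "lwr"], upr = band[, "upr"]),
    lm = fit), class = "nox_trend")
}

#' @export
print.nox_trend <- function(x, ...) {
  cat(sprintf("Trend: slope %.3f permil/yr, r = %.3f, p = %.3g\n",
              x$slope, x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
plot.nox_trend <- function(x, ...) {
  d <- x$lm$model
  graphics::plot(d$year, d$delta15N, xlab = "year",
                 ylab = "d15N (permil)", ...)
  graphics::abline(x$lm)
  graphics::lines(x$band$year, x$band$lwr, lty = 2, col = "grey40")
  graphics::lines(x$band$year, x$band$upr, lty = 2, col = "grey40")
  invisible(x)
}
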
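# Synthetic-data generators. The compiled precipitation-nitrate isotope data
# behind the published regional summaries exist only as printed figures, so
# every downstream stage is exercised against generated tables that carry the
# same statistical structure: per-stratum normal d15N distributions, replicate
# measurements nested in sites, and forward-simulated end-member mixtures.

#' Specify one observation stratum (region x urban/non-urban)
#'
#' A stratum is one region by site-class cell of the observation design,
#' described by the population mean and SD of precipitation-nitrate
#' \eqn{\delta^{15}}N (permil) across its sites, the number of sites, the
#' replicate count per site-year, and the sampling-year range.
#'
#' The stratum SD is split between a between-site and a within-site component
#' (`within_site_frac` of the *variance* goes within site, default 50/50), so
#' pooled draws recover the stated mean and SD while preserving the replicate
#' nesting the mixing model consumes.
#'
#' @param region region label, e.g. `"East Asia"`.
#' @param site_class `"urban"` or `"non-urban"`.
#' @param mean_delta,sd_delta stratum mean and SD of d15N, permil.
#' @param n_sites number of sites (>= 1).
#' @param replicates_per_site replicate measurements per site-year (>= 1).
#' @param years inclusive integer vector of candidate sampling years.
#' @param years_per_site number of distinct years each site is sampled in.
#' @param within_site_frac fraction of stratum variance placed within site.
#' @return A list of class `"stratum_spec"`.
#' @examples
#' stratum_spec("East Asia", "urban", 1.7, 5.4, n_sites = 25)
#' @export
stratum_spec <- function(region, site_class, mean_delta, sd_delta,
                         n_sites, replicates_per_site = 5L,
                         years = 2000:2017, years_per_site = 1L,
                         within_site_frac = 0.5) {
  if (!site_class %in% c("urban", "non-urban"))
    stopf("'site_class' must be \"urban\" or \"non-urban\"")
  check_number(mean_delta, "mean_delta")
  check_number(sd_delta, "sd_delta", lower = 0)
  check_number(n_sites, "n_sites", lower = 1)
  check_number(replicates_per_site, "replicates_per_site", lower = 1)
  check_number(within_site_frac, "within_site_frac", lower = 0, upper = 1)
  years <- as.integer(years)
  if (length(years) < 1L) stopf("'years' must be non-empty")
  check_number(years_per_site, "years_per_site", lower = 1,
               upper = length(years))
  structure(list(region = as.character(region), site_class = site_class,
                 mean_delta = mean_delta, sd_delta = sd_delta,
                 n_sites = as.integer(n_sites),
                 replicates_per_site = as.integer(replicates_per_site),
                 years = years, years_per_site = as.integer(years_per_site),
                 within_site_frac = within_site_frac),
            class = "stratum_spec")
}

#' Generate a synthetic observation table
#'
#' Draws site-level mean d15N values from the stratum distribution and
#' replicate observations around each site mean, for every stratum supplied.
#' Deterministic given `seed`.
#'
#' @param strata a `stratum_spec` or list of them.
#' @param seed integer seed.
#' @return data.frame with columns `site_id`, `region`, `site_class`,
#'   `year`, `delta15N` (one row per replicate measurement).
#' @examples
#' obs <- simulate_observations(
#'   stratum_spec("East Asia", "urban", 1.7, 5.4, n_sites = 5), seed = 1)
#' head(obs)
#' @export
simulate_observations <- function(strata, seed) {
  if (inherits(strata, "stratum_spec")) strata <- list(strata)
  if (!length(strata)) stopf("'strata' must be non-empty")
  if (!all(vapply(strata, inherits, logical(1), "stratum_spec")))
    stopf("'strata' must be stratum_spec objects")
  with_seed(seed, {
    parts <- lapply(seq_along(strata), function(i) {
      st <- strata[[i]]
      sd_between <- st$sd_delta * sqrt(1 - st$within_site_frac)
      sd_within <- st$sd_delta * sqrt(st$within_site_frac)
      site_means <- stats::rnorm(st$n_sites, st$mean_delta, sd_between)
      rows <- lapply(seq_len(st$n_sites), function(s) {
        yrs <- if (st$years_per_site >= length(st$years)) st$years
               else sort(sample(st$years, st$years_per_site))
        do.call(rbind, lapply(yrs, function(y) {
          data.frame(
            site_id = sprintf("%s_%s_%02d",
                              gsub("\\s+", "", st$region), st$site_class, s),
            region = st$region, site_class = st$site_class, year = y,
            delta15N = stats::rnorm(st$replicates_per_site,
                                    site_means[s], sd_within),
            stringsAsFactors = FALSE)
        }))
      })
      do.call(rbind, rows)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Specify a forward-simulated isotope mixture
#'
#' Describes the forward direction of the isotope mass balance: each
#' simulated observation is
#' \deqn{\delta = \sum_k f_k \, \delta_{k,i} + \Delta_i + \epsilon_i}
#' with per-observation source draws
#' \eqn{\delta_{k,i} \sim N(\mu_k, \sigma_k)}, atmospheric-processing offset
#' \eqn{\Delta_i \sim N(\mathrm{offset\_mean}, \mathrm{offset\_sd})} and
#' residual noise \eqn{\epsilon_i \sim N(0, \mathrm{residual\_sd})}.
#' Used for parameter-recovery testing of the mixing model.
#'
#' @param fractions numeric simplex vector of true source fractions
#'   (length 3 or 4, non-negative, summing to 1 within 1e-9).
#' @param sources a [nox_sources()] table with one row per fraction.
#' @param offset_mean,offset_sd offset distribution, permil.
#' @param residual_sd residual noise SD, permil.
#' @param n_obs number of observations to simulate.
#' @return A list of class `"mixture_spec"`.
#' @export
mixture_spec <- function(fractions, sources, offset_mean = 0, offset_sd = 0,
                         residual_sd = 0, n_obs) {
  sources <- validate_sources(sources)
  if (!is.numeric(fractions) || length(fractions) != nrow(sources))
    stopf("'fractions' must have one entry per source")
  if (!length(fractions) %in% c(3L, 4L))
    stopf("mixtures support 3 or 4 sources")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stopf("'fractions' must be non-negative and sum to 1 within 1e-9")
  check_number(offset_mean, "offset_mean")
  check_number(offset_sd, "offset_sd", lower = 0)
  check_number(residual_sd, "residual_sd", lower = 0)
  check_number(n_obs, "n_obs", lower = 1)
  structure(list(fractions = fractions, sources = sources,
                 offset_mean = offset_mean, offset_sd = offset_sd,
                 residual_sd = residual_sd, n_obs = as.integer(n_obs)),
            class = "mixture_spec")
}

#' Simulate observations from a mixture specification
#'
#' @param spec a [mixture_spec()].
#' @param seed integer seed.
#' @param year nominal sampling year recorded in the table.
#' @return data.frame in the observation-table schema (`site_id`, `region`,
#'   `site_class`, `year`, `delta15N`); the true fractions are attached as
#'   attribute `"true_fractions"`.
#' @export
simulate_mixture <- function(spec, seed, year = 2000L) {
  if (!inherits(spec, "mixture_spec")) stopf("'spec' must be a mixture_spec")
  with_seed(seed, {
    n <- spec$n_obs
    K <- length(spec$fractions)
    src_draws <- vapply(seq_len(K), function(k)
      stats::rnorm(n, spec$sources$mean[k], spec$sources$sd[k]),
      numeric(n))
    if (n == 1L) src_draws <- matrix(src_draws, nrow = 1L)
    delta <- as.vector(src_draws %*% spec$fractions) +
      stats::rnorm(n, spec$offset_mean, spec$offset_sd) +
      stats::rnorm(n, 0, spec$residual_sd)
    out <- data.frame(
      site_id = "synthetic_mixture",
      region = "synthetic",
      site_class = if (K == 4L) "urban" else "non-urban",
      year = as.integer(year), delta15N = delta, stringsAsFactors = FALSE)
    attr(out, "true_fractions") <- spec$fractions
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Generate synthetic ambient-chemistry records
#'
#' Simulates co-located ambient measurements used by the initial-NOx
#' reconstruction: concentrations of NO2, HNO3 and particulate nitrate
#' (log-normal, strictly positive), the NO2 fraction of NOx (truncated
#' normal on (0, 1]), and d15N of NOx, HNO3 and particulate nitrate
#' (normal). Defaults for `f_no2` (0.64 +/- 0.10) and `d15n_nox`
#' (-7.7 +/- 2.9 permil) follow the global mean values used when ambient
#' coverage is sparse.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param conc_meanlog,conc_sdlog length-3 log-scale parameters for the
#'   NO2, HNO3 and p-NO3 concentrations (any single consistent unit).
#' @param f_no2_mean,f_no2_sd NO2-fraction distribution, truncated to (0, 1].
#' @param d15n_nox_mean,d15n_nox_sd,d15n_hno3_mean,d15n_hno3_sd,d15n_pno3_mean,d15n_pno3_sd
#'   isotope distributions, permil.
#' @return data.frame with columns `c_no2`, `c_hno3`, `c_pno3`, `f_no2`,
#'   `d15n_nox`, `d15n_hno3`, `d15n_pno3`.
#' @export
simulate_ambient <- function(n, seed,
                             conc_meanlog = c(1.5, 0.5, 0.8),
                             conc_sdlog = c(0.4, 0.4, 0.4),
                             f_no2_mean = 0.64, f_no2_sd = 0.10,
                             d15n_nox_mean = -7.7, d15n_nox_sd = 2.9,
                             d15n_hno3_mean = 1.0, d15n_hno3_sd = 3.0,
                             d15n_pno3_mean = 5.0, d15n_pno3_sd = 4.0) {
  check_number(n, "n", lower = 1)
  if (length(conc_meanlog) != 3L || length(conc_sdlog) != 3L)
    stopf("'conc_meanlog' and 'conc_sdlog' must have length 3")
  if (any(!is.finite(conc_meanlog)) || any(conc_sdlog < 0))
    stopf("concentration parameters must be finite with sdlog >= 0")
  check_number(f_no2_mean, "f_no2_mean", lower = 1e-12, upper = 1)
  check_number(f_no2_sd, "f_no2_sd", lower = 0)
  with_seed(seed, {
    n <- as.integer(n)
    out <- data.frame(
      c_no2 = stats::rlnorm(n, conc_meanlog[1], conc_sdlog[1]),
      c_hno3 = stats::rlnorm(n, conc_meanlog[2], conc_sdlog[2]),
      c_pno3 = stats::rlnorm(n, conc_meanlog[3], conc_sdlog[3]),
      f_no2 = rtruncnorm(n, f_no2_mean, f_no2_sd, lower = 1e-12, upper = 1),
      d15n_nox = stats::rnorm(n, d15n_nox_mean, d15n_nox_sd),
      d15n_hno3 = stats::rnorm(n, d15n_hno3_mean, d15n_hno3_sd),
      d15n_pno3 = stats::rnorm(n, d15n_pno3_mean, d15n_pno3_sd))
    attr(out, "seed") <- as.integer(seed)
    out
  })
}
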
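# Regional aggregation and emission budgeting.
#
# Per-source urban and non-urban contributions are combined into a
# region-wide contribution with population weights, split into fossil
# (coal + vehicle) and non-fossil (biomass + microbial) totals, and the
# non-fossil share converts the inventory fossil-fuel emission amount into
# total and non-fossil emission budgets:
#   A_total = A_fossil / F_fossil,   A_non_fossil = A_total - A_fossil.
# Uncertainty is propagated by Monte Carlo with truncated-normal inputs.

#' Population weights for urban/non-urban aggregation
#'
#' @param p_urban fraction of the regional population in urban areas.
#' @param p_non_urban fraction in non-urban areas; defaults to the
#'   complement. The two must sum to 1 within 1e-9.
#' @return list of class `"population_weights"`.
#' @export
population_weights <- function(p_urban, p_non_urban = 1 - p_urban) {
  check_number(p_urban, "p_urban", lower = 0, upper = 1)
  check_number(p_non_urban, "p_non_urban", lower = 0, upper = 1)
  if (abs(p_urban + p_non_urban - 1) > 1e-9)
    stopf("population weights must sum to 1")
  structure(list(p_urban = p_urban, p_non_urban = p_non_urban),
            class = "population_weights")
}

#' Region-wide contribution of one source
#'
#' Combines a source's urban and non-urban fractional contributions into a
#' single region-wide contribution using population weights:
#' `F = f_urban * P_urban + f_non_urban * P_non_urban`.
#'
#' The population-weighted *sum* is the only form that keeps the result a
#' fraction and preserves sum-to-one across sources; a literal *product* of
#' all four terms (which does neither) is available via `rule = "product"`
#' purely for auditing against sources that print it that way.
#'
#' @param f_urban,f_non_urban the source's contribution at urban and
#'   non-urban sites, each in the unit interval. Vectors are combined
#'   elementwise.
#' @param weights a [population_weights()] object.
#' @param rule `"weighted_sum"` (the default, and the meaningful form) or
#'   `"product"`.
#' @return region-wide contribution(s).
#' @examples
#' regionwide_contribution(0.4, 0.6, population_weights(0.5))  # 0.5
#' @export
regionwide_contribution <- function(f_urban, f_non_urban, weights,
                                    rule = c("weighted_sum", "product")) {
  rule <- match.arg(rule)
  if (!inherits(weights, "population_weights"))
    stopf("'weights' must be population_weights()")
  if (any(f_urban < 0) || any(f_urban > 1) ||
      any(f_non_urban < 0) || any(f_non_urban > 1))
    stopf("contribution fractions must lie in [0, 1]")
  if (rule == "weighted_sum")
    f_urban * weights$p_urban + f_non_urban * weights$p_non_urban
  else
    f_urban * weights$p_urban * f_non_urban * weights$p_non_urban
}

#' Split source contributions into fossil and non-fossil totals
#'
#' Fossil = coal combustion (S1) + vehicle exhausts (S2); non-fossil =
#' biomass burning (S3) + microbial N cycles (S4). For a three-source
#' (non-urban) region pass 0 for the vehicle term.
#'
#' @param f_s1,f_s2,f_s3,f_s4 per-source contributions in the unit
#'   interval, summing
#'   to at most 1 + 1e-6.
#' @return named numeric vector `c(fossil = , non_fossil = )`.
#' @examples
#' fossil_nonfossil_split(0.2, 0.23, 0.3, 0.27)  # 0.43 / 0.57
#' @export
fossil_nonfossil_split <- function(f_s1, f_s2 = 0, f_s3 = 0, f_s4 = 0) {
  fr <- unname(c(f_s1, f_s2, f_s3, f_s4))
  if (any(fr < 0) || any(fr > 1)) stopf("fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-6) stopf("fractions sum to more than 1")
  c(fossil = fr[1] + fr[2], non_fossil = fr[3] + fr[4])
}

#' Emission budget from the inventory fossil amount and the fossil share
#'
#' Converts the inventory amount of fossil-fuel NOx emissions and the
#' isotope-derived fossil share into the total and non-fossil emission
#' amounts: `a_total = a_fossil / f_fossil` and
#' `a_non_fossil = a_total - a_fossil` (equivalently
#' `a_total * (1 - f_fossil)`, which holds exactly).
#'
#' @param a_fossil fossil-fuel NOx emission amount (Mt N yr^-1 or any fixed
#'   unit), >= 0.
#' @param f_fossil fossil share of total emissions, in (0, 1]. `f_fossil = 0`
#'   (an all-non-fossil regime) is outside the model's validity and errors.
#' @return list of class `"emission_budget"` with `a_fossil`, `f_fossil`,
#'   `f_non_fossil`, `a_total`, `a_non_fossil`.
#' @examples
#' emission_budget(a_fossil = 37.9 * 0.43, f_fossil = 0.43)
#' @export
emission_budget <- function(a_fossil, f_fossil) {
  check_number(a_fossil, "a_fossil", lower = 0)
  if (!is.numeric(f_fossil) || length(f_fossil) != 1L || !is.finite(f_fossil))
    stopf("'f_fossil' must be a single number")
  if (f_fossil <= 0)
    stopf("'f_fossil' must be > 0: an all-non-fossil regime is outside the mass-balance validity")
  if (f_fossil > 1) stopf("'f_fossil' must be <= 1")
  a_total <- a_fossil / f_fossil
  structure(list(a_fossil = a_fossil, f_fossil = f_fossil,
                 f_non_fossil = 1 - f_fossil, a_total = a_total,
                 a_non_fossil = a_total - a_fossil),
            class = "emission_budget")
}

#' @export
print.emission_budget <- function(x, digits = 3, ...) {
  cat(sprintf("Emission budget: fossil %.*f, total %.*f, non-fossil %.*f (f_fossil = %.3f)\n",
              digits, x$a_fossil, digits, x$a_total, digits, x$a_non_fossil,
              x$f_fossil))
  invisible(x)
}

#' Monte Carlo uncertainty propagation for the emission budget
#'
#' Propagates uncertainty in the fossil amount and the fossil share into the
#' total and non-fossil amounts. Inputs are drawn from truncated normals
#' (the share on (0, 1], the amount non-negative), or taken directly from
#' supplied draws (e.g. posterior fractions from [nox_mix()]); the budget
#' identity holds per draw, so conservation is exact in every retained
#' sample.
#'
#' @param a_fossil,a_fossil_sd mean and SD of the fossil amount.
#' @param f_fossil,f_fossil_sd mean and SD of the fossil share.
#' @param n_draws number of Monte Carlo draws (>= 1000).
#' @param seed integer seed.
#' @param f_draws,a_draws optional vectors of pre-computed draws replacing
#'   the truncated-normal sampling (must have equal length if both given;
#'   `n_draws` is then ignored).
#' @param keep_draws retain the per-draw quantity matrix in the result (for
#'   auditing truncation and per-draw conservation).
#' @return list of class `"emission_budget_mc"`: `central` (the
#'   [emission_budget()] at the input means), `mean` and `sd` (named vectors
#'   over a_fossil, a_total, a_non_fossil, f_fossil, f_non_fossil), and
#'   `n_draws`.
#' @export
propagate_uncertainty <- function(a_fossil, a_fossil_sd, f_fossil,
                                  f_fossil_sd, n_draws = 10000L, seed = 1L,
                                  f_draws = NULL, a_draws = NULL,
                                  keep_draws = FALSE) {
  check_number(a_fossil, "a_fossil", lower = 0)
  check_number(a_fossil_sd, "a_fossil_sd", lower = 0)
  check_number(f_fossil, "f_fossil", lower = 1e-12, upper = 1)
  check_number(f_fossil_sd, "f_fossil_sd", lower = 0)
  if (is.null(f_draws) || is.null(a_draws))
    check_number(n_draws, "n_draws", lower = 1000)
  with_seed(seed, {
    f <- if (!is.null(f_draws)) f_draws
         else rtruncnorm(n_draws, f_fossil, f_fossil_sd, lower = 1e-12,
                         upper = 1)
    a <- if (!is.null(a_draws)) a_draws
         else rtruncnorm(if (is.null(f_draws)) n_draws else length(f),
                         a_fossil, a_fossil_sd, lower = 0)
    if (length(f) != length(a))
      stopf("'f_draws' and 'a_draws' must have equal length")
    if (any(f <= 0) || any(f > 1)) stopf("supplied f_draws outside (0, 1]")
    if (any(a < 0)) stopf("supplied a_draws negative")
    a_total <- a / f
    a_nf <- a_total - a
    qty <- cbind(a_fossil = a, a_total = a_total, a_non_fossil = a_nf,
                 f_fossil = f, f_non_fossil = 1 - f)
    structure(list(
      central = emission_budget(a_fossil, f_fossil),
      mean = colMeans(qty),
      sd = apply(qty, 2, stats::sd),
      draws = if (keep_draws) qty,
      n_draws = length(f), seed = as.integer(seed)),
      class = "emission_budget_mc")
  })
}

#' @export
print.emission_budget_mc <- function(x, digits = 2, ...) {
  cat(sprintf("Monte Carlo emission budget (%d draws):\n", x$n_draws))
  for (nm in names(x$mean))
    cat(sprintf("  %-13s %8.*f +/- %.*f\n", nm, digits, x$mean[[nm]],
                digits, x$sd[[nm]]))
  cat(sprintf("  central: total %.2f, non-fossil %.2f\n",
              x$central$a_total, x$central$a_non_fossil))
  invisible(x)
}
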
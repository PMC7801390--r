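# Bayesian isotope mixing model (SIAR-style).
#
# Observed precipitation-nitrate d15N values are modelled as draws from
#   Normal( sum_k f_k mu_k + offset_mean,
#           sum_k f_k^2 sigma_k^2 + offset_sd^2 + sigma_res^2 )
# with a flat Dirichlet(1,...,1) prior on the source-fraction simplex f and
# a half-normal prior on the residual SD. Sampling is random-walk Metropolis
# on an unconstrained parameterisation: an additive-log-ratio (ALR) transform
# of the simplex (Jacobian-corrected so the prior on f stays uniform) plus
# log(sigma_res). The proposal scale adapts during burn-in toward a ~23%
# acceptance rate and is then frozen.

#' MCMC settings for the mixing model
#'
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded per chain (`< n_iter`); the proposal
#'   scale adapts only during burn-in.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param proposal_scale initial random-walk proposal SD.
#' @param resid_scale scale of the half-normal prior on the residual SD
#'   (permil). Default 5 permil, wide relative to typical source spreads.
#' @param adapt adapt the proposal scale during burn-in (logical).
#' @return A list of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_iter = 10000L, burn_in = 5000L, thin = 2L,
                          n_chains = 4L, seed = 1L, proposal_scale = 0.4,
                          resid_scale = 5, adapt = TRUE) {
  check_number(n_iter, "n_iter", lower = 2)
  check_number(burn_in, "burn_in", lower = 0)
  if (burn_in >= n_iter) stopf("'burn_in' must be < 'n_iter'")
  check_number(thin, "thin", lower = 1)
  check_number(n_chains, "n_chains", lower = 1)
  check_number(proposal_scale, "proposal_scale", lower = 1e-8)
  check_number(resid_scale, "resid_scale", lower = 1e-8)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 resid_scale = resid_scale, adapt = isTRUE(adapt)),
            class = "mcmc_settings")
}

# softmax of c(z, 0): maps R^(K-1) to the interior of the K-simplex (ALR).
#' @noRd
alr_inv <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0), 0))
  e / sum(e)
}

#' Fit the Bayesian source-apportionment mixing model
#'
#' Infers posterior source fractions for 3- or 4-source nitrogen-isotope
#' mass balance: the observed d15N values are a convex combination of the
#' source signatures plus the atmospheric-processing offset, with combined
#' variance from source spread, offset uncertainty and a residual term.
#'
#' @param observations numeric vector of precipitation-nitrate d15N values
#'   (permil), or a data.frame with a `delta15N` column.
#' @param sources a [nox_sources()] table (3 or 4 rows).
#' @param offset a [frac_offset()]; its mean shifts the mixture and its SD
#'   enters the likelihood variance. Default 0 +/- 0 (no processing offset).
#' @param settings an [mcmc_settings()] object.
#' @return An object of class `"nox_mix"`: a list with `draws` (matrix of
#'   retained simplex draws, one column per source), `sigma_res` (residual-SD
#'   draws), `chain` (chain index per draw), `accept_rate`, plus the inputs.
#'   Methods: `print`, `summary`, `coef` (posterior mean fractions), `plot`,
#'   `simulate` (posterior predictive), `fitted`, `residuals`.
#' @details With all-identical source means and zero SDs the fractions are
#'   unidentifiable; the fit proceeds with a warning (the posterior then
#'   simply returns the prior).
#' @examples
#' src <- nox_sources(vehicle = NULL, biomass = c(1, 4))[-2, ]  # coal+microbial
#' fit <- nox_mix(rnorm(30, -8, 2), src,
#'                settings = mcmc_settings(n_iter = 600, burn_in = 300,
#'                                         n_chains = 2, seed = 1))
#' coef(fit)
#' @export
nox_mix <- function(observations, sources, offset = frac_offset(0, 0),
                    settings = mcmc_settings()) {
  if (is.data.frame(observations)) {
    if (!"delta15N" %in% names(observations))
      stopf("observation data.frame needs a 'delta15N' column")
    observations <- observations$delta15N
  }
  if (!is.numeric(observations) || length(observations) < 1L ||
      any(!is.finite(observations)))
    stopf("'observations' must be a non-empty finite numeric vector")
  sources <- validate_sources(sources)
  K <- nrow(sources)
  if (!K %in% c(3L, 4L) && K != 2L)
    stopf("the mixing model supports 2-4 sources")
  if (!inherits(offset, "frac_offset")) stopf("'offset' must be a frac_offset")
  if (!inherits(settings, "mcmc_settings"))
    stopf("'settings' must be mcmc_settings()")
  if (length(unique(sources$mean)) == 1L)
    warning("all source means identical: fractions are not identifiable",
            call. = FALSE)

  y <- observations
  n <- length(y)
  ybar <- mean(y)
  ss <- sum((y - ybar)^2)
  mu <- sources$mean
  sig2 <- sources$sd^2
  off_m <- offset$mean
  off_v <- offset$sd^2
  s0 <- settings$resid_scale

  # log posterior on theta = (z[1..K-1], log sigma_res); flat Dirichlet on f
  # contributes the ALR Jacobian sum(log f); half-normal on sigma contributes
  # -sigma^2/(2 s0^2) plus the log-scale Jacobian log sigma.
  log_post <- function(theta) {
    f <- alr_inv(theta[seq_len(K - 1L)])
    sigma <- exp(theta[K])
    m <- sum(f * mu) + off_m
    v <- sum(f^2 * sig2) + off_v + sigma^2
    ll <- -0.5 * n * log(2 * pi * v) - (ss + n * (ybar - m)^2) / (2 * v)
    ll + sum(log(f)) - sigma^2 / (2 * s0^2) + theta[K]
  }

  n_par <- K
  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    theta <- c(rep(0, K - 1L), log(max(stats::sd(y), 0.1)))
    lp <- log_post(theta)
    scale <- settings$proposal_scale
    keep_idx <- seq.int(settings$burn_in + 1L, settings$n_iter,
                        by = settings$thin)
    n_keep <- length(keep_idx)
    draws <- matrix(NA_real_, n_keep, K)
    sig_draws <- numeric(n_keep)
    kept <- 0L
    acc <- 0L
    acc_win <- 0L
    for (it in seq_len(settings$n_iter)) {
      prop <- theta + stats::rnorm(n_par, 0, scale)
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc <- acc + 1L
        acc_win <- acc_win + 1L
      }
      if (settings$adapt && it <= settings$burn_in && it %% 50L == 0L) {
        rate <- acc_win / 50
        scale <- scale * exp(0.5 * (rate - 0.234))
        acc_win <- 0L
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in - 1L) %% settings$thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- alr_inv(theta[seq_len(K - 1L)])
        sig_draws[kept] <- exp(theta[K])
      }
    }
    list(draws = draws[seq_len(kept), , drop = FALSE],
         sigma = sig_draws[seq_len(kept)],
         accept = acc / settings$n_iter)
  }

  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  chains <- lapply(seq_len(settings$n_chains),
                   function(cc) run_chain(settings$seed + cc - 1L))

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- sources$name
  structure(list(
    draws = draws,
    sigma_res = unlist(lapply(chains, `[[`, "sigma")),
    chain = rep(seq_len(settings$n_chains),
                vapply(chains, function(ch) nrow(ch$draws), integer(1))),
    accept_rate = vapply(chains, `[[`, numeric(1), "accept"),
    observations = y, sources = sources, offset = offset,
    settings = settings), class = "nox_mix")
}

#' @export
print.nox_mix <- function(x, ...) {
  cat(sprintf("Bayesian NOx mixing model: %d sources, %d observations, %d draws (%d chains)\n",
              ncol(x$draws), length(x$observations), nrow(x$draws),
              x$settings$n_chains))
  cat("Posterior mean fractions:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Posterior summary of source fractions
#'
#' @param object a fitted [nox_mix()] model.
#' @param prob mass of the equal-tailed credible interval (default 0.95).
#' @param ... unused.
#' @return data.frame with one row per source (plus the residual SD): mean,
#'   sd, interval bounds, and the potential scale reduction factor when the
#'   fit has >= 2 chains.
#' @export
summary.nox_mix <- function(object, prob = 0.95, ...) {
  check_number(prob, "prob", lower = 1e-6, upper = 1 - 1e-6)
  a <- (1 - prob) / 2
  pars <- cbind(object$draws, sigma_res = object$sigma_res)
  out <- data.frame(
    parameter = colnames(pars),
    mean = colMeans(pars),
    sd = apply(pars, 2, stats::sd),
    lower = apply(pars, 2, stats::quantile, probs = a),
    upper = apply(pars, 2, stats::quantile, probs = 1 - a),
    row.names = NULL)
  if (object$settings$n_chains >= 2L) {
    rh <- check_convergence(object, quiet = TRUE)
    out$rhat <- c(rh$rhat, NA_real_)[seq_len(nrow(out))]
    out$rhat[nrow(out)] <- rhat_one(object$sigma_res, object$chain)
  }
  attr(out, "prob") <- prob
  class(out) <- c("summary.nox_mix", class(out))
  out
}

#' @export
print.summary.nox_mix <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%.0f%% equal-tailed intervals):\n",
              100 * attr(x, "prob")))
  print.data.frame(format(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.nox_mix <- function(object, ...) colMeans(object$draws)

#' @export
fitted.nox_mix <- function(object, ...) {
  m <- sum(coef(object) * object$sources$mean) + object$offset$mean
  rep(m, length(object$observations))
}

#' @export
residuals.nox_mix <- function(object, ...) {
  object$observations - fitted(object)
}

#' Posterior-predictive simulation from a fitted mixing model
#'
#' Draws new d15N observations: for each simulated value a posterior draw
#' (f, sigma_res) is selected and an observation is generated from the
#' likelihood's normal distribution.
#'
#' @param object a fitted [nox_mix()] model.
#' @param nsim number of simulated observations.
#' @param seed integer seed.
#' @param ... unused.
#' @return numeric vector of length `nsim`.
#' @export
simulate.nox_mix <- function(object, nsim = length(object$observations),
                             seed = 1L, ...) {
  with_seed(seed, {
    idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
    f <- object$draws[idx, , drop = FALSE]
    m <- as.vector(f %*% object$sources$mean) + object$offset$mean
    v <- as.vector(f^2 %*% object$sources$sd^2) + object$offset$sd^2 +
      object$sigma_res[idx]^2
    stats::rnorm(nsim, m, sqrt(v))
  })
}

#' @export
plot.nox_mix <- function(x, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::boxplot(as.data.frame(x$draws), ylim = c(0, 1),
                    ylab = "source fraction", las = 2,
                    main = "Posterior source contributions", ...)
  invisible(x)
}

#' @noRd
rhat_one <- function(par_draws, chain) {
  m <- length(unique(chain))
  if (m < 2L) return(NA_real_)
  per <- split(par_draws, chain)
  nmin <- min(lengths(per))
  per <- lapply(per, function(v) v[seq_len(nmin)])  # equal-length chains
  means <- vapply(per, mean, numeric(1))
  vars <- vapply(per, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W <= 0) return(if (B_over_n <= 0) 1 else Inf)
  sqrt((nmin - 1) / nmin + B_over_n / W)
}

#' Gelman-Rubin convergence check
#'
#' Computes the potential scale reduction factor for every source fraction
#' from the stored per-chain draws, and flags the run if any exceeds the
#' threshold.
#'
#' @param fit a fitted [nox_mix()] with >= 2 chains.
#' @param threshold flag threshold (default 1.05).
#' @param quiet suppress the message when flagged.
#' @return list with `rhat` (named vector), `pass` (per-parameter logical)
#'   and `ok` (overall).
#' @export
check_convergence <- function(fit, threshold = 1.05, quiet = FALSE) {
  if (!inherits(fit, "nox_mix")) stopf("'fit' must be a nox_mix model")
  if (fit$settings$n_chains < 2L)
    stopf("convergence diagnostics need at least 2 chains")
  rh <- vapply(seq_len(ncol(fit$draws)),
               function(j) rhat_one(fit$draws[, j], fit$chain), numeric(1))
  names(rh) <- colnames(fit$draws)
  pass <- rh < threshold
  if (!all(pass) && !quiet)
    message("convergence flagged: max PSRF = ", round(max(rh), 3))
  list(rhat = rh, pass = pass, ok = all(pass))
}

#' Two-source closed-form inversion (test oracle)
#'
#' Algebraic inversion of the two-end-member mass balance: given the mean
#' observed d15N, two source signatures and the offset mean,
#' `f1 = (obs_mean - offset_mean - mu2) / (mu1 - mu2)`, clamped to the
#' unit interval.
#' Serves as an independent oracle for the MCMC fit at K = 2.
#'
#' @param obs_mean mean observed d15N, permil.
#' @param s1,s2 source signatures: length-2 `c(mean, sd)` vectors or rows of
#'   a [nox_sources()] table.
#' @param offset_mean offset mean, permil.
#' @return the fraction of source 1, clamped to the unit interval.
#' @examples
#' closed_form_two_source(-8.15, c(13.7, 3.9), c(-30.2, 6.7), 3.9)  # 0.413
#' @export
closed_form_two_source <- function(obs_mean, s1, s2, offset_mean = 0) {
  pick_mean <- function(s) {
    if (is.data.frame(s)) s$mean[1] else as.numeric(s)[1]
  }
  mu1 <- pick_mean(s1)
  mu2 <- pick_mean(s2)
  check_number(obs_mean, "obs_mean")
  check_number(offset_mean, "offset_mean")
  if (mu1 == mu2) stopf("source means are equal: inversion undefined")
  f1 <- (obs_mean - offset_mean - mu2) / (mu1 - mu2)
  min(max(f1, 0), 1)
}
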
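# Delimited-text readers/writers and the end-to-end pipeline runner.
# All tables are small, so plain tab-separated text with headers is the only
# on-disk format; readers validate the schema and report offending rows by
# line number.

OBS_COLUMNS <- c("site_id", "region", "site_class", "year", "delta15N_permil")
AMBIENT_COLUMNS <- c("c_no2", "c_hno3", "c_pno3", "f_no2",
                     "d15n_nox", "d15n_hno3", "d15n_pno3")

#' Read an observation table
#'
#' Reads a delimited text file with header columns `site_id`, `region`,
#' `site_class`, `year`, `delta15N_permil` (one row per replicate
#' measurement). Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame with columns `site_id`, `region`, `site_class`,
#'   `year` (integer), `delta15N` (numeric).
#' @export
read_observations <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  names(raw)[names(raw) == "delta15N"] <- "delta15N_permil"
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols))
    stopf("missing columns in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  year <- suppressWarnings(as.integer(raw$year))
  delta <- suppressWarnings(as.numeric(raw$delta15N_permil))
  bad <- which(is.na(year) | !is.finite(delta))
  if (length(bad))
    stopf("malformed rows in %s (file line%s %s): year must be integer, delta15N numeric",
          path, if (length(bad) > 1) "s" else "",
          paste(bad + 1L, collapse = ", "))
  if (any(!raw$site_class %in% c("urban", "non-urban")))
    stopf("'site_class' must be 'urban' or 'non-urban' in %s", path)
  data.frame(site_id = raw$site_id, region = raw$region,
             site_class = raw$site_class, year = year, delta15N = delta,
             stringsAsFactors = FALSE)
}

#' Write an observation table
#'
#' @param observations data.frame in the schema produced by
#'   [simulate_observations()] or [read_observations()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, sep = "\t") {
  need <- c("site_id", "region", "site_class", "year", "delta15N")
  if (!all(need %in% names(observations)))
    stopf("observation table needs columns: %s", paste(need, collapse = ", "))
  out <- observations[need]
  names(out)[names(out) == "delta15N"] <- "delta15N_permil"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ambient-chemistry records
#'
#' Delimited text with header naming the seven ambient fields (see
#' [ambient_records()]); an optional `obs_delta15N_permil` column carries
#' the co-located precipitation-nitrate d15N used for offset estimation.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return validated [ambient_records()] data.frame (with `obs_delta15N`
#'   column if present in the file).
#' @export
read_ambient_records <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(AMBIENT_COLUMNS, names(raw))
  if (length(missing_cols))
    stopf("missing columns in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  out <- ambient_records(raw[AMBIENT_COLUMNS])
  if ("obs_delta15N_permil" %in% names(raw))
    out$obs_delta15N <- as.numeric(raw$obs_delta15N_permil)
  out
}

#' Write ambient-chemistry records
#'
#' @param records [ambient_records()] table (optionally with `obs_delta15N`).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_ambient_records <- function(records, path, sep = "\t") {
  records <- ambient_records(records)
  out <- as.data.frame(records)[c(AMBIENT_COLUMNS,
                                  intersect("obs_delta15N", names(records)))]
  names(out)[names(out) == "obs_delta15N"] <- "obs_delta15N_permil"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one of
#' `observations`/`strata` must be given, and exactly one of
#' `offset`/`ambient`.
#'
#' @param observations observation table, or `NULL` to simulate.
#' @param strata list of [stratum_spec()]s used when `observations` is NULL.
#' @param offset a [frac_offset()] used as-is, or `NULL` to recompute.
#' @param ambient when `offset` is NULL: a list with elements `scenario1`
#'   and `scenario2`, each an ambient table carrying `obs_delta15N`; the two
#'   scenario estimates are pooled.
#' @param sources a 4-row [nox_sources()] table; non-urban fits drop the
#'   `vehicle_exhaust` row automatically.
#' @param inventory data.frame with columns `region`, `a_fossil`,
#'   `a_fossil_sd` (emission amounts, e.g. Mt yr^-1).
#' @param populations data.frame with columns `region`, `p_urban`.
#' @param year_windows optional named list, region -> integer year vector;
#'   observations outside a region's window are dropped before fitting.
#' @param settings [mcmc_settings()] for the per-group fits (its `seed` is
#'   overridden by seeds spawned from `seed`).
#' @param fit_mode `"site_year"` (fit each site-year, then average posterior
#'   means across site-years) or `"pooled"` (one fit per region x class).
#' @param fractions optional precomputed contribution table (columns
#'   `region`, `site_class`, `source`, `mean`, `sd`) that bypasses the MCMC
#'   stage entirely.
#' @param n_mc_draws Monte Carlo draws for budget uncertainty.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(observations = NULL, strata = NULL,
                            offset = NULL, ambient = NULL,
                            sources, inventory, populations,
                            year_windows = NULL,
                            settings = mcmc_settings(),
                            fit_mode = c("site_year", "pooled"),
                            fractions = NULL,
                            n_mc_draws = 10000L, seed = 1L) {
  fit_mode <- match.arg(fit_mode)
  if (is.null(observations) == is.null(strata) && is.null(fractions))
    stopf("give exactly one of 'observations' or 'strata'")
  if (is.null(offset) && is.null(ambient))
    stopf("give 'offset' or 'ambient' scenario tables")
  if (!is.null(offset) && !inherits(offset, "frac_offset"))
    stopf("'offset' must be a frac_offset")
  sources <- validate_sources(sources)
  if (nrow(sources) != 4L)
    stopf("pipeline 'sources' must have 4 rows (urban set); non-urban drops vehicle_exhaust")
  if (!"vehicle_exhaust" %in% sources$name)
    stopf("pipeline sources must include 'vehicle_exhaust'")
  if (!is.data.frame(inventory) ||
      !all(c("region", "a_fossil", "a_fossil_sd") %in% names(inventory)))
    stopf("'inventory' needs columns region, a_fossil, a_fossil_sd")
  if (!is.data.frame(populations) ||
      !all(c("region", "p_urban") %in% names(populations)))
    stopf("'populations' needs columns region, p_urban")
  structure(list(observations = observations, strata = strata,
                 offset = offset, ambient = ambient, sources = sources,
                 inventory = inventory, populations = populations,
                 year_windows = year_windows, settings = settings,
                 fit_mode = fit_mode, fractions = fractions,
                 n_mc_draws = n_mc_draws, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full source-apportionment pipeline
#'
#' Executes the inference chain end to end: obtain observations (supplied or
#' simulated), fix or recompute the processing offset, fit the mixing model
#' per stratum, aggregate urban/non-urban contributions with population
#' weights, split fossil vs non-fossil, and convert inventory fossil amounts
#' into total/non-fossil budgets with Monte Carlo uncertainty. Every stage
#' seed derives deterministically from the master seed, so the whole bundle
#' reproduces from the manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, the observation table,
#'   contribution summaries, budget table and a run manifest are written
#'   there as delimited text.
#' @return list of class `"nox_pipeline"` with elements `observations`,
#'   `offset`, `contributions` (per region x class x source posterior-mean
#'   table), `regional` (population-weighted per-source contributions),
#'   `split` (per-region fossil/non-fossil shares with SDs), `budgets`
#'   (per-region [propagate_uncertainty()] results), and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config")
  seeds <- list(simulate = spawn_seed(config$seed, "simulate"),
                mixing = spawn_seed(config$seed, "mixing"),
                mc = spawn_seed(config$seed, "mc"))

  ## stage 1: observations
  obs <- config$observations
  if (is.null(obs) && !is.null(config$strata))
    obs <- simulate_observations(config$strata, seeds$simulate)

  ## stage 2: offset
  offset <- config$offset
  if (is.null(offset)) {
    amb <- config$ambient
    if (!all(c("scenario1", "scenario2") %in% names(amb)))
      stopf("'ambient' must have elements scenario1 and scenario2")
    est <- lapply(c("scenario1", "scenario2"), function(sc) {
      tab <- amb[[sc]]
      if (!"obs_delta15N" %in% names(tab))
        stopf("ambient %s table needs an 'obs_delta15N' column", sc)
      scenario_offset(tab$obs_delta15N, tab[AMBIENT_COLUMNS], scenario = sc)
    })
    offset <- pooled_offset(est[[1]], est[[2]])
  }

  ## stage 3: per-stratum mixing fits (or precomputed fractions)
  contributions <- config$fractions
  if (is.null(contributions)) {
    if (is.null(obs)) stopf("no observations and no precomputed fractions")
    contributions <- fit_strata(obs, config, offset, seeds$mixing)
  }
  need <- c("region", "site_class", "source", "mean", "sd")
  if (!all(need %in% names(contributions)))
    stopf("contribution table needs columns: %s", paste(need, collapse = ", "))

  ## stage 4: regional aggregation + stage 5: budgets
  regional <- list()
  split_rows <- list()
  budgets <- list()
  for (i in seq_len(nrow(config$inventory))) {
    reg <- config$inventory$region[i]
    w <- population_weights(
      config$populations$p_urban[config$populations$region == reg][1])
    cc <- contributions[contributions$region == reg, ]
    if (!nrow(cc)) stopf("no contributions for region '%s'", reg)
    per_source <- lapply(config$sources$name, function(srcnm) {
      get_cell <- function(cls) {
        r <- cc[cc$site_class == cls & cc$source == srcnm, ]
        if (nrow(r)) c(r$mean[1], r$sd[1]) else c(0, 0)  # absent source = 0
      }
      u <- get_cell("urban")
      nu <- get_cell("non-urban")
      data.frame(region = reg, source = srcnm,
                 f_region = regionwide_contribution(u[1], nu[1], w),
                 sd_region = sqrt((w$p_urban * u[2])^2 +
                                  (w$p_non_urban * nu[2])^2),
                 stringsAsFactors = FALSE)
    })
    per_source <- do.call(rbind, per_source)
    regional[[reg]] <- per_source

    getF <- function(nm) per_source$f_region[per_source$source == nm]
    getS <- function(nm) per_source$sd_region[per_source$source == nm]
    sp <- fossil_nonfossil_split(getF("coal_combustion"),
                                 getF("vehicle_exhaust"),
                                 getF("biomass_burning"), getF("microbial_N"))
    sd_fossil <- sqrt(getS("coal_combustion")^2 + getS("vehicle_exhaust")^2)
    split_rows[[reg]] <- data.frame(
      region = reg, f_fossil = sp[["fossil"]],
      f_non_fossil = sp[["non_fossil"]], f_fossil_sd = sd_fossil,
      stringsAsFactors = FALSE)

    budgets[[reg]] <- propagate_uncertainty(
      a_fossil = config$inventory$a_fossil[i],
      a_fossil_sd = config$inventory$a_fossil_sd[i],
      f_fossil = sp[["fossil"]], f_fossil_sd = sd_fossil,
      n_draws = config$n_mc_draws,
      seed = spawn_seed(seeds$mc, reg))
  }

  bundle <- structure(list(
    observations = obs, offset = offset, contributions = contributions,
    regional = do.call(rbind, regional),
    split = do.call(rbind, split_rows), budgets = budgets,
    manifest = list(master_seed = config$seed, stage_seeds = seeds,
                    fit_mode = config$fit_mode,
                    n_mc_draws = config$n_mc_draws,
                    mcmc = unclass(config$settings),
                    package_version = as.character(
                      utils::packageVersion("noxsource")))),
    class = "nox_pipeline")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# Fit the mixing model per region x site_class (pooled) or per site-year and
# summarise into a contribution table.
#' @noRd
fit_strata <- function(obs, config, offset, seed) {
  rows <- list()
  for (reg in unique(obs$region)) {
    win <- config$year_windows[[reg]]
    for (cls in unique(obs$site_class[obs$region == reg])) {
      d <- obs[obs$region == reg & obs$site_class == cls, ]
      if (!is.null(win)) d <- d[d$year %in% win, ]
      if (!nrow(d)) next
      src <- config$sources
      if (cls == "non-urban") src <- src[src$name != "vehicle_exhaust", ]
      src <- validate_sources(src)
      if (config$fit_mode == "pooled") {
        st <- config$settings
        st$seed <- spawn_seed(seed, paste(reg, cls))
        fit <- nox_mix(d$delta15N, src, offset, st)
        sm <- summary(fit)
        keep <- sm$parameter != "sigma_res"
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, site_class = cls, source = sm$parameter[keep],
          mean = sm$mean[keep], sd = sm$sd[keep], n_fits = 1L,
          stringsAsFactors = FALSE)
      } else {
        groups <- split(d, paste(d$site_id, d$year))
        means <- vapply(seq_along(groups), function(g) {
          st <- config$settings
          st$seed <- spawn_seed(seed, paste(reg, cls, names(groups)[g]))
          coef(nox_mix(groups[[g]]$delta15N, src, offset, st))
        }, numeric(nrow(src)))
        means <- matrix(means, nrow = nrow(src))  # K x n_groups
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, site_class = cls, source = src$name,
          mean = rowMeans(means),
          sd = if (ncol(means) > 1L) apply(means, 1, stats::sd) else
            rep(0, nrow(src)),
          n_fits = ncol(means), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stopf("no fittable strata after filtering")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @noRd
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$observations))
    write_observations(bundle$observations,
                       file.path(outdir, "observations.tsv"))
  utils::write.table(bundle$contributions,
                     file.path(outdir, "contributions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$regional, file.path(outdir, "regional.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  btab <- do.call(rbind, lapply(names(bundle$budgets), function(reg) {
    b <- bundle$budgets[[reg]]
    data.frame(region = reg,
               a_fossil = b$mean[["a_fossil"]],
               a_fossil_sd = b$sd[["a_fossil"]],
               a_total = b$mean[["a_total"]],
               a_total_sd = b$sd[["a_total"]],
               a_non_fossil = b$mean[["a_non_fossil"]],
               a_non_fossil_sd = b$sd[["a_non_fossil"]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cbind(btab, bundle$split[btab$region,
                                              c("f_fossil", "f_fossil_sd")]),
                     file.path(outdir, "budgets.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  man <- bundle$manifest
  writeLines(c(
    sprintf("master_seed\t%d", man$master_seed),
    sprintf("stage_seed_%s\t%d", names(man$stage_seeds),
            unlist(man$stage_seeds)),
    sprintf("fit_mode\t%s", man$fit_mode),
    sprintf("n_mc_draws\t%d", man$n_mc_draws),
    sprintf("offset\t%.6f +/- %.6f (%s)", bundle$offset$mean,
            bundle$offset$sd, bundle$offset$scenario),
    sprintf("package_version\t%s", man$package_version)),
    file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' @export
print.nox_pipeline <- function(x, ...) {
  cat("NOx source-apportionment pipeline result\n")
  print(x$offset)
  cat("Fossil / non-fossil split by region:\n")
  print.data.frame(x$split, row.names = FALSE)
  cat("Budgets (central total / non-fossil):\n")
  for (reg in names(x$budgets))
    cat(sprintf("  %-14s %8.2f / %.2f\n", reg,
                x$budgets[[reg]]$central$a_total,
                x$budgets[[reg]]$central$a_non_fossil))
  invisible(x)
}
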
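#' Source signature table for NOx end-members
#'
#' Builds the table of nitrogen-isotope signatures (mean and SD of
#' \eqn{\delta^{15}}N, in permil) for the candidate NOx emission sources used
#' by the mixing model. The four canonical sources are coal combustion (S1)
#' and vehicle exhausts (S2) — the fossil pair — and biomass burning (S3) and
#' microbial N cycling in soils and wastes (S4) — the non-fossil pair.
#'
#' Defaults are provided only for coal combustion (13.7 +/- 3.9 permil) and
#' the microbial N cycle (-30.2 +/- 6.7 permil), the two end-members with
#' well-established compiled signatures. Vehicle-exhaust and biomass-burning
#' signatures vary strongly across compilations (engine fleet, fuel type,
#' burning conditions), so they must be supplied explicitly by the user from
#' whichever compilation fits the study region.
#'
#' @param coal,vehicle,biomass,microbial length-2 numeric vectors
#'   `c(mean, sd)` in permil. `vehicle` and `biomass` have no defaults;
#'   pass `NULL` to omit a source (e.g. drop `vehicle` for non-urban fits).
#' @return A data.frame of class `"nox_sources"` with columns `name`,
#'   `mean`, `sd` (one row per retained source, in S1..S4 order).
#' @examples
#' src <- nox_sources(vehicle = c(-4, 4), biomass = c(1, 4))
#' src
#' # three-source (non-urban) set:
#' nox_sources(vehicle = NULL, biomass = c(1, 4))
#' @export
nox_sources <- function(coal = c(13.7, 3.9), vehicle, biomass,
                        microbial = c(-30.2, 6.7)) {
  if (missing(vehicle))
    stopf("'vehicle' signature must be supplied (no default); use NULL to omit the source")
  if (missing(biomass))
    stopf("'biomass' signature must be supplied (no default); use NULL to omit the source")
  sigs <- list(coal_combustion = coal, vehicle_exhaust = vehicle,
               biomass_burning = biomass, microbial_N = microbial)
  sigs <- sigs[!vapply(sigs, is.null, logical(1))]
  for (nm in names(sigs)) {
    s <- sigs[[nm]]
    if (!is.numeric(s) || length(s) != 2L || any(!is.finite(s)))
      stopf("signature '%s' must be a finite numeric c(mean, sd)", nm)
    if (s[2] < 0) stopf("signature '%s' has negative sd", nm)
  }
  out <- data.frame(name = names(sigs),
                    mean = vapply(sigs, `[`, numeric(1), 1L),
                    sd = vapply(sigs, `[`, numeric(1), 2L),
                    row.names = NULL, stringsAsFactors = FALSE)
  validate_sources(out)
}

# Accepts a nox_sources object or a plain data.frame with name/mean/sd.
#' @noRd
validate_sources <- function(sources) {
  if (!is.data.frame(sources) ||
      !all(c("name", "mean", "sd") %in% names(sources)))
    stopf("'sources' must be a data.frame with columns name, mean, sd")
  if (nrow(sources) < 2L) stopf("need at least two sources")
  if (anyDuplicated(sources$name)) stopf("source names must be unique")
  if (any(!is.finite(sources$mean)) || any(!is.finite(sources$sd)))
    stopf("source means and sds must be finite")
  if (any(sources$sd < 0)) stopf("source sds must be >= 0")
  class(sources) <- unique(c("nox_sources", class(sources)))
  sources
}

#' @export
print.nox_sources <- function(x, ...) {
  cat("NOx source signatures (d15N, permil):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
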
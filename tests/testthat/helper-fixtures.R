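# Shared fixtures. Vehicle-exhaust and biomass-burning signatures are
# synthetic stand-ins (plausible literature-range values); coal and
# microbial are the compiled anchors.

test_sources4 <- function() {
  nox_sources(coal = c(13.7, 3.9), vehicle = c(-4, 4),
              biomass = c(1, 4), microbial = c(-30.2, 6.7))
}

test_sources3 <- function() {
  nox_sources(coal = c(13.7, 3.9), vehicle = NULL,
              biomass = c(1, 4), microbial = c(-30.2, 6.7))
}

# Two well-separated narrow sources for oracle checks.
test_sources2 <- function(sd = 1) {
  validate_df <- data.frame(name = c("neg", "pos"), mean = c(-10, 10),
                            sd = c(sd, sd), stringsAsFactors = FALSE)
  validate_df
}

quick_settings <- function(seed = 1L, n_chains = 2L, n_iter = 2000L) {
  mcmc_settings(n_iter = n_iter, burn_in = n_iter %/% 2L, thin = 2L,
                n_chains = n_chains, seed = seed)
}

ambient_one <- function(c_no2 = 1, c_hno3 = 1, c_pno3 = 1, f_no2 = 0.5,
                        d15n_nox = -8, d15n_hno3 = 0, d15n_pno3 = 4) {
  data.frame(c_no2 = c_no2, c_hno3 = c_hno3, c_pno3 = c_pno3,
             f_no2 = f_no2, d15n_nox = d15n_nox, d15n_hno3 = d15n_hno3,
             d15n_pno3 = d15n_pno3)
}
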
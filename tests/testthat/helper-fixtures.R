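# Small in-code fixtures shared across test files.

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A tiny fully deterministic dataset: 2 larvae, 2 metamorphs, 2 adults
# (one recaptured once).
tiny_dataset <- function() {
  larvae <- data.frame(
    wetland_id = c("W01", "W01"),
    capture_date = as.Date(c("2015-01-15", "2015-03-01")),
    pond_fill_date = as.Date(c("2014-11-01", "2014-11-01")),
    svl_mm = c(12.0, 22.5),
    stringsAsFactors = FALSE
  )
  larvae$age_years <- as.numeric(larvae$capture_date -
                                   larvae$pond_fill_date) / 365.25
  metamorphs <- data.frame(
    wetland_id = c("W01", "W01"), cohort_year = c(2015L, 2015L),
    svl_mm = c(38.0, 41.5), stringsAsFactors = FALSE
  )
  adults <- list(
    A1 = capture_history("A1", as.Date("2015-11-01"), c(0, 1.0),
                         c(52.0, 55.0)),
    A2 = capture_history("A2", as.Date("2015-11-05"), 0, 58.5)
  )
  growth_dataset(larvae, metamorphs, adults)
}

# A state matched to tiny_dataset (2 metamorphs, 2 adults), strictly
# inside all supports.
tiny_state <- function() {
  model_state(
    params = list(mu_Linf = 59, sigma2_Linf = 5, k_larval = 1.77,
                  k_adult = 0.91, t0 = 0, alpha = 4.5, sigma2_t = 0.25,
                  sigma2_L = 4),
    latents = list(tm_metamorph = c(0.4, 0.5),
                   tm_adult = c(0.45, 0.55),
                   age_first_capture = c(3.0, 6.0),
                   Linf_individual = c(57.0, 61.0))
  )
}

# Build a posterior_samples object from a list of per-chain matrices of
# population-parameter draws (no latents).
fake_samples <- function(chains) {
  structure(list(
    draws = chains,
    param_names = colnames(chains[[1]]),
    n_pop = ncol(chains[[1]]),
    config = NULL,
    priors = default_priors(),
    provenance = list()
  ), class = "posterior_samples")
}

pop_names <- c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0",
               "alpha", "sigma2_t", "sigma2_L")

# Replicate one population-parameter vector into a single-chain
# posterior_samples object.
constant_samples <- function(values, n = 50) {
  m <- matrix(rep(values, each = n), nrow = n,
              dimnames = list(NULL, pop_names))
  fake_samples(list(m))
}
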
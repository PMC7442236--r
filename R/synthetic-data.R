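#' @title Synthetic data with the model's exact generative structure
#' @description
#' The generator emulates the three field sampling designs the model was
#' built for: cross-sectional dipnet sampling of known-age larvae (age 0 at
#' pond filling), drift-fence captures of emigrating metamorphs whose age
#' at metamorphosis is latent, and annual mark-recapture histories of
#' unknown-age terrestrial adults. Because it draws from precisely the
#' hierarchical model the sampler fits, it supports parameter-recovery and
#' calibration tests; it deliberately does not emulate hydroperiod-driven
#' plasticity in metamorph size, detection heterogeneity, or mortality.
#' @name synthetic_data
NULL

#' Generating parameter values for simulations
#'
#' Defaults are the point estimates of the motivating flatwoods-salamander
#' analysis where available (asymptotic length 59.0 mm with
#' between-individual variance 5.0 mm^2, larval growth rate 1.77/yr, adult
#' growth rate 0.91/yr, median adult age 4.5 yr); the log-age variance
#' (0.25) and observation variance (4.0 mm^2) are generator defaults chosen
#' to give realistic scatter.
#'
#' @param mu_Linf,sigma2_Linf,k_larval,k_adult,t0,alpha,sigma2_t,sigma2_L
#'   Population parameter values (see [model_spec]).
#' @return Named list of the eight population parameters.
#' @export
synthetic_truth <- function(mu_Linf = 59.0, sigma2_Linf = 5.0,
                            k_larval = 1.77, k_adult = 0.91, t0 = 0.0,
                            alpha = 4.5, sigma2_t = 0.25, sigma2_L = 4.0) {
  list(mu_Linf = mu_Linf, sigma2_Linf = sigma2_Linf, k_larval = k_larval,
       k_adult = k_adult, t0 = t0, alpha = alpha, sigma2_t = sigma2_t,
       sigma2_L = sigma2_L)
}

#' Simulation configuration
#'
#' Default stream sizes match the motivating study (411 larvae, 766
#' metamorphs, 927 adults). Adults are re-encountered at integer-year
#' offsets (annual breeding migrations) with a fixed per-year recapture
#' probability over a nine-year study window.
#'
#' @param n_larvae,n_metamorphs,n_adults Stream sizes.
#' @param larval_age_window Length-2 range (years) from which larval
#'   capture ages are drawn uniformly.
#' @param recapture_prob Probability an adult is recaptured in any given
#'   later year.
#' @param max_study_years Number of years after first capture during which
#'   recaptures can occur.
#' @param truth Named list from [synthetic_truth()].
#' @param priors A `prior_spec`; supplies the latent supports
#'   (`tm_bounds`, `t_max`).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_larvae = 411, n_metamorphs = 766, n_adults = 927,
                       larval_age_window = c(0.05, 0.6),
                       recapture_prob = 0.4, max_study_years = 9,
                       truth = synthetic_truth(),
                       priors = default_priors(), seed = NULL) {
  stopifnot(n_larvae >= 0, n_metamorphs >= 0, n_adults >= 0,
            recapture_prob >= 0, recapture_prob <= 1,
            length(larval_age_window) == 2,
            larval_age_window[1] < larval_age_window[2])
  structure(list(n_larvae = n_larvae, n_metamorphs = n_metamorphs,
                 n_adults = n_adults,
                 larval_age_window = larval_age_window,
                 recapture_prob = recapture_prob,
                 max_study_years = max_study_years,
                 truth = truth, priors = priors, seed = seed),
            class = "sim_config")
}

## Draw observation noise around a vector of curve means, resampling any
## draw that lands at or below zero (lengths are physical quantities).
.noisy_length <- function(mu, sigma2_L) {
  if (sigma2_L == 0) return(mu)
  out <- stats::rnorm(length(mu), mu, sqrt(sigma2_L))
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mu[bad], sqrt(sigma2_L))
    bad <- bad[out[bad] <= 0]
  }
  ## quantised to 0.01 mm so CSV round trips are exact
  round(out, 2)
}

.maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Simulate known-age larval records
#'
#' Ages are uniform over the configured window (quantised to whole days so
#' calendar dates are exact); lengths are the larval curve plus Gaussian
#' noise, resampled if non-positive.
#'
#' @param config A `sim_config`.
#' @param seed Optional seed override (`NULL` = current RNG state).
#' @return Data frame of larval records (see [read_larval_csv()]).
#' @export
simulate_larvae <- function(config, seed = config$seed) {
  .maybe_seed(seed)
  n <- config$n_larvae
  tr <- config$truth
  if (n == 0) return(empty_larvae())
  win_days <- round(config$larval_age_window * DAYS_PER_YEAR)
  age_days <- sample(seq(win_days[1], win_days[2]), n, replace = TRUE)
  age <- age_days / DAYS_PER_YEAR
  mu <- larval_length(age, tr$mu_Linf, tr$k_larval, tr$t0)
  fill <- as.Date("2014-11-01")
  data.frame(
    wetland_id = "W01",
    capture_date = fill + age_days,
    pond_fill_date = fill,
    svl_mm = .noisy_length(mu, tr$sigma2_L),
    age_years = age,
    stringsAsFactors = FALSE
  )
}

#' Simulate metamorph records
#'
#' Each record has a latent age at metamorphosis drawn uniformly over the
#' prior support; length is the larval curve at that age plus noise.
#'
#' @inheritParams simulate_larvae
#' @return List with `records` (data frame) and `tm` (true latent ages).
#' @export
simulate_metamorphs <- function(config, seed = config$seed) {
  .maybe_seed(seed)
  n <- config$n_metamorphs
  tr <- config$truth
  tmb <- config$priors$tm_bounds
  if (n == 0) return(list(records = empty_metamorphs(), tm = numeric()))
  tm <- stats::runif(n, tmb[1], tmb[2])
  mu <- length_at_metamorphosis(tm, tr$mu_Linf, tr$k_larval, tr$t0)
  list(
    records = data.frame(wetland_id = "W01", cohort_year = 2015L,
                         svl_mm = .noisy_length(mu, tr$sigma2_L),
                         stringsAsFactors = FALSE),
    tm = tm
  )
}

## Inverse-CDF draw from logN(log(alpha), sigma2_t) truncated to
## (lower, upper); vectorised over lower.
.rtrunc_lnorm <- function(n, alpha, sigma2_t, lower, upper) {
  sdlog <- sqrt(sigma2_t); meanlog <- log(alpha)
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

## Normal(mu, sd) truncated below at `lower`, by inverse CDF.
.rtrunc_norm_lower <- function(n, mu, sd, lower) {
  plo <- stats::pnorm(lower, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mu, sd)
}

#' Simulate adult capture histories
#'
#' Per individual: a latent age at metamorphosis (uniform), an individual
#' asymptote (normal truncated below at the individual's metamorphic
#' length), and a latent age at first capture (truncated lognormal). The
#' first occasion is at offset zero; each subsequent integer-year offset up
#' to `max_study_years` is included independently with probability
#' `recapture_prob`. Occasion lengths are the adult curve plus noise.
#'
#' @inheritParams simulate_larvae
#' @return List with `histories` (list of `capture_history`) and `latents`
#'   (list with `tm`, `age_first_capture`, `Linf_individual`).
#' @export
simulate_adults <- function(config, seed = config$seed) {
  .maybe_seed(seed)
  n <- config$n_adults
  tr <- config$truth
  tmb <- config$priors$tm_bounds
  if (n == 0) {
    return(list(histories = list(),
                latents = list(tm = numeric(),
                               age_first_capture = numeric(),
                               Linf_individual = numeric())))
  }
  tm <- stats::runif(n, tmb[1], tmb[2])
  ltm <- length_at_metamorphosis(tm, tr$mu_Linf, tr$k_larval, tr$t0)
  Linf_i <- if (tr$sigma2_Linf == 0) rep(tr$mu_Linf, n) else
    .rtrunc_norm_lower(n, tr$mu_Linf, sqrt(tr$sigma2_Linf), ltm)
  t_first <- .rtrunc_lnorm(n, tr$alpha, tr$sigma2_t,
                           lower = tm, upper = config$priors$t_max)
  first_date <- as.Date("2014-11-01") + sample.int(120, n, replace = TRUE)
  histories <- vector("list", n)
  for (i in seq_len(n)) {
    later <- which(stats::runif(config$max_study_years) <
                     config$recapture_prob)
    ## annual migrations land on calendar days: quantise year offsets to
    ## whole days so dates and offsets round-trip exactly through CSV
    offsets <- round(c(0, later) * DAYS_PER_YEAR) / DAYS_PER_YEAR
    mu <- adult_length_at_recapture(t_first[i], offsets, tm[i], ltm[i],
                                    Linf_i[i], tr$k_adult, tr$t0)
    histories[[i]] <- capture_history(
      sprintf("A%04d", i), first_date[i], offsets,
      .noisy_length(mu, tr$sigma2_L))
  }
  names(histories) <- vapply(histories, `[[`, character(1), "individual_id")
  list(histories = histories,
       latents = list(tm = tm, age_first_capture = t_first,
                      Linf_individual = Linf_i))
}

#' Simulate a complete dataset
#'
#' Runs the three stream simulators from deterministic substreams of the
#' configured seed and bundles the results.
#'
#' @param config A `sim_config`.
#' @return List with `dataset` (a `growth_dataset`) and `latents` (the true
#'   latent variables, for recovery tests).
#' @export
simulate_dataset <- function(config = sim_config()) {
  seed <- config$seed
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list((seed + c(101L, 202L, 303L)) %% .Machine$integer.max)
  larv <- simulate_larvae(config, seed = seeds[[1]])
  meta <- simulate_metamorphs(config, seed = seeds[[2]])
  adult <- simulate_adults(config, seed = seeds[[3]])
  list(
    dataset = growth_dataset(larv, meta$records, adult$histories),
    latents = list(tm_metamorph = meta$tm,
                   tm_adult = adult$latents$tm,
                   age_first_capture = adult$latents$age_first_capture,
                   Linf_individual = adult$latents$Linf_individual)
  )
}

#' Write a simulated dataset plus its generating truth
#'
#' Emits the three CSVs in the package's data dialect and a `truth.json`
#' sidecar holding every generating population parameter.
#'
#' @param sim Result of [simulate_dataset()].
#' @param truth The generating parameters (defaults to
#'   [synthetic_truth()]).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(sim, truth, dir) {
  paths <- write_dataset_csv(sim$dataset, dir)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth = truth_path))
}
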
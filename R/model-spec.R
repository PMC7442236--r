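#' @title Joint probability model
#' @description
#' The joint model has eight population-level parameters and four blocks of
#' latent variables.
#'
#' Population parameters (all shared across the dataset):
#' \describe{
#'   \item{mu_Linf}{population mean asymptotic length (mm); prior U(30, 100)}
#'   \item{sigma2_Linf}{between-individual variance of asymptotic length
#'     (mm^2); prior Gamma(0.1, 0.1)}
#'   \item{k_larval}{larval growth rate (per year); prior Gamma(0.1, 0.1)}
#'   \item{k_adult}{adult growth rate (per year); prior Gamma(0.1, 0.1)}
#'   \item{t0}{theoretical age at length zero (years); prior U(-2, 2)}
#'   \item{alpha}{median adult age at first capture (years); prior U(0.5, 20)}
#'   \item{sigma2_t}{variance of log age at first capture; prior
#'     Gamma(0.1, 0.1)}
#'   \item{sigma2_L}{observation variance (mm^2), shared across all three
#'     life stages; prior Gamma(0.1, 0.1)}
#' }
#' Gamma priors use the shape--rate convention.
#'
#' Latent variables:
#' \describe{
#'   \item{tm_metamorph}{age at metamorphosis of each metamorph record;
#'     U(0.2, 0.7) years}
#'   \item{tm_adult}{age at metamorphosis of each adult; U(0.2, 0.7) years}
#'   \item{age_first_capture}{age of each adult at first capture; lognormal
#'     with log-median log(alpha) and log-variance sigma2_t, truncated to
#'     (tm_adult[i], t_max]}
#'   \item{Linf_individual}{per-adult asymptotic length; Normal(mu_Linf,
#'     sigma2_Linf) truncated below at the individual's length at
#'     metamorphosis. Individual heterogeneity enters the adult stage only;
#'     larvae and metamorphs use the population mean asymptote.}
#' }
#'
#' Observed lengths in every stream are Normal(model mean, sigma2_L).
#' @name model_spec
NULL

#' Default prior specification
#'
#' Vague priors for all eight population parameters, the uniform support of
#' the latent age at metamorphosis, and the upper truncation bound of the
#' latent adult age distribution.
#'
#' @param tm_bounds Length-2 support of the age at metamorphosis (years).
#' @param t_max Upper truncation bound (years) for the latent adult age at
#'   first capture; defaults to the upper bound of the `alpha` prior.
#' @return An object of class `prior_spec`: a named list of per-parameter
#'   distribution descriptions.
#' @export
default_priors <- function(tm_bounds = c(0.2, 0.7), t_max = 20) {
  stopifnot(length(tm_bounds) == 2, tm_bounds[1] < tm_bounds[2],
            t_max > 0)
  structure(list(
    mu_Linf     = list(dist = "uniform", min = 30, max = 100),
    sigma2_Linf = list(dist = "gamma", shape = 0.1, rate = 0.1),
    k_larval    = list(dist = "gamma", shape = 0.1, rate = 0.1),
    k_adult     = list(dist = "gamma", shape = 0.1, rate = 0.1),
    t0          = list(dist = "uniform", min = -2, max = 2),
    alpha       = list(dist = "uniform", min = 0.5, max = 20),
    sigma2_t    = list(dist = "gamma", shape = 0.1, rate = 0.1),
    sigma2_L    = list(dist = "gamma", shape = 0.1, rate = 0.1),
    tm_bounds   = as.numeric(tm_bounds),
    t_max       = as.numeric(t_max)
  ), class = "prior_spec")
}

#' Log prior density of one population parameter
#'
#' @param x Parameter value (vectorised).
#' @param spec One element of a `prior_spec` (a uniform or gamma
#'   description).
#' @return Log density; `-Inf` outside the support.
#' @export
param_log_prior <- function(x, spec) {
  switch(spec$dist,
    uniform = stats::dunif(x, spec$min, spec$max, log = TRUE),
    gamma = ifelse(x > 0,
                   stats::dgamma(x, shape = spec$shape, rate = spec$rate,
                                 log = TRUE),
                   -Inf),
    stop("unknown prior family: ", spec$dist, call. = FALSE)
  )
}

#' Truncated lognormal log density of a latent adult age
#'
#' Density of `logN(log(alpha), sigma2_t)` renormalised to
#' `[lower, upper]`; `-Inf` outside. Vectorised over `t` and `lower`.
#'
#' @param t Age(s) in years.
#' @param alpha Median of the untruncated lognormal (years).
#' @param sigma2_t Variance of log age.
#' @param lower,upper Truncation bounds (years), `0 < lower < upper`.
#' @return Log density values.
#' @export
latent_age_log_density <- function(t, alpha, sigma2_t, lower, upper) {
  stopifnot(alpha > 0, sigma2_t > 0)
  if (any(lower <= 0) || any(lower >= upper)) {
    stop("invalid truncation bounds: need 0 < lower < upper", call. = FALSE)
  }
  sdlog <- sqrt(sigma2_t)
  meanlog <- log(alpha)
  norm <- stats::plnorm(upper, meanlog, sdlog) -
    stats::plnorm(lower, meanlog, sdlog)
  out <- stats::dlnorm(t, meanlog, sdlog, log = TRUE) - log(norm)
  out[t < lower | t > upper] <- -Inf
  out
}

#' Construct a model state
#'
#' @param params Named list with the eight population parameters.
#' @param latents Named list with numeric vectors `tm_metamorph`,
#'   `tm_adult`, `age_first_capture`, `Linf_individual`; adult vectors must
#'   have equal length.
#' @return An object of class `model_state`.
#' @export
model_state <- function(params, latents = list(tm_metamorph = numeric(),
                                               tm_adult = numeric(),
                                               age_first_capture = numeric(),
                                               Linf_individual = numeric())) {
  required <- c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0",
                "alpha", "sigma2_t", "sigma2_L")
  stopifnot(all(required %in% names(params)))
  n_ad <- length(latents$tm_adult)
  stopifnot(length(latents$age_first_capture) == n_ad,
            length(latents$Linf_individual) == n_ad)
  structure(list(params = params[required], latents = latents),
            class = "model_state")
}

## bare VBGE, no argument checking: hot-path use only
.vb <- function(t, Linf, k, t0) Linf * (1 - exp(-k * (t - t0)))

## Flattened numeric views of a dataset, precomputed once per fit so the
## likelihood is pure vector arithmetic.
model_data <- function(ds) {
  stopifnot(inherits(ds, "growth_dataset"))
  occ_ind <- integer(0); occ_dt <- numeric(0); occ_svl <- numeric(0)
  if (length(ds$adults) > 0) {
    n_occ <- vapply(ds$adults, function(h) length(h$svl_mm), integer(1))
    occ_ind <- rep(seq_along(ds$adults), n_occ)
    occ_dt <- unlist(lapply(ds$adults, `[[`, "time_offset_years"),
                     use.names = FALSE)
    occ_svl <- unlist(lapply(ds$adults, `[[`, "svl_mm"), use.names = FALSE)
  }
  list(
    larv_age = ds$larvae$age_years,
    larv_svl = ds$larvae$svl_mm,
    meta_svl = ds$metamorphs$svl_mm,
    n_meta = nrow(ds$metamorphs),
    n_adult = length(ds$adults),
    occ_ind = occ_ind,
    occ_dt = occ_dt,
    occ_svl = occ_svl
  )
}

.in_support <- function(p, priors) {
  p$mu_Linf > priors$mu_Linf$min && p$mu_Linf < priors$mu_Linf$max &&
    p$t0 > priors$t0$min && p$t0 < priors$t0$max &&
    p$alpha > priors$alpha$min && p$alpha < priors$alpha$max &&
    p$sigma2_Linf > 0 && p$k_larval > 0 && p$k_adult > 0 &&
    p$sigma2_t > 0 && p$sigma2_L > 0
}

#' Log prior density of a full model state
#'
#' Sums the population-parameter priors and the hierarchical priors of all
#' latent variables (ages at metamorphosis, truncated-lognormal ages at
#' first capture, truncated-normal individual asymptotes). Returns `-Inf`
#' whenever any support constraint is violated.
#'
#' @param state A `model_state`.
#' @param priors A `prior_spec`.
#' @return Scalar log density.
#' @export
log_prior <- function(state, priors = default_priors()) {
  p <- state$params
  if (!.in_support(p, priors)) return(-Inf)
  lp <- sum(vapply(
    c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0", "alpha",
      "sigma2_t", "sigma2_L"),
    function(nm) param_log_prior(p[[nm]], priors[[nm]]), numeric(1)))
  lat <- state$latents
  tmb <- priors$tm_bounds
  tm_all <- c(lat$tm_metamorph, lat$tm_adult)
  if (length(tm_all) > 0) {
    if (any(tm_all < tmb[1] | tm_all > tmb[2])) return(-Inf)
    lp <- lp + length(tm_all) * stats::dunif(tmb[1], tmb[1], tmb[2],
                                             log = TRUE)
  }
  n_ad <- length(lat$tm_adult)
  if (n_ad > 0) {
    t_ <- lat$age_first_capture
    if (any(t_ <= lat$tm_adult) || any(t_ > priors$t_max)) return(-Inf)
    lp <- lp + sum(latent_age_log_density(t_, p$alpha, p$sigma2_t,
                                          lower = lat$tm_adult,
                                          upper = priors$t_max))
    ltm <- .vb(lat$tm_adult, p$mu_Linf, p$k_larval, p$t0)
    li <- lat$Linf_individual
    if (any(li <= ltm)) return(-Inf)
    sd_li <- sqrt(p$sigma2_Linf)
    lp <- lp + sum(stats::dnorm(li, p$mu_Linf, sd_li, log = TRUE) -
                     stats::pnorm(ltm, p$mu_Linf, sd_li,
                                  lower.tail = FALSE, log.p = TRUE))
  }
  lp
}

#' Stage-wise log likelihoods
#'
#' Each observed SVL is Normal with the stage's model mean and shared
#' variance `sigma2_L`. Larval means come from the VBGE at the known age;
#' metamorph means from the larval curve at that record's latent age at
#' metamorphosis; adult means from the adult curve at the individual's
#' latent age at first capture plus the occasion offset, anchored at the
#' individual's latent length at metamorphosis and asymptote.
#'
#' @param larvae Data frame of larval records.
#' @param metamorphs Data frame of metamorph records.
#' @param adults List of `capture_history` objects.
#' @param state A `model_state`.
#' @return Scalar log likelihood.
#' @name stage_likelihoods
NULL

#' @rdname stage_likelihoods
#' @export
log_lik_larvae <- function(larvae, state) {
  if (nrow(larvae) == 0) return(0)
  p <- state$params
  mu <- larval_length(larvae$age_years, p$mu_Linf, p$k_larval, p$t0)
  sum(stats::dnorm(larvae$svl_mm, mu, sqrt(p$sigma2_L), log = TRUE))
}

#' @rdname stage_likelihoods
#' @export
log_lik_metamorphs <- function(metamorphs, state) {
  n <- nrow(metamorphs)
  if (n == 0) return(0)
  if (length(state$latents$tm_metamorph) != n) {
    stop("need one tm_metamorph latent per metamorph record", call. = FALSE)
  }
  p <- state$params
  mu <- length_at_metamorphosis(state$latents$tm_metamorph, p$mu_Linf,
                                p$k_larval, p$t0)
  sum(stats::dnorm(metamorphs$svl_mm, mu, sqrt(p$sigma2_L), log = TRUE))
}

#' @rdname stage_likelihoods
#' @export
log_lik_adults <- function(adults, state) {
  if (length(adults) == 0) return(0)
  if (length(state$latents$tm_adult) != length(adults)) {
    stop("need one latent triple per adult history", call. = FALSE)
  }
  md <- list(
    occ_ind = rep(seq_along(adults),
                  vapply(adults, function(h) length(h$svl_mm), integer(1))),
    occ_dt = unlist(lapply(adults, `[[`, "time_offset_years"),
                    use.names = FALSE),
    occ_svl = unlist(lapply(adults, `[[`, "svl_mm"), use.names = FALSE)
  )
  .log_lik_adults_md(md, state)
}

.adult_occasion_means <- function(md, params, latents) {
  ltm <- .vb(latents$tm_adult, params$mu_Linf, params$k_larval,
             params$t0)
  i <- md$occ_ind
  latents$Linf_individual[i] -
    (latents$Linf_individual[i] - ltm[i]) *
    exp(-params$k_adult * (latents$age_first_capture[i] + md$occ_dt -
                             (latents$tm_adult[i] + params$t0)))
}

.log_lik_adults_md <- function(md, state) {
  if (length(md$occ_svl) == 0) return(0)
  mu <- .adult_occasion_means(md, state$params, state$latents)
  sum(stats::dnorm(md$occ_svl, mu, sqrt(state$params$sigma2_L), log = TRUE))
}

#' Unnormalised log posterior
#'
#' `log_prior + log_lik_larvae + log_lik_metamorphs + log_lik_adults`;
#' `-Inf` from any component propagates.
#'
#' @param state A `model_state`.
#' @param ds A `growth_dataset`.
#' @param priors A `prior_spec`.
#' @return Scalar log density.
#' @export
log_posterior <- function(state, ds, priors = default_priors()) {
  lp <- log_prior(state, priors)
  if (!is.finite(lp)) return(-Inf)
  lp + log_lik_larvae(ds$larvae, state) +
    log_lik_metamorphs(ds$metamorphs, state) +
    log_lik_adults(ds$adults, state)
}
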
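#' @title Adaptive Metropolis-within-Gibbs sampler
#' @description
#' The posterior is sampled with componentwise random-walk Metropolis
#' updates. Each sweep updates the eight population parameters one at a
#' time (full-posterior acceptance ratio) and then the four latent blocks
#' element-wise in vectorised form: metamorph ages, adult ages at
#' metamorphosis, adult ages at first capture, and individual asymptotes.
#' Individuals are conditionally independent given the population
#' parameters, so each latent element's acceptance ratio only involves that
#' individual's likelihood and hierarchical-prior terms (including the
#' truncation normalisers that depend on its age at metamorphosis).
#'
#' Proposals are Gaussian on transformed scales — log for positive
#' parameters, logit for interval-bounded ones, identity for the individual
#' asymptotes — with the Jacobian correction included in the acceptance
#' ratio, so proposals never leave the support. Per-component proposal
#' scales adapt during burn-in only (Robbins-Monro toward a target
#' acceptance rate, 0.44 by default) and are frozen afterwards, preserving
#' ergodicity of the post-burn-in kernel.
#' @name mcmc_engine
NULL

#' Fit configuration
#'
#' Defaults follow the full estimation protocol of the motivating analysis:
#' three chains of 500,000 iterations, 100,000 discarded as burn-in, and
#' every 100th retained draw kept.
#'
#' @param n_chains Number of independent chains (>= 2 for diagnostics).
#' @param n_iter Iterations (sweeps) per chain.
#' @param n_burnin Burn-in sweeps discarded per chain; adaptation happens
#'   only here.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Master integer seed; per-chain substream seeds are derived
#'   deterministically from it.
#' @param adapt Adapt proposal scales during burn-in?
#' @param target_accept Target acceptance rate per scalar component.
#' @param proposal_scales Optional named list of initial proposal standard
#'   deviations on the transformed scales (`params` for the population
#'   block; `latent` for latent elements).
#' @param keep_latents Retain latent draws in the output (needed for
#'   posterior predictive checks on the adult stage)?
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_chains = 3, n_iter = 500000, n_burnin = 100000,
                       thin = 100, seed = 1, adapt = TRUE,
                       target_accept = 0.44, proposal_scales = NULL,
                       keep_latents = TRUE) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, thin = thin, seed = as.integer(seed),
                 adapt = adapt, target_accept = target_accept,
                 proposal_scales = proposal_scales,
                 keep_latents = keep_latents),
            class = "fit_config")
}

#' Preset fit configurations
#'
#' `full` is the complete estimation protocol (3 x 500,000, burn-in
#' 100,000, thin 100); `reduced` (3 x 20,000, burn-in 5,000, thin 10) is
#' sized for desk-scale parameter-recovery runs; `smoke` is a seconds-long
#' sanity setting.
#'
#' @param preset One of `"full"`, `"reduced"`, `"smoke"`.
#' @param ... Overrides passed on to [fit_config()].
#' @export
preset_config <- function(preset = c("reduced", "full", "smoke"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    full = list(n_chains = 3, n_iter = 500000, n_burnin = 100000,
                thin = 100),
    reduced = list(n_chains = 3, n_iter = 20000, n_burnin = 5000,
                   thin = 10),
    smoke = list(n_chains = 2, n_iter = 600, n_burnin = 300, thin = 3))
  do.call(fit_config, utils::modifyList(base, list(...)))
}

.POP_PARAMS <- c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0",
                 "alpha", "sigma2_t", "sigma2_L")

## transform descriptors for the population parameters
.param_transforms <- function(priors) {
  list(
    mu_Linf = list(type = "logit", lo = priors$mu_Linf$min,
                   hi = priors$mu_Linf$max),
    sigma2_Linf = list(type = "log"),
    k_larval = list(type = "log"),
    k_adult = list(type = "log"),
    t0 = list(type = "logit", lo = priors$t0$min, hi = priors$t0$max),
    alpha = list(type = "logit", lo = priors$alpha$min,
                 hi = priors$alpha$max),
    sigma2_t = list(type = "log"),
    sigma2_L = list(type = "log")
  )
}

.fwd <- function(x, tr) {
  switch(tr$type,
    log = log(x),
    logit = stats::qlogis((x - tr$lo) / (tr$hi - tr$lo)),
    identity = x)
}

.bwd <- function(z, tr) {
  switch(tr$type,
    log = exp(z),
    logit = tr$lo + (tr$hi - tr$lo) * stats::plogis(z),
    identity = z)
}

## log |dx/dz|, up to additive constants
.log_jac <- function(x, tr) {
  switch(tr$type,
    log = log(x),
    logit = log(x - tr$lo) + log(tr$hi - x),
    identity = 0)
}

#' Draw an overdispersed initial state
#'
#' Population parameters are drawn uniformly over (for bounded priors)
#' their support or (for gamma priors) a moderate positive range; latent
#' ages at metamorphosis are uniform over their support, ages at first
#' capture come from the truncated lognormal at the drawn
#' (`alpha`, `sigma2_t`), and individual asymptotes from the truncated
#' normal. Redraws until the log posterior is finite.
#'
#' @param priors A `prior_spec`.
#' @param ds A `growth_dataset`.
#' @param max_tries Redraw budget before failing.
#' @return A `model_state` with finite log posterior.
#' @export
initialize_state <- function(priors, ds, max_tries = 100) {
  n_meta <- nrow(ds$metamorphs)
  n_ad <- length(ds$adults)
  tmb <- priors$tm_bounds
  for (try in seq_len(max_tries)) {
    params <- list(
      mu_Linf = stats::runif(1, 40, 90),
      sigma2_Linf = stats::runif(1, 1, 10),
      k_larval = stats::runif(1, 0.3, 4),
      k_adult = stats::runif(1, 0.3, 3),
      t0 = stats::runif(1, -0.5, 0.5),
      alpha = stats::runif(1, 1, 10),
      sigma2_t = stats::runif(1, 0.1, 1),
      sigma2_L = stats::runif(1, 1, 10)
    )
    tm_adult <- stats::runif(n_ad, tmb[1], tmb[2])
    ltm <- length_at_metamorphosis(tm_adult, params$mu_Linf,
                                   params$k_larval, params$t0)
    latents <- list(
      tm_metamorph = stats::runif(n_meta, tmb[1], tmb[2]),
      tm_adult = tm_adult,
      age_first_capture = .rtrunc_lnorm(n_ad, params$alpha,
                                        params$sigma2_t, lower = tm_adult,
                                        upper = priors$t_max),
      Linf_individual = .rtrunc_norm_lower(n_ad, params$mu_Linf,
                                           sqrt(params$sigma2_Linf),
                                           pmax(ltm, 0) + 0.1)
    )
    st <- model_state(params, latents)
    if (is.finite(log_posterior(st, ds, priors))) return(st)
  }
  stop("failed to find a finite-posterior initial state", call. = FALSE)
}

## ---- internal fast likelihood pieces -------------------------------------

## per-individual adult local log posterior pieces, all vectorised;
## returns a list of vectors of length n_adult
.adult_local <- function(md, pp, lat, priors) {
  ltm <- .vb(lat$tm_adult, pp$mu_Linf, pp$k_larval, pp$t0)
  mu <- .adult_occasion_means(md, pp, lat)
  occ_ld <- stats::dnorm(md$occ_svl, mu, sqrt(pp$sigma2_L), log = TRUE)
  lik <- as.numeric(rowsum(occ_ld, md$occ_ind))
  sdlog <- sqrt(pp$sigma2_t); meanlog <- log(pp$alpha)
  t_norm <- stats::plnorm(priors$t_max, meanlog, sdlog) -
    stats::plnorm(lat$tm_adult, meanlog, sdlog)
  sd_li <- sqrt(pp$sigma2_Linf)
  list(
    lik = lik,
    ltm = ltm,
    t_prior = stats::dlnorm(lat$age_first_capture, meanlog, sdlog,
                            log = TRUE) - log(t_norm),
    li_prior = stats::dnorm(lat$Linf_individual, pp$mu_Linf, sd_li,
                            log = TRUE) -
      stats::pnorm(ltm, pp$mu_Linf, sd_li, lower.tail = FALSE,
                   log.p = TRUE)
  )
}

## fast full log posterior from flat pieces
.lp_full <- function(pp, lat, md, priors) {
  st <- structure(list(params = pp, latents = lat), class = "model_state")
  lp <- log_prior(st, priors)
  if (!is.finite(lp)) return(-Inf)
  sdl <- sqrt(pp$sigma2_L)
  if (length(md$larv_svl) > 0) {
    mu <- .vb(md$larv_age, pp$mu_Linf, pp$k_larval, pp$t0)
    lp <- lp + sum(stats::dnorm(md$larv_svl, mu, sdl, log = TRUE))
  }
  if (md$n_meta > 0) {
    mu <- .vb(lat$tm_metamorph, pp$mu_Linf, pp$k_larval, pp$t0)
    lp <- lp + sum(stats::dnorm(md$meta_svl, mu, sdl, log = TRUE))
  }
  if (length(md$occ_svl) > 0) {
    mu <- .adult_occasion_means(md, pp, lat)
    lp <- lp + sum(stats::dnorm(md$occ_svl, mu, sdl, log = TRUE))
  }
  lp
}

## One full sweep over all components. `env` is a mutable chain
## environment holding pp, lat, md, priors, transforms, scales, current lp,
## and acceptance accumulators.
.sweep <- function(env) {
  pp <- env$pp; lat <- env$lat; md <- env$md; priors <- env$priors
  tmb <- priors$tm_bounds
  sdl <- sqrt(pp$sigma2_L)

  ## -- population parameters, one at a time, full-posterior ratio --------
  acc_pop <- logical(length(.POP_PARAMS))
  for (j in seq_along(.POP_PARAMS)) {
    nm <- .POP_PARAMS[j]
    tr <- env$transforms[[nm]]
    x <- pp[[nm]]
    z <- .fwd(x, tr) + env$scale_pop[j] * stats::rnorm(1)
    x_new <- .bwd(z, tr)
    pp_new <- pp; pp_new[[nm]] <- x_new
    lp_new <- .lp_full(pp_new, lat, md, priors)
    log_ratio <- (lp_new + .log_jac(x_new, tr)) -
      (env$lp + .log_jac(x, tr))
    if (is.finite(lp_new) && log(stats::runif(1)) < log_ratio) {
      pp <- pp_new
      env$lp <- lp_new
      acc_pop[j] <- TRUE
      sdl <- sqrt(pp$sigma2_L)
    }
  }
  env$pp <- pp

  ## -- metamorph ages, element-wise vectorised ---------------------------
  n_meta <- md$n_meta
  acc_meta_rate <- NA_real_
  if (n_meta > 0) {
    tm <- lat$tm_metamorph
    z <- stats::qlogis((tm - tmb[1]) / (tmb[2] - tmb[1])) +
      env$scale_tm_meta * stats::rnorm(n_meta)
    tm_new <- tmb[1] + (tmb[2] - tmb[1]) * stats::plogis(z)
    mu_old <- .vb(tm, pp$mu_Linf, pp$k_larval, pp$t0)
    mu_new <- .vb(tm_new, pp$mu_Linf, pp$k_larval, pp$t0)
    lik_delta <- stats::dnorm(md$meta_svl, mu_new, sdl, log = TRUE) -
      stats::dnorm(md$meta_svl, mu_old, sdl, log = TRUE)
    delta <- lik_delta +
      log(tm_new - tmb[1]) + log(tmb[2] - tm_new) -
      log(tm - tmb[1]) - log(tmb[2] - tm)
    acc <- log(stats::runif(n_meta)) < delta
    tm[acc] <- tm_new[acc]
    lat$tm_metamorph <- tm
    env$lp <- env$lp + sum(lik_delta[acc])
    env$acc_tm_meta <- acc
    acc_meta_rate <- mean(acc)
  }

  ## -- adult latent blocks ----------------------------------------------
  n_ad <- md$n_adult
  if (n_ad > 0) {
    cur <- .adult_local(md, pp, lat, priors)

    ## (a) age at metamorphosis
    tm <- lat$tm_adult
    z <- stats::qlogis((tm - tmb[1]) / (tmb[2] - tmb[1])) +
      env$scale_tm_ad * stats::rnorm(n_ad)
    tm_new <- tmb[1] + (tmb[2] - tmb[1]) * stats::plogis(z)
    lat_new <- lat; lat_new$tm_adult <- tm_new
    prop <- .adult_local(md, pp, lat_new, priors)
    delta <- (prop$lik + prop$t_prior + prop$li_prior) -
      (cur$lik + cur$t_prior + cur$li_prior) +
      log(tm_new - tmb[1]) + log(tmb[2] - tm_new) -
      log(tm - tmb[1]) - log(tmb[2] - tm)
    bad <- lat$age_first_capture <= tm_new |
      lat$Linf_individual <= prop$ltm
    delta[bad] <- -Inf
    acc <- log(stats::runif(n_ad)) < delta
    lat$tm_adult[acc] <- tm_new[acc]
    env$lp <- env$lp +
      sum((prop$lik + prop$t_prior + prop$li_prior)[acc] -
            (cur$lik + cur$t_prior + cur$li_prior)[acc])
    env$acc_tm_ad <- acc
    cur <- .adult_local(md, pp, lat, priors)

    ## (b) age at first capture, logit on (tm_i, t_max)
    t_ <- lat$age_first_capture
    lo <- lat$tm_adult; hi <- priors$t_max
    z <- stats::qlogis((t_ - lo) / (hi - lo)) +
      env$scale_t * stats::rnorm(n_ad)
    t_new <- lo + (hi - lo) * stats::plogis(z)
    lat_new <- lat; lat_new$age_first_capture <- t_new
    prop <- .adult_local(md, pp, lat_new, priors)
    delta <- (prop$lik + prop$t_prior) - (cur$lik + cur$t_prior) +
      log(t_new - lo) + log(hi - t_new) -
      log(t_ - lo) - log(hi - t_)
    acc <- log(stats::runif(n_ad)) < delta
    lat$age_first_capture[acc] <- t_new[acc]
    env$lp <- env$lp + sum((prop$lik + prop$t_prior)[acc] -
                             (cur$lik + cur$t_prior)[acc])
    env$acc_t <- acc
    cur <- .adult_local(md, pp, lat, priors)

    ## (c) individual asymptotes, identity random walk
    li <- lat$Linf_individual
    li_new <- li + env$scale_li * stats::rnorm(n_ad)
    lat_new <- lat; lat_new$Linf_individual <- li_new
    prop <- .adult_local(md, pp, lat_new, priors)
    delta <- (prop$lik + prop$li_prior) - (cur$lik + cur$li_prior)
    delta[li_new <= cur$ltm] <- -Inf
    acc <- log(stats::runif(n_ad)) < delta
    lat$Linf_individual[acc] <- li_new[acc]
    env$lp <- env$lp + sum((prop$lik + prop$li_prior)[acc] -
                             (cur$lik + cur$li_prior)[acc])
    env$acc_li <- acc
  }

  env$lat <- lat
  env$acc_pop <- acc_pop
  invisible(env)
}

## Robbins-Monro adaptation of log proposal scales toward the target
## acceptance rate; called during burn-in only.
.adapt_scales <- function(env, sweep_idx, target) {
  step <- min(0.25, sweep_idx^-0.6)
  env$scale_pop <- env$scale_pop *
    exp(step * (as.numeric(env$acc_pop) - target))
  if (length(env$acc_tm_meta) > 0) {
    env$scale_tm_meta <- env$scale_tm_meta *
      exp(step * (as.numeric(env$acc_tm_meta) - target))
  }
  if (length(env$acc_tm_ad) > 0) {
    env$scale_tm_ad <- env$scale_tm_ad *
      exp(step * (as.numeric(env$acc_tm_ad) - target))
    env$scale_t <- env$scale_t *
      exp(step * (as.numeric(env$acc_t) - target))
    env$scale_li <- env$scale_li *
      exp(step * (as.numeric(env$acc_li) - target))
  }
  invisible(env)
}

.make_chain_env <- function(state, ds, priors, scales = NULL) {
  md <- model_data(ds)
  env <- new.env(parent = emptyenv())
  env$pp <- state$params
  env$lat <- state$latents
  env$md <- md
  env$priors <- priors
  env$transforms <- .param_transforms(priors)
  init_pop <- if (!is.null(scales$params)) scales$params else
    rep(0.1, length(.POP_PARAMS))
  init_lat <- if (!is.null(scales$latent)) scales$latent else 0.5
  env$scale_pop <- rep_len(init_pop, length(.POP_PARAMS))
  env$scale_tm_meta <- rep_len(init_lat, md$n_meta)
  env$scale_tm_ad <- rep_len(init_lat, md$n_adult)
  env$scale_t <- rep_len(init_lat, md$n_adult)
  env$scale_li <- rep_len(if (!is.null(scales$latent)) scales$latent
                          else 1.0, md$n_adult)
  env$acc_tm_meta <- logical(0)
  env$acc_tm_ad <- logical(0)
  env$acc_t <- logical(0)
  env$acc_li <- logical(0)
  env$lp <- .lp_full(env$pp, env$lat, md, priors)
  env
}

#' One Metropolis-within-Gibbs sweep
#'
#' Exposed for inspection and testing; [run_mcmc()] drives the same kernel.
#'
#' @param state A `model_state` with finite log posterior.
#' @param ds A `growth_dataset`.
#' @param priors A `prior_spec`.
#' @param scales Optional named list of proposal scales (see
#'   [fit_config()]).
#' @return A list with the updated `state`, logical `accept` flags for the
#'   population-parameter components, and per-block latent acceptance
#'   vectors in `accept_latent`.
#' @export
mh_step <- function(state, ds, priors = default_priors(), scales = NULL) {
  env <- .make_chain_env(state, ds, priors, scales)
  if (!is.finite(env$lp)) {
    stop("state has non-finite log posterior", call. = FALSE)
  }
  .sweep(env)
  list(
    state = model_state(env$pp, env$lat),
    accept = stats::setNames(env$acc_pop, .POP_PARAMS),
    accept_latent = list(tm_metamorph = env$acc_tm_meta,
                         tm_adult = env$acc_tm_ad,
                         age_first_capture = env$acc_t,
                         Linf_individual = env$acc_li)
  )
}

.flatten_state <- function(env, keep_latents) {
  pop <- unlist(env$pp[.POP_PARAMS], use.names = FALSE)
  if (!keep_latents) return(pop)
  c(pop, env$lat$tm_metamorph, env$lat$tm_adult,
    env$lat$age_first_capture, env$lat$Linf_individual)
}

.param_names <- function(md, keep_latents) {
  nms <- .POP_PARAMS
  if (!keep_latents) return(nms)
  c(nms,
    if (md$n_meta > 0) sprintf("tm_meta[%d]", seq_len(md$n_meta)),
    if (md$n_adult > 0) sprintf("tm_adult[%d]", seq_len(md$n_adult)),
    if (md$n_adult > 0) sprintf("t_first[%d]", seq_len(md$n_adult)),
    if (md$n_adult > 0) sprintf("Linf_ind[%d]", seq_len(md$n_adult)))
}

#' Run the full MCMC fit
#'
#' Runs `n_chains` independent chains from overdispersed starts, adapting
#' proposal scales during burn-in only, and retains every `thin`-th
#' post-burn-in draw. Fully reproducible given the master seed.
#'
#' @param ds A `growth_dataset`.
#' @param priors A `prior_spec`.
#' @param config A `fit_config`.
#' @param progress Print chain progress every 5% of iterations?
#' @return An object of class `posterior_samples`: a list with `draws`
#'   (one matrix per chain, retained draws by parameters), `param_names`,
#'   `n_pop` (number of population parameters), `config`, `priors`, and
#'   `provenance` (seed, data stream sizes, final proposal scales and
#'   post-burn-in acceptance rates per chain).
#' @export
run_mcmc <- function(ds, priors = default_priors(),
                     config = fit_config(), progress = FALSE) {
  stopifnot(inherits(ds, "growth_dataset"), inherits(config, "fit_config"))
  md <- model_data(ds)
  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  nms <- .param_names(md, config$keep_latents)
  draws <- vector("list", config$n_chains)
  chain_info <- vector("list", config$n_chains)
  for (chain in seq_len(config$n_chains)) {
    set.seed((config$seed + 104729L * chain) %% .Machine$integer.max)
    state <- initialize_state(priors, ds)
    env <- .make_chain_env(state, ds, priors, config$proposal_scales)
    mat <- matrix(NA_real_, nrow = n_keep, ncol = length(nms),
                  dimnames = list(NULL, nms))
    keep_row <- 0L
    n_acc_post <- numeric(length(.POP_PARAMS))
    n_post <- 0L
    report_every <- max(1L, config$n_iter %/% 20L)
    for (it in seq_len(config$n_iter)) {
      .sweep(env)
      if (config$adapt && it <= config$n_burnin) {
        .adapt_scales(env, it, config$target_accept)
      }
      if (it %% 2000L == 0L) {
        ## guard against accumulated round-off in the incremental lp
        env$lp <- .lp_full(env$pp, env$lat, env$md, env$priors)
      }
      if (it > config$n_burnin) {
        n_post <- n_post + 1L
        n_acc_post <- n_acc_post + as.numeric(env$acc_pop)
        if ((it - config$n_burnin) %% config$thin == 0L) {
          keep_row <- keep_row + 1L
          mat[keep_row, ] <- .flatten_state(env, config$keep_latents)
        }
      }
      if (progress && it %% report_every == 0L) {
        message(sprintf(
          "chain %d: %3.0f%% done, lp = %.1f, mean pop acceptance %.2f",
          chain, 100 * it / config$n_iter, env$lp, mean(env$acc_pop)))
      }
    }
    draws[[chain]] <- mat[seq_len(keep_row), , drop = FALSE]
    chain_info[[chain]] <- list(
      accept_rate_pop = stats::setNames(n_acc_post / max(n_post, 1L),
                                        .POP_PARAMS),
      final_scale_pop = stats::setNames(env$scale_pop, .POP_PARAMS))
  }
  structure(list(
    draws = draws,
    param_names = nms,
    n_pop = length(.POP_PARAMS),
    config = config,
    priors = priors,
    provenance = list(
      seed = config$seed,
      n_larvae = length(md$larv_svl),
      n_metamorphs = md$n_meta,
      n_adults = md$n_adult,
      chains = chain_info)
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples>\n")
  cat("  chains:", length(x$draws), "\n")
  cat("  retained draws per chain:", nrow(x$draws[[1]]), "\n")
  cat("  parameters:", length(x$param_names),
      sprintf("(%d population)", x$n_pop), "\n")
  invisible(x)
}

#' Generic componentwise adaptive random-walk Metropolis sampler
#'
#' The same kernel as the model fit, but for an arbitrary log target on
#' an unconstrained vector; used to validate the sampler against analytic
#' targets.
#'
#' @param log_target Function mapping a numeric vector to a log density.
#' @param init Numeric starting vector with finite log target.
#' @param n_iter Total sweeps.
#' @param n_burnin Burn-in sweeps (with adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param scales Initial per-component proposal standard deviations.
#' @param target_accept Adaptation target acceptance rate.
#' @return Matrix of retained draws (rows) by components (columns).
#' @export
sample_rw_metropolis <- function(log_target, init, n_iter,
                                 n_burnin = n_iter %/% 5, thin = 1,
                                 scales = rep(1, length(init)),
                                 target_accept = 0.44) {
  d <- length(init)
  x <- init
  lp <- log_target(x)
  stopifnot(is.finite(lp))
  scales <- rep_len(scales, d)
  n_keep <- (n_iter - n_burnin) %/% thin
  out <- matrix(NA_real_, n_keep, d)
  row <- 0L
  for (it in seq_len(n_iter)) {
    acc <- logical(d)
    for (j in seq_len(d)) {
      x_new <- x
      x_new[j] <- x[j] + scales[j] * stats::rnorm(1)
      lp_new <- log_target(x_new)
      if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
        x <- x_new; lp <- lp_new; acc[j] <- TRUE
      }
    }
    if (it <= n_burnin) {
      step <- min(0.25, it^-0.6)
      scales <- scales * exp(step * (as.numeric(acc) - target_accept))
    }
    if (it > n_burnin && (it - n_burnin) %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- x
    }
  }
  out[seq_len(row), , drop = FALSE]
}
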
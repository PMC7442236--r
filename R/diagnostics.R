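#' @title Convergence diagnostics and posterior predictive checks
#' @description
#' Classic multi-chain diagnostics as used in the WinBUGS era: the
#' Gelman-Rubin potential scale reduction factor (PSRF) per parameter, the
#' Brooks-Gelman multivariate PSRF over a parameter block, effective sample
#' size via initial-positive-sequence autocorrelation truncation, and
#' chi-square-type posterior predictive (Bayesian) p-values for larval
#' sizes and adult growth increments.
#' @name diagnostics
NULL

.as_chain_matrix <- function(chains) {
  if (is.matrix(chains)) return(chains)
  if (is.list(chains)) {
    n <- unique(vapply(chains, length, integer(1)))
    if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
    return(do.call(cbind, chains))
  }
  stop("chains must be a matrix (iterations x chains) or list of vectors",
       call. = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF:
#' `R = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B = n * var(chain means)`. Identical chains give
#' `sqrt((n-1)/n)`, the formula's floor.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of length >= 2.
#' @param split Split each chain in half first (halves treated as chains)?
#' @return Scalar PSRF.
#' @export
psrf <- function(chains, split = FALSE) {
  m <- .as_chain_matrix(chains)
  if (split) {
    n2 <- nrow(m) %/% 2
    m <- cbind(m[seq_len(n2), , drop = FALSE],
               m[nrow(m) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(m); k <- ncol(m)
  stopifnot(k >= 2, n >= 2)
  W <- mean(apply(m, 2, stats::var))
  if (W == 0) stop("degenerate chains: zero within-chain variance",
                   call. = FALSE)
  B <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Brooks-Gelman multivariate PSRF
#'
#' `MPSRF = sqrt((n-1)/n + (m+1)/m * lambda_1)` where `lambda_1` is the
#' largest eigenvalue of `W^{-1} B / n`, `W` the mean within-chain
#' covariance and `B/n` the between-chain covariance of the chain means.
#'
#' @param chains List of matrices (iterations x parameters), one per chain.
#' @return Scalar MPSRF.
#' @export
multivariate_psrf <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  dims <- vapply(chains, dim, integer(2))
  stopifnot(length(unique(dims[1, ])) == 1, length(unique(dims[2, ])) == 1)
  n <- dims[1, 1]; p <- dims[2, 1]; m <- length(chains)
  if (p >= n) stop("need more draws per chain than parameters",
                   call. = FALSE)
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  means <- t(vapply(chains, colMeans, numeric(p)))
  if (p == 1) means <- matrix(means, ncol = 1)
  Bn <- stats::cov(means)  # = B/n
  Winv_B <- tryCatch(solve(W, Bn), error = function(e) {
    stop("within-chain covariance is singular; select a smaller ",
         "parameter subset", call. = FALSE)
  })
  lambda1 <- max(Re(eigen(Winv_B, only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lambda1)
}

#' Effective sample size
#'
#' Per chain, the autocorrelation spectrum is truncated at the first
#' non-positive pair sum of consecutive autocorrelations
#' (initial-positive-sequence rule), giving
#' `ess = n / (1 + 2 * sum(rho))`; chain ESS values are summed.
#'
#' @param chains Matrix (iterations x chains), list of vectors, or a
#'   single numeric vector.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains) && is.null(dim(chains))) {
    chains <- matrix(chains, ncol = 1)
  }
  m <- .as_chain_matrix(chains)
  ess_one <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) {
      stop("degenerate chain: zero variance", call. = FALSE)
    }
    rho <- as.numeric(stats::acf(x, lag.max = n - 1, plot = FALSE,
                                 demean = TRUE)$acf)[-1]
    ## pair consecutive autocorrelations; stop before the first
    ## non-positive pair sum
    n_pairs <- length(rho) %/% 2
    s <- 0
    for (k in seq_len(n_pairs)) {
      pair <- rho[2 * k - 1] + rho[2 * k]
      if (pair <= 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }
  sum(apply(m, 2, ess_one))
}

## Pooled draw matrix across chains, optionally restricted to columns
.pooled_draws <- function(samples, cols = NULL) {
  m <- do.call(rbind, samples$draws)
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  m
}

#' Posterior summaries
#'
#' Pooled across chains: posterior mean and equal-tailed 95% credible
#' interval per parameter; PSRF and ESS are included when at least two
#' chains are present.
#'
#' @param samples A `posterior_samples` object.
#' @param params Character vector of parameter names (default: population
#'   parameters only).
#' @return Data frame with columns `parameter, mean, lo95, hi95, psrf,
#'   ess`.
#' @export
summarize_draws <- function(samples,
                            params = samples$param_names[
                              seq_len(samples$n_pop)]) {
  stopifnot(inherits(samples, "posterior_samples"))
  pooled <- .pooled_draws(samples, params)
  multi <- length(samples$draws) >= 2
  out <- data.frame(
    parameter = params,
    mean = colMeans(pooled),
    lo95 = apply(pooled, 2, stats::quantile, 0.025),
    hi95 = apply(pooled, 2, stats::quantile, 0.975),
    psrf = NA_real_,
    ess = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (multi) {
    for (j in seq_along(params)) {
      cols <- vapply(samples$draws, function(d) d[, params[j]],
                     numeric(nrow(samples$draws[[1]])))
      out$psrf[j] <- tryCatch(psrf(cols), error = function(e) NA_real_)
      out$ess[j] <- tryCatch(effective_sample_size(cols),
                             error = function(e) NA_real_)
    }
  }
  out
}

#' Full diagnostics report
#'
#' Univariate PSRF and ESS per population parameter, the multivariate PSRF
#' over the population block, and (when the dataset is supplied) Bayesian
#' p-values for larval sizes and adult growth increments.
#'
#' @param samples A `posterior_samples` object (>= 2 chains).
#' @param ds Optional `growth_dataset` for the posterior predictive
#'   checks.
#' @param seed Seed for the replicate simulations.
#' @return A list with `psrf`, `ess` (named vectors), `mpsrf`, and, if
#'   `ds` is given, `bayes_p_larval` and `bayes_p_adult_increments`.
#' @export
diagnostics_report <- function(samples, ds = NULL, seed = 1) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(samples$draws) < 2) {
    stop("diagnostics require at least 2 chains", call. = FALSE)
  }
  pop <- samples$param_names[seq_len(samples$n_pop)]
  summ <- summarize_draws(samples, pop)
  rep <- list(
    psrf = stats::setNames(summ$psrf, pop),
    ess = stats::setNames(summ$ess, pop),
    mpsrf = multivariate_psrf(
      lapply(samples$draws, function(d) d[, pop, drop = FALSE]))
  )
  if (!is.null(ds)) {
    if (nrow(ds$larvae) > 0) {
      rep$bayes_p_larval <- bayesian_pvalue(samples, ds, "larval",
                                            seed = seed)
    }
    if (length(ds$adults) > 0) {
      rep$bayes_p_adult_increments <-
        bayesian_pvalue(samples, ds, "adult_increments", seed = seed + 1)
    }
  }
  rep
}

#' Posterior predictive (Bayesian) p-value
#'
#' Discrepancy is the sum of squared Pearson residuals
#' `D = sum(((y - mu) / sigma_L)^2)`. For the larval stage, `y` are the
#' observed larval lengths and `mu` the larval curve at the known ages.
#' For the adult stage, `y` are the successive-occasion growth increments
#' of recaptured individuals and `mu` the model-mean increments (this uses
#' the retained latent draws, so the fit must keep latents). For each
#' retained draw, replicate data are simulated from that draw and the
#' replicate discrepancy computed; the p-value is the proportion of draws
#' with `D_rep > D_obs`, ties counting one half.
#'
#' @param samples A `posterior_samples` object with latent draws for the
#'   adult stage.
#' @param ds A `growth_dataset`.
#' @param stage `"larval"` or `"adult_increments"`.
#' @param seed Seed for the replicate simulations.
#' @return Scalar p-value in `[0, 1]`.
#' @export
bayesian_pvalue <- function(samples, ds,
                            stage = c("larval", "adult_increments"),
                            seed = 1) {
  stage <- match.arg(stage)
  stopifnot(inherits(samples, "posterior_samples"))
  pooled <- .pooled_draws(samples)
  if (nrow(pooled) == 0) stop("no retained draws", call. = FALSE)
  set.seed(seed)
  if (stage == "larval") {
    if (nrow(ds$larvae) == 0) stop("no larval data", call. = FALSE)
    age <- ds$larvae$age_years
    obs <- ds$larvae$svl_mm
    stat <- vapply(seq_len(nrow(pooled)), function(r) {
      d <- pooled[r, ]
      mu <- larval_length(age, d[["mu_Linf"]], d[["k_larval"]], d[["t0"]])
      sdl <- sqrt(d[["sigma2_L"]])
      D_obs <- sum(((obs - mu) / sdl)^2)
      y_rep <- stats::rnorm(length(mu), mu, sdl)
      D_rep <- sum(((y_rep - mu) / sdl)^2)
      c(D_obs, D_rep)
    }, numeric(2))
  } else {
    if (length(ds$adults) == 0) stop("no adult data", call. = FALSE)
    md <- model_data(ds)
    n_ad <- md$n_adult
    lat_cols <- list(
      tm_adult = sprintf("tm_adult[%d]", seq_len(n_ad)),
      t_first = sprintf("t_first[%d]", seq_len(n_ad)),
      Linf_ind = sprintf("Linf_ind[%d]", seq_len(n_ad)))
    if (!all(unlist(lat_cols) %in% samples$param_names)) {
      stop("adult-increment check needs latent draws ",
           "(fit with keep_latents = TRUE)", call. = FALSE)
    }
    ## occasion pairs within individuals: successive differences
    keep_pair <- c(FALSE, diff(md$occ_ind) == 0)
    prev <- which(keep_pair) - 1L
    curr <- which(keep_pair)
    if (length(curr) == 0) {
      stop("no recaptured individuals: increments undefined", call. = FALSE)
    }
    obs_inc <- md$occ_svl[curr] - md$occ_svl[prev]
    stat <- vapply(seq_len(nrow(pooled)), function(r) {
      d <- pooled[r, ]
      lat <- list(tm_adult = unname(d[lat_cols$tm_adult]),
                  age_first_capture = unname(d[lat_cols$t_first]),
                  Linf_individual = unname(d[lat_cols$Linf_ind]))
      pp <- as.list(d[seq_len(samples$n_pop)])
      mu <- .adult_occasion_means(md, pp, lat)
      sdl <- sqrt(pp$sigma2_L)
      mu_inc <- mu[curr] - mu[prev]
      D_obs <- sum(((obs_inc - mu_inc) / sdl)^2)
      y_rep <- stats::rnorm(length(mu), mu, sdl)
      rep_inc <- y_rep[curr] - y_rep[prev]
      D_rep <- sum(((rep_inc - mu_inc) / sdl)^2)
      c(D_obs, D_rep)
    }, numeric(2))
  }
  mean(stat[2, ] > stat[1, ]) + 0.5 * mean(stat[2, ] == stat[1, ])
}
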
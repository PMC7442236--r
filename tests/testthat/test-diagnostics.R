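test_that("psrf hits its formula floor on identical chains", {
  x <- rnorm(400)
  expect_equal(psrf(list(x, x)), sqrt(399 / 400), tolerance = 1e-12)
  expect_equal(psrf(list(x, x, x)), sqrt(399 / 400), tolerance = 1e-12)
})

test_that("psrf separates diverged chains and passes mixed ones", {
  set.seed(21)
  c1 <- rnorm(500, 0, 1)
  c2 <- rnorm(500, 10, 1)
  expect_gt(psrf(list(c1, c2)), 3)
  set.seed(22)
  same <- replicate(3, rnorm(5000), simplify = FALSE)
  expect_lt(psrf(same), 1.05)
})

test_that("psrf matches a brute-force evaluation and the coda oracle", {
  set.seed(23)
  chains <- replicate(3, cumsum(rnorm(1000)) * 0.05 + rnorm(1000),
                      simplify = FALSE)
  # brute-force re-evaluation of the classic formula
  n <- 1000
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  expect_equal(psrf(chains), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-12)

  # coda refines the classic estimator (between-chain inflation and a
  # df adjustment); on long well-mixed chains the two coincide
  skip_if_not_installed("coda")
  set.seed(24)
  mixed <- replicate(3, rnorm(5000), simplify = FALSE)
  ml <- coda::mcmc.list(lapply(mixed, coda::mcmc))
  expect_equal(psrf(mixed),
               unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1]),
               tolerance = 0.005)
})

test_that("psrf rejects degenerate chains", {
  expect_error(psrf(list(rep(1, 50), rep(1, 50))), "degenerate")
})

test_that("multivariate psrf matches its closed form and coda", {
  x <- matrix(rnorm(600), ncol = 2)
  # identical chains: B = 0, floor sqrt((n-1)/n)
  expect_equal(multivariate_psrf(list(x, x)), sqrt(299 / 300),
               tolerance = 1e-12)

  # single-parameter reduction: the univariate formula with the
  # Brooks-Gelman (m+1)/m between-chain factor
  set.seed(31)
  c1 <- matrix(rnorm(800, 0, 1)); c2 <- matrix(rnorm(800, 0.4, 1.3))
  n <- 800; m <- 2
  W <- (var(as.numeric(c1)) + var(as.numeric(c2))) / 2
  Bn <- var(c(mean(c1), mean(c2)))
  expect_equal(multivariate_psrf(list(c1, c2)),
               sqrt((n - 1) / n + (m + 1) / m * Bn / W),
               tolerance = 1e-9)

  # independent dense-eigen oracle on a 2-parameter, 3-chain fixture
  set.seed(32)
  chains <- replicate(3, cbind(rnorm(500), rnorm(500, 1, 2)),
                      simplify = FALSE)
  n <- 500; m <- 3
  W2 <- (cov(chains[[1]]) + cov(chains[[2]]) + cov(chains[[3]])) / m
  mu <- t(sapply(chains, colMeans))
  Bn2 <- cov(mu)
  lam <- max(eigen(solve(W2) %*% Bn2)$values)
  expect_equal(multivariate_psrf(chains),
               sqrt((n - 1) / n + (m + 1) / m * lam),
               tolerance = 1e-9)
})

test_that("mpsrf never drops below the formula floor", {
  set.seed(33)
  for (i in 1:20) {
    chains <- replicate(3, cbind(rnorm(200), rnorm(200)),
                        simplify = FALSE)
    expect_gte(multivariate_psrf(chains), sqrt(199 / 200))
  }
})

test_that("effective sample size is sane for iid and AR(1) chains", {
  set.seed(41)
  iid <- matrix(rnorm(12000), ncol = 3)
  ess <- effective_sample_size(iid)
  expect_gt(ess, 0.8 * 12000)
  expect_lt(ess, 1.2 * 12000)

  # AR(1) with phi = 0.9: asymptotic ESS ratio (1 - phi)/(1 + phi)
  set.seed(42)
  phi <- 0.9
  n <- 20000
  ar <- as.numeric(arima.sim(list(ar = phi), n))
  ess_ar <- effective_sample_size(ar)
  target <- n * (1 - phi) / (1 + phi)
  expect_gt(ess_ar, target / 1.5)
  expect_lt(ess_ar, target * 1.5)

  expect_error(effective_sample_size(rep(2, 100)), "degenerate")
})

test_that("posterior summaries pool chains correctly", {
  m1 <- matrix(1:100, ncol = 1, dimnames = list(NULL, "k_larval"))
  s <- summarize_draws(fake_samples(list(m1)), "k_larval")
  expect_equal(s$mean, 50.5)
  expect_equal(s$lo95, unname(quantile(1:100, 0.025)))

  # all draws equal: degenerate CrI
  cs <- constant_samples(c(59, 5, 1.77, 0.91, 0, 4.5, 0.25, 4))
  sc <- summarize_draws(cs, "mu_Linf")
  expect_equal(sc$mean, 59)
  expect_equal(sc$lo95, 59)
  expect_equal(sc$hi95, 59)

  # shifting draws shifts the mean (linearity)
  set.seed(51)
  base <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "t0"))
  s0 <- summarize_draws(fake_samples(list(base)), "t0")
  s3 <- summarize_draws(fake_samples(list(base + 3)), "t0")
  expect_equal(s3$mean, s0$mean + 3)
  expect_equal(s3$lo95, s0$lo95 + 3)
})

test_that("bayesian p-value detects inflated replicate variance", {
  # observations generated with tiny noise; posterior believes huge noise
  set.seed(61)
  cfg <- sim_config(n_larvae = 80, n_metamorphs = 0, n_adults = 0,
                    truth = synthetic_truth(sigma2_L = 0.04), seed = 61)
  ds <- growth_dataset(larvae = simulate_larvae(cfg))
  loud <- constant_samples(c(59, 5, 1.77, 0.91, 0, 4.5, 0.25, 400),
                           n = 200)
  expect_gt(bayesian_pvalue(loud, ds, "larval", seed = 1), 0.95)
  # and the reverse: posterior believes far less noise than the data show
  cfg2 <- sim_config(n_larvae = 80, n_metamorphs = 0, n_adults = 0,
                     truth = synthetic_truth(sigma2_L = 400), seed = 62)
  ds2 <- growth_dataset(larvae = simulate_larvae(cfg2))
  quiet <- constant_samples(c(59, 5, 1.77, 0.91, 0, 4.5, 0.25, 4),
                            n = 200)
  expect_lt(bayesian_pvalue(quiet, ds2, "larval", seed = 1), 0.05)
})

test_that("bayesian p-value is invariant to observation order", {
  set.seed(63)
  cfg <- sim_config(n_larvae = 40, n_metamorphs = 0, n_adults = 0,
                    seed = 63)
  ds <- growth_dataset(larvae = simulate_larvae(cfg))
  ds_perm <- growth_dataset(larvae = ds$larvae[sample(40), ])
  s <- constant_samples(c(59, 5, 1.77, 0.91, 0, 4.5, 0.25, 4), n = 150)
  expect_equal(bayesian_pvalue(s, ds, "larval", seed = 9),
               bayesian_pvalue(s, ds_perm, "larval", seed = 9))
})

test_that("p-value errors without data for the requested stage", {
  s <- constant_samples(c(59, 5, 1.77, 0.91, 0, 4.5, 0.25, 4))
  expect_error(bayesian_pvalue(s, growth_dataset(), "larval"), "no larval")
  expect_error(bayesian_pvalue(s, growth_dataset(), "adult_increments"),
               "no adult")
})
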
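test_that("default priors encode the intended vague distributions", {
  pr <- default_priors()
  # gamma shape/rate convention: prior mean of a rate parameter is 1
  expect_equal(pr$k_larval$shape / pr$k_larval$rate, 1.0)
  # uniform density inside the asymptote bounds
  expect_equal(param_log_prior(55, pr$mu_Linf), log(1 / 70))
  # outside support
  expect_identical(param_log_prior(2.5, pr$t0), -Inf)
  expect_identical(param_log_prior(-0.1, pr$sigma2_L), -Inf)
  expect_equal(pr$tm_bounds, c(0.2, 0.7))
  expect_equal(pr$t_max, 20)
})

test_that("truncated lognormal latent age density is renormalised", {
  expect_identical(latent_age_log_density(20.1, 4, 0.25, 0.5, 20), -Inf)
  expect_identical(latent_age_log_density(0.4, 4, 0.25, 0.5, 20), -Inf)
  # integrates to 1 over the truncation interval
  f <- function(t) exp(latent_age_log_density(t, 4, 0.25, 0.5, 20))
  expect_equal(integrate(f, 0.5, 20, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # frozen quadrature oracle (30-digit mpmath)
  expect_equal(latent_age_log_density(4, 4, 0.25, 0.5, 20),
               -1.611426034834879, tolerance = 1e-10)
  expect_error(latent_age_log_density(1, 4, 0.25, 2, 1), "bounds")
})

test_that("log_prior sums component log densities and guards support", {
  pr <- default_priors()
  st <- tiny_state()
  by_hand <- sum(vapply(
    c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0", "alpha",
      "sigma2_t", "sigma2_L"),
    function(nm) param_log_prior(st$params[[nm]], pr[[nm]]), numeric(1))) +
    4 * dunif(0.45, 0.2, 0.7, log = TRUE) +
    sum(latent_age_log_density(st$latents$age_first_capture, 4.5, 0.25,
                               lower = st$latents$tm_adult, upper = 20)) +
    sum(dnorm(st$latents$Linf_individual, 59, sqrt(5), log = TRUE) -
          pnorm(length_at_metamorphosis(st$latents$tm_adult, 59, 1.77, 0),
                59, sqrt(5), lower.tail = FALSE, log.p = TRUE))
  expect_equal(log_prior(st, pr), by_hand, tolerance = 1e-12)

  bad <- tiny_state()
  bad$params$k_adult <- -1
  expect_identical(log_prior(bad, pr), -Inf)

  bad2 <- tiny_state()
  bad2$latents$tm_adult[1] <- 0.9  # outside U(0.2, 0.7)
  expect_identical(log_prior(bad2, pr), -Inf)

  bad3 <- tiny_state()
  bad3$latents$age_first_capture[1] <- 0.3  # younger than metamorphosis
  expect_identical(log_prior(bad3, pr), -Inf)

  # no latents: population terms only
  st0 <- model_state(tiny_state()$params)
  pop_only <- sum(vapply(
    c("mu_Linf", "sigma2_Linf", "k_larval", "k_adult", "t0", "alpha",
      "sigma2_t", "sigma2_L"),
    function(nm) param_log_prior(st0$params[[nm]], pr[[nm]]), numeric(1)))
  expect_equal(log_prior(st0, pr), pop_only)
})

test_that("larval likelihood is a sum of normal log densities", {
  st <- tiny_state()
  # one larva observed exactly at its predicted mean
  age <- 0.3
  mu <- larval_length(age, 59, 1.77, 0)
  one <- data.frame(wetland_id = "W", capture_date = Sys.Date(),
                    pond_fill_date = Sys.Date() - 110, svl_mm = mu,
                    age_years = age)
  expect_equal(log_lik_larvae(one, st), -0.5 * log(2 * pi * 4))

  # duplicating a record doubles its contribution
  ds <- tiny_dataset()
  l1 <- log_lik_larvae(ds$larvae[1, ], st)
  expect_equal(log_lik_larvae(ds$larvae[c(1, 1), ], st), 2 * l1)

  # per-record oracle
  mu_all <- larval_length(ds$larvae$age_years, 59, 1.77, 0)
  expect_equal(log_lik_larvae(ds$larvae, st),
               sum(dnorm(ds$larvae$svl_mm, mu_all, 2, log = TRUE)))
})

test_that("metamorph likelihood uses the latent ages", {
  st <- tiny_state()
  ds <- tiny_dataset()
  mu <- length_at_metamorphosis(c(0.4, 0.5), 59, 1.77, 0)
  expect_equal(log_lik_metamorphs(ds$metamorphs, st),
               sum(dnorm(ds$metamorphs$svl_mm, mu, 2, log = TRUE)))
  expect_equal(log_lik_metamorphs(ds$metamorphs[0, ], st), 0)
  st_bad <- tiny_state()
  st_bad$latents$tm_metamorph <- 0.4  # one latent for two records
  expect_error(log_lik_metamorphs(ds$metamorphs, st_bad), "one tm")
})

test_that("adult likelihood sums occasion terms across histories", {
  st <- tiny_state()
  ds <- tiny_dataset()
  lat <- st$latents
  ltm <- length_at_metamorphosis(lat$tm_adult, 59, 1.77, 0)
  by_hand <- 0
  for (i in 1:2) {
    h <- ds$adults[[i]]
    mu <- adult_length_at_recapture(lat$age_first_capture[i],
                                    h$time_offset_years, lat$tm_adult[i],
                                    ltm[i], lat$Linf_individual[i],
                                    0.91, 0)
    by_hand <- by_hand + sum(dnorm(h$svl_mm, mu, 2, log = TRUE))
  }
  expect_equal(log_lik_adults(ds$adults, st), by_hand, tolerance = 1e-12)

  # single occasion observed exactly at its predicted mean
  mu1 <- adult_length(3.0, 0.45, ltm[1], lat$Linf_individual[1], 0.91, 0)
  one <- list(capture_history("X", "2015-11-01", 0, mu1))
  st1 <- st
  st1$latents <- list(tm_metamorph = numeric(), tm_adult = 0.45,
                      age_first_capture = 3.0,
                      Linf_individual = lat$Linf_individual[1])
  expect_equal(log_lik_adults(one, st1), -0.5 * log(2 * pi * 4))

  expect_error(log_lik_adults(ds$adults, st1), "one latent triple")
})

test_that("log_posterior composes prior and likelihoods", {
  pr <- default_priors()
  st <- tiny_state()
  ds <- tiny_dataset()
  expect_equal(log_posterior(st, ds, pr),
               log_prior(st, pr) + log_lik_larvae(ds$larvae, st) +
                 log_lik_metamorphs(ds$metamorphs, st) +
                 log_lik_adults(ds$adults, st))
  # empty dataset: posterior is the prior alone
  st0 <- model_state(st$params)
  expect_equal(log_posterior(st0, growth_dataset(), pr),
               log_prior(st0, pr))
  # out-of-support state
  bad <- tiny_state()
  bad$params$sigma2_L <- 0
  expect_identical(log_posterior(bad, ds, pr), -Inf)
})

test_that("likelihoods are invariant to record order", {
  st <- tiny_state()
  ds <- tiny_dataset()
  expect_equal(log_lik_larvae(ds$larvae[2:1, ], st),
               log_lik_larvae(ds$larvae, st))
  st_swap <- st
  st_swap$latents$tm_metamorph <- rev(st$latents$tm_metamorph)
  expect_equal(log_lik_metamorphs(ds$metamorphs[2:1, ], st_swap),
               log_lik_metamorphs(ds$metamorphs, st))
})
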
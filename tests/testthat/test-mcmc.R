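test_that("log-posterior enforces support and reduces to likelihood + prior", {
  tab <- random_cognacy_table(40, seed = 21)
  priors <- prior_config(
    homer = prior_uniform(100, 5000),
    hittite = prior_uniform(3200, 3600),
    root = prior_uniform(7000, 11000)
  )
  # violating the tree constraint zeroes the density
  expect_identical(
    log_posterior(list(age_homer = 9500, age_hittite = 3400, age_root = 9000),
                  tab, priors),
    -Inf
  )
  expect_identical(
    log_posterior(list(age_homer = 2000, age_hittite = 3400, age_root = 12000),
                  tab, priors),
    -Inf
  )
  # under uniform priors the posterior differs from the likelihood by a constant
  offs <- vapply(list(c(1000, 3300, 8000), c(2500, 3500, 9500), c(4000, 3250, 10500)),
                 function(a) {
                   ages <- tree_ages(a[1], a[2], a[3])
                   log_posterior(ages, tab, priors) -
                     as.numeric(total_loglik(tab, ages))
                 }, numeric(1))
  expect_equal(max(offs) - min(offs), 0, tolerance = 1e-10)
  # dropping the likelihood leaves the log prior alone
  expect_equal(
    log_posterior(tree_ages(2000, 3400, 9000), tab, priors, use_likelihood = FALSE),
    -log(4900) - log(400) - log(4000),
    tolerance = 1e-10
  )
})

test_that("chains are bit-identical under the same seed and settings", {
  tab <- filter_usable(reference_cognacy_table(seed = 1))
  st <- mcmc_settings(n_iterations = 5000, seed = 77)
  ch1 <- suppressWarnings(run_mcmc(tab, prior_config(), st))
  ch2 <- suppressWarnings(run_mcmc(tab, prior_config(), st))
  expect_identical(ch1$age_homer, ch2$age_homer)
  expect_identical(ch1$log_posterior, ch2$log_posterior)
  st2 <- mcmc_settings(n_iterations = 5000, seed = 78)
  ch3 <- suppressWarnings(run_mcmc(tab, prior_config(), st2))
  expect_false(identical(ch1$age_homer, ch3$age_homer))
})

test_that("with no data the posterior reproduces the priors", {
  empty <- filter_usable(reference_cognacy_table(seed = 1))[0, ]
  priors <- prior_config(
    homer = prior_normal(2800, 200),
    hittite = prior_uniform(3200, 3600),
    root = prior_normal(8700, 550)
  )
  ch <- run_mcmc(empty, priors, mcmc_settings(n_iterations = 150000, seed = 5))
  # Kolmogorov-Smirnov distance between the marginal and the analytic prior
  ks_dist <- function(x, cdf) max(abs(seq_along(x) / length(x) - cdf(sort(x))))
  expect_lt(ks_dist(ch$age_homer, function(q) stats::pnorm(q, 2800, 200)), 0.05)
  expect_lt(ks_dist(ch$age_hittite, function(q) stats::punif(q, 3200, 3600)), 0.05)
  expect_lt(ks_dist(ch$age_root, function(q) stats::pnorm(q, 8700, 550)), 0.05)
})

test_that("an explicit seed is mandatory and settings are validated", {
  expect_error(mcmc_settings(), class = "lexidate_validation_error")
  expect_error(mcmc_settings(n_iterations = 100, burn_in_fraction = 1, seed = 1),
               class = "lexidate_validation_error")
  expect_error(mcmc_settings(n_iterations = 100, thin = 1000, seed = 1),
               class = "lexidate_validation_error")
})

test_that("posterior summaries convert calendars and ignore chain order", {
  const <- tibble::tibble(
    iteration = 1:200, age_homer = 2707, age_hittite = 3400,
    age_root = 9000, log_posterior = 0
  )
  s <- summarize_posterior(const, reference_year = 2000)
  hom <- s[s$parameter == "age_homer", ]
  expect_equal(hom$mean_date_bce, 707)
  expect_equal(hom$ci_high - hom$ci_low, 0)
  # iid normal draws: equal-tailed endpoints match the analytic quantiles
  set.seed(12)
  n <- 20000
  iid <- tibble::tibble(
    iteration = 1:n, age_homer = rnorm(n, 2800, 200),
    age_hittite = 3400, age_root = 9000, log_posterior = 0
  )
  s2 <- summarize_posterior(iid, reference_year = 2000)
  hom2 <- s2[s2$parameter == "age_homer", ]
  expect_equal(hom2$ci_low, qnorm(0.025, 2800, 200), tolerance = 15)
  expect_equal(hom2$ci_high, qnorm(0.975, 2800, 200), tolerance = 15)
  rev_s <- summarize_posterior(iid[n:1, ], reference_year = 2000)
  expect_equal(rev_s$mean, s2$mean)
  expect_equal(rev_s$ci_low, s2$ci_low)
  # shifting the reference year shifts BCE dates only
  s3 <- summarize_posterior(iid, reference_year = 2100)
  expect_equal(s3$mean, s2$mean)
  expect_equal(s3$mean_date_bce, s2$mean_date_bce - 100)
  expect_error(summarize_posterior(iid[1:50, ]),
               class = "lexidate_validation_error")
  # HPD of a symmetric unimodal sample is close to equal-tailed
  s4 <- summarize_posterior(iid, reference_year = 2000, interval = "hpd")
  expect_equal(s4$ci_low[1], hom2$ci_low, tolerance = 40)
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(9)
  n <- 20000
  white <- rnorm(n)
  expect_gt(ess(white), 0.8 * n)
  expect_lte(ess(white), n)
  expect_equal(ess(rep(3.2, 500)), 1)
  # AR(1) with coefficient 0.9: ESS/n -> (1 - 0.9) / (1 + 0.9)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  expect_equal(ess(ar) / n, 0.1 / 1.9, tolerance = 0.3)
  expect_error(ess(rnorm(50)), class = "lexidate_validation_error")
})

test_that("tidy, glance and autoplot expose the chain in standard forms", {
  tab <- filter_usable(reference_cognacy_table(seed = 1))
  ch <- suppressWarnings(
    run_mcmc(tab, prior_config(), mcmc_settings(n_iterations = 20000, seed = 2))
  )
  td <- tidy(ch)
  expect_equal(td$term, c("age_homer", "age_hittite", "age_root"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(ch)
  expect_equal(gl$n_retained, nrow(ch))
  expect_gt(gl$ess_min, 100)
  p <- autoplot(ch)
  expect_s3_class(p, "ggplot")
})
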
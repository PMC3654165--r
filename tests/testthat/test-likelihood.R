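test_that("retention probability honours half-life and unit conventions", {
  expect_equal(retention_probability(2.5, 0), 1.0)
  hl <- 2500
  r_half <- 1e4 * log(2) / hl
  expect_equal(retention_probability(r_half, hl), 0.5, tolerance = 1e-12)
  expect_equal(retention_probability(1.0, 1e4), exp(-1), tolerance = 1e-12)
  expect_error(retention_probability(-1, 100), class = "lexidate_domain_error")
  expect_error(retention_probability(1, -100), class = "lexidate_domain_error")
})

test_that("retention probability decreases strictly in rate and time", {
  rates <- seq(0.1, 10, length.out = 40)
  times <- seq(0, 2e4, length.out = 40)
  expect_true(all(diff(retention_probability(rates, 3000)) < 0))
  p_t <- retention_probability(2, times)
  expect_true(all(diff(p_t) < 0))
  expect_true(all(p_t > 0 & p_t <= 1))
})

test_that("path times follow the bracketing geometry and are additive", {
  pt <- path_times(tree_ages(2700, 3400, 9000))
  expect_equal(pt$t_om, 2700)
  expect_equal(pt$t_hh, 11900)
  expect_equal(pt$t_hm, 14600)
  expect_equal(path_times(tree_ages(0, 3400, 9000))$t_om, 0)
  set.seed(31)
  for (i in 1:20) {
    root <- runif(1, 5000, 15000)
    ages <- tree_ages(runif(1, 0, root * 0.99), runif(1, 1, root * 0.99), root)
    pt <- path_times(ages)
    expect_equal(pt$t_hm, pt$t_hh + pt$t_om, tolerance = 1e-9)
  }
  expect_error(tree_ages(9500, 3400, 9000), class = "lexidate_domain_error")
  expect_error(tree_ages(2700, -1, 9000), class = "lexidate_domain_error")
})

test_that("sister-lineage convention lengthens only the Homer-Modern path", {
  ages <- tree_ages(2700, 3400, 9000)
  anc <- path_times(ages)
  sis <- path_times(ages, split_age = 3000)
  expect_equal(sis$t_om, 2 * 3000 - 2700)
  expect_equal(sis$t_hh, anc$t_hh)
  expect_equal(sis$t_hm, anc$t_hm)
  # coincident split reduces to the ancestor convention
  expect_equal(path_times(ages, split_age = 2700), anc)
  expect_error(path_times(ages, split_age = 2000),
               class = "lexidate_domain_error")
})

test_that("pair log-likelihood matches closed forms and the brute-force oracle", {
  one <- tibble::tibble(rate = 1, cognate = 1)
  expect_equal(as.numeric(pair_loglik(one, 1e4)), -1.0, tolerance = 1e-12)
  allcog <- tibble::tibble(rate = c(1, 2, 3), cognate = 1)
  expect_equal(as.numeric(pair_loglik(allcog, 0)), 0)
  expect_warning(
    ll0 <- pair_loglik(tibble::tibble(rate = 1, cognate = 0), 0),
    "probability-zero"
  )
  expect_identical(as.numeric(ll0), -Inf)
  expect_equal(attr(pair_loglik(allcog, 100), "n_terms"), 3L)
  for (seed in 1:25) {
    d <- random_pair_data(20, seed)
    for (t in c(500, 2700, 8000, 20000)) {
      expect_equal(as.numeric(pair_loglik(d, t)),
                   brute_force_pair_loglik(d, t), tolerance = 1e-10)
    }
  }
})

test_that("pair log-likelihood is unimodal in separation time", {
  for (seed in c(3, 14)) {
    d <- random_pair_data(40, seed)
    grid <- seq(100, 3e4, length.out = 300)
    ll <- vapply(grid, function(t) as.numeric(pair_loglik(d, t)), numeric(1))
    signs <- sign(diff(ll))
    # once the surface starts decreasing it never increases again
    expect_lte(sum(diff(signs[signs != 0]) != 0), 1)
  }
})

test_that("composite likelihood decomposes over pairs and ignores row order", {
  tab <- random_cognacy_table(60, seed = 8)
  ages <- tree_ages(2000, 3500, 9000)
  pt <- path_times(ages)
  manual <- as.numeric(pair_loglik(tibble::tibble(rate = tab$rate, cognate = tab$hittite_homer), pt$t_hh)) +
    as.numeric(pair_loglik(tibble::tibble(rate = tab$rate, cognate = tab$hittite_modern), pt$t_hm)) +
    as.numeric(pair_loglik(tibble::tibble(rate = tab$rate, cognate = tab$homer_modern), pt$t_om))
  expect_equal(as.numeric(total_loglik(tab, ages)), manual, tolerance = 1e-12)
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(as.numeric(total_loglik(shuffled, ages)),
               as.numeric(total_loglik(tab, ages)), tolerance = 1e-12)
  expect_error(total_loglik(dplyr::mutate(tab, rate = NA_real_), ages),
               class = "lexidate_validation_error")
})

test_that("pairwise MLE recovers the single-rate closed form", {
  r <- 2.0
  d <- tibble::tibble(rate = r, cognate = rep(c(1, 0), c(6, 4)))
  fit <- pair_mle(d, lower = 10, upper = 4e4)
  expect_equal(fit$t_hat, -(1e4 / r) * log(0.6), tolerance = 1e-4)
  expect_true(fit$ci_low < fit$t_hat && fit$t_hat < fit$ci_high)
  # all-cognate data: monotone likelihood, boundary optimum flagged
  expect_warning(
    flat <- pair_mle(tibble::tibble(rate = 1, cognate = rep(1, 5)),
                     lower = 100, upper = 1e4),
    "boundary"
  )
  expect_true(flat$at_boundary)
  expect_lt(flat$t_hat, 200)
})

test_that("optimizer agrees with a dense grid for heterogeneous rates", {
  for (seed in c(2, 9)) {
    d <- random_pair_data(50, seed)
    grid <- seq(100, 3e4, length.out = 200)
    ll <- vapply(grid, function(t) as.numeric(pair_loglik(d, t)), numeric(1))
    step <- grid[2] - grid[1]
    fit <- pair_mle(d, lower = 100, upper = 3e4)
    expect_lt(abs(fit$t_hat - grid[which.max(ll)]), step + 1e-6)
  }
})

test_that("adding words moves the MLE in the expected direction", {
  set.seed(55)
  for (i in 1:8) {
    d <- random_pair_data(15, seed = 200 + i)
    if (sum(d$cognate) %in% c(0, nrow(d))) next
    base <- pair_mle(d)$t_hat
    new_rate <- stats::rlnorm(1, 0.5, 0.7)
    with_cog <- dplyr::bind_rows(d, tibble::tibble(rate = new_rate, cognate = 1))
    with_non <- dplyr::bind_rows(d, tibble::tibble(rate = new_rate, cognate = 0))
    expect_lte(pair_mle(with_cog)$t_hat, base + 1)
    expect_gte(pair_mle(with_non)$t_hat, base - 1)
  }
})

test_that("likelihood grid and Newick export are consistent with the ages", {
  tab <- random_cognacy_table(40, seed = 4)
  g <- loglik_grid(tab, c(1000, 2000, 3000), 3400, 9000)
  expect_equal(nrow(g), 3)
  expect_equal(g$loglik[2],
               as.numeric(total_loglik(tab, tree_ages(2000, 3400, 9000))))
  nwk <- dated_tree_newick(tree_ages(2700, 3400, 9000))
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("Homeric_Greek", "Modern_Greek", "Hittite"))
  # Hittite tip depth = root age - hittite age; Modern tip depth = root age
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  names(depths) <- tr$tip.label
  expect_equal(unname(depths["Hittite"]), 9000 - 3400)
  expect_equal(unname(depths["Modern_Greek"]), 9000)
})
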
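#' Probability that a word is retained (still cognate) after a given time
#'
#' Lexical replacement is modeled as a memoryless process: a word with
#' replacement rate `r` (expected replacements per 10,000 years) survives a
#' path of `t` years unreplaced with probability `exp(-r * t / 10000)`. This
#' is the unique form consistent with a constant linguistic half-life
#' `hl = 10000 * log(2) / r`; typical basic-vocabulary words have half-lives
#' of 2,000-3,000 years. The 10,000-year unit conversion is applied here and
#' nowhere else.
#'
#' @param rate Replacement rate(s), replacements per 10,000 years; positive.
#' @param path_time Separation time(s) in years along the tree path; >= 0.
#' @return Retention probability in `(0, 1]`, vectorised over both arguments.
#' @examples
#' retention_probability(2.7726, 2500) # one half-life
#' @export
retention_probability <- function(rate, path_time) {
  if (any(rate <= 0) || any(path_time < 0)) {
    abort("rate must be > 0 and path_time >= 0",
          class = "lexidate_domain_error")
  }
  exp(-rate * path_time / 1e4)
}

#' Log-likelihood of one pairwise cognacy comparison
#'
#' For a set of words compared between two languages separated by `path_time`
#' years, each cognate word contributes `log(retention_probability)` and each
#' non-cognate word the log of its complement. Accumulation is entirely in
#' log space.
#'
#' @param pair_data A data frame with columns `rate` (replacements per 10,000
#'   years) and `cognate` (1/0 or logical), one row per word.
#' @param path_time Separation time in years, `>= 0`.
#' @return The log-likelihood (natural log), with attribute `n_terms` giving
#'   the number of words. `path_time = 0` with at least one non-cognate word
#'   is a probability-zero configuration and returns `-Inf` with a warning.
#' @examples
#' d <- tibble::tibble(rate = c(1, 2), cognate = c(1, 0))
#' pair_loglik(d, 5000)
#' @export
pair_loglik <- function(pair_data, path_time) {
  stopifnot(is.data.frame(pair_data), all(c("rate", "cognate") %in% names(pair_data)))
  if (length(path_time) != 1 || !is.finite(path_time) || path_time < 0) {
    abort("path_time must be a single finite non-negative number",
          class = "lexidate_domain_error")
  }
  rate <- pair_data$rate
  cog <- as.logical(pair_data$cognate)
  if (any(is.na(rate)) || any(rate <= 0) || any(is.na(cog))) {
    abort("every word needs a positive rate and a 0/1 cognacy judgment",
          class = "lexidate_domain_error")
  }
  x <- rate * path_time / 1e4
  ll_cog <- -sum(x[cog])
  # log(1 - exp(-x)) via expm1 for numerical stability at small x
  xr <- x[!cog]
  if (any(xr == 0)) {
    warn("path_time = 0 with non-cognate words: probability-zero configuration")
    ll_non <- -Inf
  } else {
    ll_non <- sum(log(-expm1(-xr)))
  }
  structure(ll_cog + ll_non, n_terms = length(rate))
}

pair_frames <- function(table) {
  lapply(setNames(pair_levels, pair_levels), function(p) {
    tibble::tibble(rate = table$rate, cognate = table[[p]])
  })
}

#' Composite log-likelihood over the three language pairs
#'
#' The overall likelihood is the product of the three pairwise comparisons
#' (Hittite-Homer, Hittite-Modern, Homer-Modern), each evaluated at the path
#' time implied by the node ages; here computed as the sum of the three
#' pairwise log-likelihoods. The pairwise comparisons share words, so this is
#' a composite likelihood, used exactly as such.
#'
#' @param table A filtered cognacy tibble (all judgments present, rates > 0).
#' @param ages A [tree_ages()] object.
#' @param split_age Optional sister-lineage divergence age; see [path_times()].
#' @return Composite log-likelihood with attribute `n_terms` (total word-pair
#'   terms, 3x the word count).
#' @examples
#' tab <- filter_usable(reference_cognacy_table(seed = 1))
#' total_loglik(tab, tree_ages(2700, 3400, 9000))
#' @export
total_loglik <- function(table, ages, split_age = NULL) {
  if (any(!usable_rows(table))) {
    abort("table contains incomplete records; run filter_usable() first",
          class = "lexidate_validation_error")
  }
  pt <- path_times(ages, split_age = split_age)
  frames <- pair_frames(table)
  ll <- pair_loglik(frames$hittite_homer, pt$t_hh) +
    pair_loglik(frames$hittite_modern, pt$t_hm) +
    pair_loglik(frames$homer_modern, pt$t_om)
  structure(as.numeric(ll), n_terms = 3L * nrow(table))
}

#' Maximum-likelihood separation time for one pair
#'
#' Diagnostic point estimate: maximizes [pair_loglik()] over `path_time` by
#' bounded one-dimensional optimization and attaches the profile-likelihood
#' interval at 1.92 log units below the maximum (the chi-squared 95% cutoff).
#' The full analysis is Bayesian; this is a per-pair sanity check. When every
#' word shares one cognacy class the likelihood is monotone and the optimum
#' sits on a search boundary, which is reported with a warning.
#'
#' @param pair_data A data frame with columns `rate` and `cognate`.
#' @param lower,upper Search bounds on the separation time, years.
#' @param tol Convergence tolerance passed to [stats::optimize()].
#' @return A one-row tibble: `t_hat`, `loglik`, `ci_low`, `ci_high`,
#'   `at_boundary`.
#' @examples
#' d <- tibble::tibble(rate = rep(2, 10), cognate = rep(c(1, 0), 5))
#' pair_mle(d) # closed form: -(10000/2) * log(0.5)
#' @export
pair_mle <- function(pair_data, lower = 1, upper = 5e4, tol = 1e-6) {
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper <= lower) {
    abort("search bounds must be finite, positive and ordered",
          class = "lexidate_domain_error")
  }
  f <- function(t) as.numeric(pair_loglik(pair_data, t))
  opt <- optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
  t_hat <- opt$maximum
  ll_max <- opt$objective
  span <- upper - lower
  at_boundary <- t_hat - lower < 1e-4 * span || upper - t_hat < 1e-4 * span
  if (at_boundary) {
    warn("likelihood is monotone over the search bounds; estimate at boundary")
  }
  drop_f <- function(t) f(t) - (ll_max - 1.92)
  ci_low <- if (drop_f(lower) < 0 && !at_boundary) {
    uniroot(drop_f, c(lower, t_hat), tol = tol)$root
  } else {
    lower
  }
  ci_high <- if (drop_f(upper) < 0 && !at_boundary) {
    uniroot(drop_f, c(t_hat, upper), tol = tol)$root
  } else {
    upper
  }
  tibble::tibble(
    t_hat = t_hat, loglik = ll_max,
    ci_low = ci_low, ci_high = ci_high, at_boundary = at_boundary
  )
}

#' Log-likelihood surface over the Homeric age
#'
#' Evaluates the composite log-likelihood on a grid of Homeric ages with the
#' Hittite and root ages held fixed; convenient for plotting the surface or
#' exporting it as TSV.
#'
#' @param table A filtered cognacy tibble.
#' @param ages_grid Numeric vector of candidate Homeric ages, years BP.
#' @param age_hittite,age_root Fixed ages for the other two nodes, years BP.
#' @return A tibble with columns `age_homer` and `loglik`.
#' @export
loglik_grid <- function(table, ages_grid, age_hittite, age_root) {
  tibble::tibble(
    age_homer = ages_grid,
    loglik = purrr::map_dbl(
      ages_grid,
      function(a) as.numeric(total_loglik(table, tree_ages(a, age_hittite, age_root)))
    )
  )
}
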
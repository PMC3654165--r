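# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# A small cognacy tibble with arbitrary judgments and rates.
random_pair_data <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    rate = stats::rlnorm(n, 0.5, 0.7),
    cognate = stats::rbinom(n, 1, 0.5)
  )
}

random_cognacy_table <- function(n, seed) {
  set.seed(seed)
  tab <- tibble::tibble(
    meaning = sprintf("w%03d", seq_len(n)),
    rate = stats::rlnorm(n, 0.5, 0.7),
    hittite_homer = stats::rbinom(n, 1, 0.25),
    hittite_modern = stats::rbinom(n, 1, 0.15),
    homer_modern = stats::rbinom(n, 1, 0.5)
  )
  filter_usable(tab)
}

# Brute-force pairwise likelihood: multiply per-word probabilities directly
# (raw space), then log - deliberately a different accumulation path from
# pair_loglik's log-space sum.
brute_force_pair_loglik <- function(pair_data, path_time) {
  p <- exp(-pair_data$rate * path_time / 1e4)
  log(prod(ifelse(pair_data$cognate == 1, p, 1 - p)))
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments;
# feasible only for tiny samples.
enumerated_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  obs <- sum(rank(pooled)[seq_len(m)])
  combos <- utils::combn(n, m)
  stats_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- m * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# Monte-Carlo standard error of a posterior mean from the ESS.
mcse_mean <- function(x) stats::sd(x) / sqrt(ess(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
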
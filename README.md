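# lexidate

Bayesian dating of language divergence from lexical replacement, built
around one concrete question: **how old are the Homeric epics?**

Languages shed vocabulary the way genomes shed sequence identity. For a
meaning with replacement rate *r* (expected replacements per 10,000 years),
two languages separated by a total path of *t* years are still *cognate* for
that meaning — their words descend from the same ancestral word — with
probability

```
p(t) = exp(-r t / 10^4)
```

Given binary cognacy judgments on Swadesh-list meanings for the three pairs
among **Hittite**, **Homeric Greek** and **Modern Greek**, plus per-meaning
rates, the pairwise log-likelihood of a separation time *t* is

```
l(t | D) = sum_{cognate} log p_k(t) + sum_{non-cognate} log(1 - p_k(t))
```

and the three pairs combine as a composite likelihood on a fixed tree in
which Hittite is the Anatolian outgroup and Homeric Greek sits as a sampled
ancestor on the Modern Greek lineage, bracketed in time between the two.
A Metropolis–Hastings sampler then draws the three node ages (Homeric tip,
Hittite tip, Indo-European root) under historical calibration priors and
reports the posterior of Homer's age as calendar dates BCE.

The package is tidyverse-native: cognacy tables are tibbles, every
user-facing function takes a data frame first and pipes, fitted chains have
`tidy()`, `glance()` and `autoplot()` methods.

## What's in the box

| Area | Functions |
| --- | --- |
| Cognacy data | `read_cognacy_table()`, `write_cognacy_table()`, `filter_usable()`, `summarize_pairs()`, `compare_rate_classes()` |
| Likelihood | `retention_probability()`, `path_times()`, `pair_loglik()`, `total_loglik()`, `pair_mle()`, `loglik_grid()` |
| Bayesian dating | `prior_config()`, `prior_flat()` / `prior_uniform()` / `prior_normal()`, `mcmc_settings()`, `run_mcmc()`, `summarize_posterior()`, `ess()` |
| Simulation & validation | `rate_distribution_spec()`, `draw_rates()`, `simulate_cognacy()`, `reference_cognacy_table()`, `recovery_experiment()` |
| Output | `autoplot()` (posterior histogram), `plot_likelihood_surface()`, `dated_tree_newick()` |

A thin command-line front end with `summarize`, `date`, `simulate` and
`recover` subcommands ships at `inst/scripts/lexidate`
(`system.file("scripts", "lexidate", package = "lexidate")`).

## Worked example

`reference_cognacy_table()` builds a 173-meaning table whose pairwise
cognate counts match the published Hittite/Homeric/Modern comparison
exactly, with replacement rates reconstructed class-conditionally from the
published descriptive statistics (the true per-word rates are external
data; see the vignette for what that reconstruction can and cannot honour).

```r
library(lexidate)

tab <- filter_usable(reference_cognacy_table(seed = 1))
summarize_pairs(tab)
#> # A tibble: 3 × 10
#>   pair           n_cognate n_noncognate pct_cognate rate_mean_cognate rate_sd_cognate rate_mean_noncognate rate_sd_noncognate  p_value test
#> 1 hittite_homer         33          140        19.1              1.62           0.888                 3.34               2.22 2.26e- 3 ranksum
#> 2 hittite_modern        23          150        13.3              1.38           0.725                 3.26               2.18 2.97e- 3 ranksum
#> 3 homer_modern          87           86        50.3              1.26           1.39                  4.78               1.03 4.62e-24 ranksum
```

Reading the rows: Hittite and Modern Greek share the fewest cognates
(13.3%), Hittite–Homeric 19.1%, Homeric–Modern 50.3%, and on every pair the
words that stayed cognate have slower replacement rates than those that
changed — the signal the dating method feeds on.

Dating with the informative prior on Homer's age (normal, centred 800 BCE,
SD 200 years) and the default calibrations (Hittite uniform 3,200–3,600 BP;
root normal 8,700 ± 550 BP):

```r
ch <- run_mcmc(tab, prior_config(homer = prior_normal(2800, 200)),
               mcmc_settings(seed = 42))
summarize_posterior(ch)
#> # A tibble: 3 × 9
#>   parameter    mean ci_low ci_high mean_date_bce ci_low_bce ci_high_bce    ess acceptance_rate
#> 1 age_homer   2942.  2605.   3280.          942.       605.       1280. 17136.           0.267
#> 2 age_hittite 3415.  3212.   3592.         1415.      1212.       1592. 15642.           0.269
#> 3 age_root    8073.  7382.   8795.         6073.      5382.       6795. 15866.           0.266
```

The posterior mean date for the Homeric epics in this run is **942 BCE**
with a 95% credible interval of **605–1280 BCE** — inside the published
uncertainty for the informative reanalysis, if older than the published
point estimate, a gap the vignette traces to the reconstructed (rather
than true per-word) replacement rates. `autoplot(ch)` draws the posterior
histogram on the BCE scale; `tidy(ch)` and `glance(ch)` give broom-style
summaries.

Validation runs entirely from the generative side of the model — Poisson
replacement events on the branches of the same tree:

```r
rec <- recovery_experiment(simulation_config(n_words = 173, seed = 11),
                           prior_config(),
                           mcmc_settings(n_iterations = 40000,
                                         burn_in_fraction = 0.2,
                                         thin = 5, seed = 0),
                           n_replicates = 50)
glance(rec)   # coverage of the 95% interval, bias, MAE against truth
```

## Vignette

`vignettes/dating-by-lexical-replacement.Rmd` documents the model and its
assumptions, the tree conventions, the prior defaults and why, the sampler
and its diagnostics, what the simulator does and does not emulate, the
reconstruction of the reference rate set (including an internal-consistency
analysis of the published descriptive statistics), and known limitations.
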
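#' Read a cognacy table
#'
#' Reads a delimited text file of per-meaning cognacy judgments and lexical
#' replacement rates into a tibble. The expected columns are `meaning` (a
#' Swadesh-style gloss), `rate` (expected replacements per 10,000 years) and
#' one binary column per language pair: `hittite_homer`, `hittite_modern`,
#' `homer_modern`, coded `1` (cognate), `0` (non-cognate) or `NA` (missing or
#' unjudgeable).
#'
#' Missing cells are preserved; no filtering happens here (see
#' [filter_usable()]). The returned tibble carries attributes `n_total` and
#' `n_usable` so that a pipeline can report how many meanings survive the
#' completeness filter.
#'
#' @param path Path to a TSV (default) or CSV file with the header above.
#' @param delim Field delimiter; `"\t"` by default, use `","` for CSV.
#' @return A `cognacy_tbl` tibble with columns `meaning`, `rate`,
#'   `hittite_homer`, `hittite_modern`, `homer_modern`.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' write_cognacy_table(simulate_cognacy(simulation_config(n_words = 20, seed = 1)), path)
#' tab <- read_cognacy_table(path)
#' attr(tab, "n_total")
#' @export
read_cognacy_table <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(paste0("cognacy file not found: ", path), class = "lexidate_io_error")
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(
      meaning = readr::col_character(),
      rate = readr::col_double(),
      .default = readr::col_character()
    ),
    na = c("NA", ""),
    progress = FALSE,
    show_col_types = FALSE
  )
  needed <- c("meaning", "rate", pair_levels)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cognacy file lacks required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "lexidate_validation_error"
    )
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(
      paste0("malformed cognacy file at line ", probs$row[1] + 1L, ": ",
             probs$expected[1], " expected, saw '", probs$actual[1], "'"),
      class = "lexidate_parse_error"
    )
  }
  parse_judgment <- function(x, col) {
    bad <- !is.na(x) & !x %in% c("0", "1")
    if (any(bad)) {
      abort(
        paste0("unknown cognacy token '", x[which(bad)[1]], "' in column ",
               col, " (row ", which(bad)[1], "); expected 1, 0 or NA"),
        class = "lexidate_validation_error"
      )
    }
    as.integer(x)
  }
  out <- raw[needed]
  for (p in pair_levels) out[[p]] <- parse_judgment(out[[p]], p)
  new_cognacy_tbl(out)
}

#' Write a cognacy table
#'
#' Inverse of [read_cognacy_table()]; judgments are written as `1`/`0`/`NA`.
#'
#' @param table A cognacy tibble.
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_cognacy_table <- function(table, path, delim = "\t") {
  readr::write_delim(
    table[c("meaning", "rate", pair_levels)],
    path, delim = delim, na = "NA"
  )
  invisible(path)
}

new_cognacy_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "n_total") <- nrow(x)
  attr(x, "n_usable") <- sum(usable_rows(x))
  class(x) <- c("cognacy_tbl", class(x))
  x
}

usable_rows <- function(table) {
  !is.na(table$rate) & table$rate > 0 &
    !is.na(table$hittite_homer) &
    !is.na(table$hittite_modern) &
    !is.na(table$homer_modern)
}

#' Keep only meanings usable by the composite likelihood
#'
#' A meaning is usable when all three pairwise cognacy judgments are present
#' and its replacement rate is present and positive: the composite likelihood
#' multiplies over all three pairwise comparisons, so a meaning missing any of
#' them contributes nothing identifiable. In the Homeric analysis this filter
#' takes the 200 Swadesh meanings down to the 173 with complete information.
#'
#' @param table A cognacy tibble as returned by [read_cognacy_table()] or
#'   [simulate_cognacy()].
#' @return The filtered `cognacy_tbl`; `attr(, "n_total")` preserves the
#'   pre-filter row count.
#' @export
filter_usable <- function(table) {
  keep <- usable_rows(table)
  out <- tibble::as_tibble(table)[keep, , drop = FALSE]
  attr(out, "n_total") <- nrow(table)
  attr(out, "n_usable") <- nrow(out)
  class(out) <- c("cognacy_tbl", class(tibble::tibble()))
  out
}

#' Descriptive summary of one language pair
#'
#' Counts cognate and non-cognate meanings for one pair, the percent cognate,
#' the class-conditional mean and SD of the replacement rates, and a two-sided
#' p-value for the rate contrast between the classes (cognate words are
#' expected to be slow words). Operates on a complete (filtered) table.
#'
#' @param table A filtered cognacy tibble (see [filter_usable()]).
#' @param pair_name One of `"hittite_homer"`, `"hittite_modern"`,
#'   `"homer_modern"`.
#' @param test `"ranksum"` (default, Wilcoxon rank-sum; rates are strongly
#'   right-skewed) or `"welch"` (unequal-variance t-test on means).
#' @return A one-row tibble with columns `pair`, `n_cognate`, `n_noncognate`,
#'   `pct_cognate`, `rate_mean_cognate`, `rate_sd_cognate`,
#'   `rate_mean_noncognate`, `rate_sd_noncognate`, `p_value`, `test`.
#'   `pct_cognate` is unrounded; display rounding is the caller's concern.
#' @export
summarize_pair <- function(table, pair_name, test = c("ranksum", "welch")) {
  test <- match.arg(test)
  pair_name <- match.arg(pair_name, pair_levels)
  if (nrow(table) == 0) {
    abort("cannot summarize an empty cognacy table",
          class = "lexidate_validation_error")
  }
  if (any(!usable_rows(table))) {
    abort("table contains incomplete records; run filter_usable() first",
          class = "lexidate_validation_error")
  }
  is_cog <- table[[pair_name]] == 1L
  rc <- table$rate[is_cog]
  rn <- table$rate[!is_cog]
  p <- if (length(rc) >= 2 && length(rn) >= 2) {
    compare_rate_classes(rc, rn, method = test)
  } else {
    NA_real_
  }
  tibble::tibble(
    pair = pair_name,
    n_cognate = sum(is_cog),
    n_noncognate = sum(!is_cog),
    pct_cognate = 100 * mean(is_cog),
    rate_mean_cognate = mean(rc),
    rate_sd_cognate = if (length(rc) >= 2) sd(rc) else NA_real_,
    rate_mean_noncognate = mean(rn),
    rate_sd_noncognate = if (length(rn) >= 2) sd(rn) else NA_real_,
    p_value = p,
    test = test
  )
}

#' Descriptive summary of all three language pairs
#'
#' Applies [summarize_pair()] to each pair and stacks the rows, reproducing
#' the standard descriptive table for the Hittite / Homeric / Modern Greek
#' comparison: cognate counts, percent cognate, and the class-conditional
#' replacement-rate contrast.
#'
#' @inheritParams summarize_pair
#' @return A three-row tibble, one row per pair, in the order Hittite-Homer,
#'   Hittite-Modern, Homer-Modern.
#' @examples
#' tab <- filter_usable(reference_cognacy_table(seed = 1))
#' summarize_pairs(tab)
#' @export
summarize_pairs <- function(table, test = c("ranksum", "welch")) {
  test <- match.arg(test)
  purrr::map_dfr(pair_levels, function(p) summarize_pair(table, p, test = test))
}

#' Two-sided test of a rate difference between cognate classes
#'
#' Tests whether the replacement rates of cognate words differ in location
#' from those of non-cognate words. The default is the Wilcoxon rank-sum test
#' because replacement rates are strongly right-skewed; a Welch
#' unequal-variance t-test on the means is available as an alternative.
#'
#' @param rates_cognate,rates_noncognate Numeric vectors of positive rates.
#' @param method `"ranksum"` or `"welch"`.
#' @return The two-sided p-value. Two identical constant samples give 1 with
#'   a warning (no information about a difference).
#' @export
compare_rate_classes <- function(rates_cognate, rates_noncognate,
                                 method = c("ranksum", "welch")) {
  method <- match.arg(method)
  if (length(rates_cognate) == 0 || length(rates_noncognate) == 0) {
    abort("both rate classes must be non-empty",
          class = "lexidate_validation_error")
  }
  pooled <- c(rates_cognate, rates_noncognate)
  if (length(unique(pooled)) == 1L) {
    warn("all rates identical across classes; p-value is 1")
    return(1)
  }
  p <- if (method == "ranksum") {
    stats::wilcox.test(rates_cognate, rates_noncognate, exact = FALSE)$p.value
  } else {
    stats::t.test(rates_cognate, rates_noncognate, var.equal = FALSE)$p.value
  }
  unname(p)
}

#' @export
print.cognacy_tbl <- function(x, ...) {
  cat(sprintf("# Cognacy table: %d meanings (%d usable)\n",
              attr(x, "n_total") %||% nrow(x),
              attr(x, "n_usable") %||% sum(usable_rows(x))))
  NextMethod()
}
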
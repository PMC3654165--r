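#' Node ages on the fixed three-language tree
#'
#' The analysis works on a fixed topology: the Indo-European root splits into
#' the Anatolian lineage leading to the Hittite tip and the lineage leading
#' through Homeric Greek to Modern Greek. Homeric Greek is modeled by default
#' as a sampled direct ancestor of Modern Greek (a zero-length side branch on
#' that lineage). All ages are in years before present; Modern Greek is the
#' present, fixed at age 0.
#'
#' @param age_homer Age of the Homeric tip, years BP; the quantity of interest.
#' @param age_hittite Age of the Hittite tip, years BP.
#' @param age_root Age of the Indo-European root, years BP.
#' @return A `tree_ages` list with the three ages plus `age_modern = 0`.
#' @examples
#' tree_ages(2700, 3400, 9000)
#' @export
tree_ages <- function(age_homer, age_hittite, age_root) {
  x <- list(
    age_homer = as.numeric(age_homer),
    age_hittite = as.numeric(age_hittite),
    age_root = as.numeric(age_root),
    age_modern = 0
  )
  if (!ages_valid(x)) {
    abort(paste0(
      "invalid tree ages: need 0 <= age_homer < age_root and ",
      "0 < age_hittite < age_root (got homer=", x$age_homer,
      ", hittite=", x$age_hittite, ", root=", x$age_root, ")"
    ), class = "lexidate_domain_error")
  }
  structure(x, class = "tree_ages")
}

ages_valid <- function(x) {
  is.finite(x$age_homer) && is.finite(x$age_hittite) && is.finite(x$age_root) &&
    x$age_homer >= 0 && x$age_homer < x$age_root &&
    x$age_hittite > 0 && x$age_hittite < x$age_root
}

#' @export
print.tree_ages <- function(x, ...) {
  cat(sprintf(
    "Tree ages (years BP): Homer %.0f | Hittite %.0f | IE root %.0f\n",
    x$age_homer, x$age_hittite, x$age_root
  ))
  invisible(x)
}

#' Pairwise separation times implied by node ages
#'
#' Converts node ages into the total path duration separating each pair of
#' sampled languages - the time the per-word replacement clock runs along the
#' tree path connecting them (summing both descending lineages through the
#' root where applicable).
#'
#' Under the default sampled-ancestor convention, Homeric Greek lies on the
#' Modern Greek lineage, so `t_om = age_homer`,
#' `t_hh = (age_root - age_hittite) + (age_root - age_homer)` and
#' `t_hm = (age_root - age_hittite) + age_root`; these satisfy the path
#' additivity identity `t_hm = t_hh + t_om`. If `split_age` is supplied,
#' Homeric Greek is instead a sister tip diverging from the Modern lineage at
#' `split_age` years BP, which lengthens the Homer-Modern path to
#' `2 * split_age - age_homer` (additivity no longer holds).
#'
#' @param ages A [tree_ages()] object.
#' @param split_age Optional Greek divergence age (years BP) for the
#'   sister-lineage convention; must satisfy
#'   `age_homer <= split_age <= age_root`. `NULL` (default) selects the
#'   sampled-ancestor convention.
#' @return A one-row tibble with columns `t_hh`, `t_hm`, `t_om` (years).
#' @examples
#' path_times(tree_ages(2700, 3400, 9000))
#' @export
path_times <- function(ages, split_age = NULL) {
  if (!inherits(ages, "tree_ages")) ages <- do.call(tree_ages, as.list(ages)[1:3])
  t_om <- if (is.null(split_age)) {
    ages$age_homer
  } else {
    if (split_age < ages$age_homer || split_age > ages$age_root) {
      abort("split_age must lie between age_homer and age_root",
            class = "lexidate_domain_error")
    }
    2 * split_age - ages$age_homer
  }
  split <- split_age %||% ages$age_homer
  tibble::tibble(
    t_hh = (ages$age_root - ages$age_hittite) +
      (ages$age_root - split) + (split - ages$age_homer),
    t_hm = (ages$age_root - ages$age_hittite) + ages$age_root,
    t_om = t_om
  )
}

#' Export the dated tree in Newick format
#'
#' Writes the fixed three-taxon tree with branch lengths in years implied by
#' the node ages, with Homeric Greek as a zero-length sampled-ancestor side
#' branch: `((Homeric:0, Modern:age_homer)...)`. Useful for plotting with ape
#' or FigTree.
#'
#' @param ages A [tree_ages()] object.
#' @param path Optional file to write to; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly if written to a file).
#' @export
dated_tree_newick <- function(ages, path = NULL) {
  if (!inherits(ages, "tree_ages")) ages <- do.call(tree_ages, as.list(ages)[1:3])
  nwk <- sprintf(
    "((Homeric_Greek:0,Modern_Greek:%g)Greek_ancestor:%g,Hittite:%g)Indo_European;",
    ages$age_homer,
    ages$age_root - ages$age_homer,
    ages$age_root - ages$age_hittite
  )
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
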
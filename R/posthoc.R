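# Post-hoc analyses of fitted species-level sensitivities: phylogenetic
# signal (Blomberg's K over a set of bootstrap trees) and the
# nocturnal-versus-diurnal comparison.

#' Blomberg's K for a set of tip values on a phylogeny
#'
#' The ratio of the observed mean squared error structure to its Brownian
#' expectation computed from the phylogenetic variance-covariance matrix;
#' K is about 1 when trait values evolved by Brownian motion along the tree
#' and well below 1 when they are independent of phylogeny. Computation
#' delegates to [picante::Kcalc()]; this wrapper enforces the tip/value
#' matching contract.
#'
#' @param values named numeric, one value per tree tip.
#' @param tree an [ape::phylo] with positive branch lengths.
#' @return K (scalar).
#' @export
blombergs_k <- function(values, tree) {
  if (is.null(names(values))) stop("values must be named by species")
  unmatched <- c(setdiff(names(values), tree$tip.label),
                 setdiff(tree$tip.label, names(values)))
  if (length(unmatched)) {
    stop("tips and values do not match: ",
         paste(unique(unmatched), collapse = ", "))
  }
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("tree must have positive branch lengths")
  }
  as.numeric(picante::Kcalc(values[tree$tip.label], tree, checkdata = FALSE))
}

#' Blomberg's K over a set of bootstrap trees
#'
#' One K per tree (same tip values throughout), summarized by median and
#' range — the uncertainty in K attributable to phylogenetic uncertainty.
#'
#' @param values named numeric per species.
#' @param trees list of [ape::phylo] (or an `ape::multiPhylo`).
#' @return list with `k` (vector, one per tree), `median`, `range`.
#' @export
k_over_tree_set <- function(values, trees) {
  if (length(trees) == 0) stop("empty tree set")
  k <- vapply(seq_along(trees), function(i) {
    tryCatch(blombergs_k(values, trees[[i]]), error = function(e) {
      stop("tree ", i, ": ", conditionMessage(e))
    })
  }, numeric(1))
  list(k = k, median = stats::median(k), range = range(k))
}

#' Welch two-sample t test of group sensitivities
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value (delegates to [stats::t.test()]). Used to compare
#' mean sensitivity between nocturnal and diurnal migrants.
#'
#' @param group_a,group_b numeric vectors, each of length at least 2.
#' @param var_equal use the pooled-variance test instead (default `FALSE`).
#' @return list with `mean_diff` (mean of A minus mean of B), `t`, `df`, `p`.
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(
    mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Diel comparison of species sensitivities
#'
#' Splits species-level sensitivities by diel migration strategy and runs
#' the two-group test on nocturnal versus diurnal migrants; species labelled
#' `both` or `unknown` are excluded from the comparison.
#'
#' @param sensitivities data frame `species_code`, `sensitivity` (see
#'   [species_sensitivity()]).
#' @param traits trait table with `diel`.
#' @return the [welch_t_test()] result plus group sizes.
#' @export
diel_comparison <- function(sensitivities, traits) {
  diel <- traits$diel[match(sensitivities$species_code, traits$species_code)]
  noct <- sensitivities$sensitivity[diel == "nocturnal"]
  diur <- sensitivities$sensitivity[diel == "diurnal"]
  if (length(noct) < 2 || length(diur) < 2) {
    stop("need at least 2 nocturnal and 2 diurnal species")
  }
  out <- welch_t_test(noct, diur)
  out$n_nocturnal <- length(noct)
  out$n_diurnal <- length(diur)
  out
}
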
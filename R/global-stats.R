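# Global condition comparison: are the averaged landscapes of the two
# conditions further apart than expected under random reassignment of
# pathways to conditions?

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")` (step-up
#' procedure controlling the false discovery rate).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Global permutation test on averaged landscape differences
#'
#' Observed statistics are the sup-, 1- and 2-norms of
#' `average(disease) - average(control)`. Under the null, all landscapes
#' are pooled and randomly reassigned into two groups of the original
#' sizes; the p-value per norm is the proportion of permutations whose
#' statistic is greater than or equal to the observed one. The three
#' norms' p-values are BH-adjusted as one family (one homological
#' dimension per call).
#'
#' @param landscapes_c,landscapes_d lists of [landscape()] objects (one
#'   per pathway) for the control and disease condition; same grid and
#'   dimension throughout.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for reproducible permutations.
#' @param norms subset of `c("sup", "one", "two")`.
#' @param estimator `"count"` for p = count/N (the raw proportion) or
#'   `"plus_one"` for the conservative (count + 1)/(N + 1).
#' @return a tibble of class `pph_global_test` with columns `dimension`,
#'   `norm`, `observed`, `p`, `q`, `n_perm`, `seed`.
#' @export
global_permutation_test <- function(landscapes_c, landscapes_d,
                                    n_perm = 1000, seed = NULL,
                                    norms = c("sup", "one", "two"),
                                    estimator = c("count", "plus_one")) {
  estimator <- match.arg(estimator)
  norms <- match.arg(norms, several.ok = TRUE)
  if (length(landscapes_c) == 0L || length(landscapes_d) == 0L) {
    stop("both condition groups must contain at least one landscape")
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  all_l <- c(landscapes_c, landscapes_d)
  check_compatible(all_l)
  if (!is.null(seed)) set.seed(seed)

  n_c <- length(landscapes_c)
  n <- length(all_l)
  grid <- all_l[[1]]$grid
  K <- max(vapply(all_l, function(l) nrow(l$levels), integer(1)))
  mats <- lapply(all_l, function(l) pad_levels(l$levels, K, length(grid)))

  diff_norms <- function(idx_c) {
    mc <- Reduce(`+`, mats[idx_c]) / length(idx_c)
    md <- Reduce(`+`, mats[-idx_c]) / (n - length(idx_c))
    D <- new_landscape(grid, md - mc, all_l[[1]]$dimension)
    vapply(norms, function(w) landscape_norm(D, w), numeric(1))
  }
  observed <- diff_norms(seq_len(n_c))
  perm <- matrix(NA_real_, n_perm, length(norms))
  for (b in seq_len(n_perm)) {
    perm[b, ] <- diff_norms(sample(n, n_c))
  }
  counts <- colSums(perm >= matrix(observed, n_perm, length(norms),
                                   byrow = TRUE) - 1e-12)
  p <- if (estimator == "count") counts / n_perm else (counts + 1) / (n_perm + 1)
  out <- tibble::tibble(
    dimension = all_l[[1]]$dimension,
    norm = norms,
    observed = unname(observed),
    p = unname(p),
    q = bh_adjust(p),
    n_perm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  structure(out, class = c("pph_global_test", class(out)))
}

#' @method glance pph_global_test
#' @export
glance.pph_global_test <- function(x, ...) {
  tibble::tibble(dimension = x$dimension[1],
                 n_perm = x$n_perm[1],
                 min_q = min(x$q),
                 all_significant = all(x$q < 0.05))
}
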
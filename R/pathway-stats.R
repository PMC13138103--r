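# Per-pathway comparison of Betti series between conditions: two-sample
# KS statistic and Cohen's d on the tau = 101 per-threshold Betti values,
# permutation p-values by pooling and resplitting the values, BH across
# pathways within each (statistic, dimension) family, and the four-test
# intersection rule for significance.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `K = sup_v |F_C(v) - F_D(v)|` over the empirical CDFs of the two value
#' samples (here: the Betti numbers of the two conditions across all
#' filtration steps). Tie-aware; agrees with `stats::ks.test()$statistic`.
#'
#' @param x,y numeric vectors (non-empty).
#' @return the statistic, in `[0, 1]`.
#' @examples
#' ks_statistic(c(0, 0, 1, 2), c(1, 2, 2, 3))  # 0.5
#' @export
ks_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("series must be non-empty")
  z <- c(x, y)
  w <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  ord <- order(z)
  cs <- cumsum(w[ord])
  zs <- z[ord]
  valid <- c(zs[-1] != zs[-length(zs)], TRUE)
  max(abs(cs[valid]))
}

#' Cohen's d between two Betti series
#'
#' Standardized mean difference `d = mu_delta / s` with
#' `mu_delta = mean(series_c) - mean(series_d)` and `s` the pooled sample
#' standard deviation (n - 1 denominators). A positive `d` means the
#' control series runs higher (e.g. more disconnected components in the
#' control condition for dimension 0). If both series are constant the
#' result is 0 when they are equal and a signed `Inf` sentinel otherwise.
#'
#' @param series_c,series_d numeric vectors of length >= 2 (by default the
#'   tau = 101 Betti values of the control and disease filtration).
#' @return a real number (possibly `Inf`/`-Inf` for degenerate input).
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # -1
#' @export
cohens_d <- function(series_c, series_d) {
  cohen_components(series_c, series_d)$d
}

cohen_components <- function(series_c, series_d) {
  n1 <- length(series_c); n2 <- length(series_d)
  if (n1 < 2L || n2 < 2L) stop("series must have length >= 2")
  mu_delta <- mean(series_c) - mean(series_d)
  s <- sqrt(((n1 - 1) * stats::var(series_c) +
               (n2 - 1) * stats::var(series_d)) / (n1 + n2 - 2))
  d <- if (s > 0) mu_delta / s
       else if (mu_delta == 0) 0
       else sign(mu_delta) * Inf
  list(d = d, mu_delta = mu_delta, s = s)
}

#' Permutation p-value for a Betti-series statistic
#'
#' Pools the two series' values, repeatedly resplits them at random into
#' two groups of the original sizes, recomputes the statistic (KS, or
#' |Cohen's d| for a two-sided effect-size test), and returns the
#' proportion of permuted statistics greater than or equal to the
#' observed one (ties inclusive).
#'
#' @param series_c,series_d numeric vectors.
#' @param stat `"ks"` or `"d"`.
#' @param n_perm number of permutations (default 5000).
#' @param seed optional integer seed.
#' @param estimator `"count"` (count/N) or `"plus_one"`
#'   ((count + 1)/(N + 1)).
#' @return p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(series_c, series_d, stat = c("ks", "d"),
                               n_perm = 5000, seed = NULL,
                               estimator = c("count", "plus_one")) {
  stat <- match.arg(stat)
  estimator <- match.arg(estimator)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (stat == "ks") ks_statistic
              else function(a, b) abs(cohens_d(a, b))
  observed <- stat_fun(series_c, series_d)
  pool <- c(series_c, series_d)
  n1 <- length(series_c); n <- length(pool)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    if (stat_fun(pool[idx], pool[-idx]) >= observed - 1e-12) {
      count <- count + 1L
    }
  }
  if (estimator == "count") count / n_perm else (count + 1) / (n_perm + 1)
}

#' Compare one pathway's Betti series between conditions
#'
#' Computes the KS statistic, Cohen's d (with mean difference and pooled
#' standard deviation) and their permutation p-values for each homology
#' dimension of a pathway.
#'
#' @param curve_c,curve_d [betti_curve()] objects for the control and
#'   disease condition of the same pathway.
#' @param dimensions homology dimensions to test (default `c(0, 1)`).
#' @param n_perm permutations per test (default 5000).
#' @param seed optional integer seed.
#' @return tibble with one row per dimension: `pathway_id`, `dimension`,
#'   `K`, `d`, `mu_delta`, `s_pooled`, `p_ks`, `p_d`.
#' @export
compare_pathway <- function(curve_c, curve_d, dimensions = c(0L, 1L),
                            n_perm = 5000, seed = NULL) {
  stopifnot(inherits(curve_c, "betti_curve"), inherits(curve_d, "betti_curve"))
  if (!is.null(seed)) set.seed(seed)
  id <- attr(curve_c, "pathway_id") %||% NA_character_
  purrr::map_dfr(dimensions, function(dm) {
    sc <- betti_series(curve_c, dm)
    sd_ <- betti_series(curve_d, dm)
    cc <- cohen_components(sc, sd_)
    tibble::tibble(
      pathway_id = id,
      dimension = as.integer(dm),
      K = ks_statistic(sc, sd_),
      d = cc$d,
      mu_delta = cc$mu_delta,
      s_pooled = cc$s,
      p_ks = permutation_pvalue(sc, sd_, "ks", n_perm),
      p_d = permutation_pvalue(sc, sd_, "d", n_perm)
    )
  })
}

#' Four-test significance across pathways
#'
#' Applies BH correction across pathways within each of the four test
#' families ({KS, Cohen's d} x {dimension 0, dimension 1}) and flags a
#' pathway as significant only when all four q-values fall below `alpha`.
#'
#' @param results tibble with columns `pathway_id`, `dimension` (0 and 1
#'   for every pathway), `p_ks`, `p_d` (e.g. rows from
#'   [compare_pathway()]).
#' @param alpha FDR threshold (default 0.05).
#' @return the input with added `q_ks`, `q_d` and a per-pathway
#'   `significant` flag.
#' @export
pathway_significance <- function(results, alpha = 0.05) {
  results <- tibble::as_tibble(results)
  needed <- c("pathway_id", "dimension", "p_ks", "p_d")
  if (!all(needed %in% names(results))) {
    stop("`results` must have columns ", paste(needed, collapse = ", "))
  }
  counts <- table(results$pathway_id)
  bad <- names(counts)[counts != 2L]
  if (length(bad) || !all(results$dimension %in% c(0L, 1L))) {
    stop("each pathway needs exactly one row per dimension 0 and 1; ",
         "offending: ", paste(bad, collapse = ", "))
  }
  out <- results |>
    dplyr::group_by(.data$dimension) |>
    dplyr::mutate(q_ks = bh_adjust(.data$p_ks),
                  q_d = bh_adjust(.data$p_d)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::mutate(significant = all(c(.data$q_ks, .data$q_d) < alpha)) |>
    dplyr::ungroup()
  structure(out, class = c("pph_pathway_tests", class(out)), alpha = alpha)
}

#' @method glance pph_pathway_tests
#' @export
glance.pph_pathway_tests <- function(x, ...) {
  tibble::tibble(
    n_pathways = dplyr::n_distinct(x$pathway_id),
    n_significant = dplyr::n_distinct(x$pathway_id[x$significant]),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
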
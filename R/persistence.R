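# Barcodes from the filtration via the rank invariant.
#
# The Betti series alone does not determine how features pair into bars;
# the canonical one-parameter construction uses the persistent Betti
# numbers beta_n(i, j) = dim Z_n(G_i) - dim(Z_n(G_i) /\ B_n(G_j)) (valid
# here because the chain spaces are nested under edge inclusion) and the
# inclusion-exclusion multiplicities
#   mu(i, j) = beta(i, j-1) - beta(i, j) - beta(i-1, j-1) + beta(i-1, j).
# Classes alive at the last step are "essential" and capped at death 1.0
# (the full network is always present at f = 1). A "curve" heuristic mode
# (all births at the Betti increment, each decrement kills the youngest
# live bar) is kept for comparison with Betti-series-only pipelines.

#' Persistence barcode of a filtered digraph
#'
#' @param fg a [filtered_digraph()].
#' @param dimension homology dimension, 0 or 1.
#' @param step filtration step (default 0.01).
#' @param method `"rank"` (canonical rank-invariant pairing, default) or
#'   `"curve"` (heuristic pairing from the Betti series alone).
#' @param cap_essential if `TRUE` (default) classes alive at `f = 1` are
#'   recorded with death 1.0 and `essential = TRUE`; if `FALSE` they are
#'   dropped.
#' @param p prime modulus for the coefficient field.
#' @return a tibble of class `pph_barcode` with columns `dimension`,
#'   `birth`, `death`, `essential`.
#' @export
persistence_pairs <- function(fg, dimension = 1L, step = 0.01,
                              method = c("rank", "curve"),
                              cap_essential = TRUE, p = GF_DEFAULT_PRIME) {
  stopifnot(inherits(fg, "filtered_digraph"), dimension %in% c(0L, 1L))
  method <- match.arg(method)
  grid <- filtration_grid(step)
  T_ <- length(grid) - 1L

  if (dimension == 0L || method == "curve") {
    curve <- betti_curve(fg, step = step, p = p)
    series <- betti_series(curve, dimension)
    bars <- if (dimension == 0L) {
      bars_dim0(series, grid)
    } else {
      bars_from_curve(series, grid)
    }
  } else {
    bars <- bars_rank_dim1(fg, grid, step, p)
  }
  if (!cap_essential) bars <- bars[!bars$essential, , drop = FALSE]
  out <- tibble::tibble(dimension = rep(as.integer(dimension), nrow(bars)),
                        birth = bars$birth, death = bars$death,
                        essential = bars$essential)
  structure(out, class = c("pph_barcode", class(out)),
            pathway_id = fg$network$pathway_id,
            condition = fg$condition, step = step)
}

# dimension 0: the map H0(G_i) -> H0(G_j) is always surjective (the vertex
# set is fixed), so beta0(i, j) = beta0(G_j): every component is born at 0
# and deaths follow the beta0 decrements.
bars_dim0 <- function(series, grid) {
  births <- numeric(0); deaths <- numeric(0)
  drops <- which(diff(series) < 0)
  for (t in drops) {
    k <- series[t] - series[t + 1L]
    births <- c(births, rep(0, k))
    deaths <- c(deaths, rep(grid[t + 1L], k))
  }
  n_ess <- series[length(series)]
  tibble::tibble(
    birth = c(births, rep(0, n_ess)),
    death = c(deaths, rep(grid[length(grid)], n_ess)),
    essential = c(rep(FALSE, length(deaths)), rep(TRUE, n_ess))
  )
}

# heuristic pairing from the Betti series: increments open bars, each
# decrement closes the youngest live bar (LIFO).
bars_from_curve <- function(series, grid) {
  live <- numeric(0)  # birth times, youngest last
  births <- numeric(0); deaths <- numeric(0)
  prev <- 0L
  for (t in seq_along(series)) {
    delta <- series[t] - prev
    if (delta > 0) live <- c(live, rep(grid[t], delta))
    if (delta < 0) {
      for (i in seq_len(-delta)) {
        births <- c(births, live[length(live)])
        deaths <- c(deaths, grid[t])
        live <- live[-length(live)]
      }
    }
    prev <- series[t]
  }
  tibble::tibble(
    birth = c(births, live),
    death = c(deaths, rep(grid[length(grid)], length(live))),
    essential = c(rep(FALSE, length(deaths)), rep(TRUE, length(live)))
  )
}

# dimension 1 via the rank invariant. Only critical grid indices (where an
# edge enters) can change anything, so persistent Betti numbers are
# computed on critical indices and step-function lookup handles the rest.
bars_rank_dim1 <- function(fg, grid, step, p) {
  nodes <- fg$network$nodes
  edges <- fg$network$edges
  m <- nrow(edges)
  T_ <- length(grid) - 1L
  entry <- entry_index(edges$distance, step)
  crit <- sort(unique(c(0L, entry)))

  # per critical index: cycle-space basis K (embedded in full edge coords)
  # and boundary-space spanning set B, plus their dimensions
  K_list <- vector("list", length(crit))
  B_list <- vector("list", length(crit))
  rB <- integer(length(crit))
  for (i in seq_along(crit)) {
    sel <- which(entry <= crit[i])
    sub <- edges[sel, , drop = FALSE]
    D1 <- build_d1(nodes, sub)
    Ksub <- gf_nullspace(D1, p)
    K <- matrix(0, m, ncol(Ksub))
    if (ncol(Ksub)) K[sel, ] <- Ksub
    Bsub <- b1_spanning_set(sub, p)
    B <- matrix(0, m, ncol(Bsub))
    if (ncol(Bsub)) B[sel, ] <- Bsub
    K_list[[i]] <- K
    B_list[[i]] <- B
    rB[i] <- gf_rank(B, p)
  }

  # beta(i, j) on critical indices: rank([K_i | B_j]) - rank(B_j)
  memo <- new.env(parent = emptyenv())
  floor_crit <- function(t) {
    # position in `crit` of the largest critical index <= t; 0 if t < 0
    if (t < 0L) return(0L)
    findInterval(t, crit)
  }
  beta_pos <- function(pi, pj) {
    # pi, pj are positions in `crit` (0 = nothing present / beta = 0)
    if (pi == 0L) return(0L)
    key <- paste(pi, pj)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- gf_rank(cbind(K_list[[pi]], B_list[[pj]]), p) - rB[pj]
    memo[[key]] <- val
    val
  }
  beta_ij <- function(i, j) beta_pos(floor_crit(i), floor_crit(j))

  births <- numeric(0); deaths <- numeric(0); ess <- logical(0)
  for (bi in crit) {
    for (dj in crit[crit > bi]) {
      mu <- beta_ij(bi, dj - 1L) - beta_ij(bi, dj) -
        beta_ij(bi - 1L, dj - 1L) + beta_ij(bi - 1L, dj)
      if (mu > 0) {
        births <- c(births, rep(grid[bi + 1L], mu))
        deaths <- c(deaths, rep(grid[dj + 1L], mu))
        ess <- c(ess, rep(FALSE, mu))
      }
    }
    mu_inf <- beta_ij(bi, T_) - beta_ij(bi - 1L, T_)
    if (mu_inf > 0) {
      births <- c(births, rep(grid[bi + 1L], mu_inf))
      deaths <- c(deaths, rep(grid[length(grid)], mu_inf))
      ess <- c(ess, rep(TRUE, mu_inf))
    }
  }
  tibble::tibble(birth = births, death = deaths, essential = ess)
}

#' Number of bars alive at each grid threshold
#'
#' A bar `(b, d)` is alive at `f` when `b <= f < d`; essential bars are
#' alive from their birth onwards. By construction this matches the Betti
#' curve of the same filtration pointwise.
#'
#' @param barcode a `pph_barcode`.
#' @param grid thresholds at which to count (defaults to the barcode's own
#'   grid).
#' @return integer vector of live-bar counts along `grid`.
#' @export
bars_alive <- function(barcode, grid = NULL) {
  if (is.null(grid)) grid <- filtration_grid(attr(barcode, "step") %||% 0.01)
  vapply(grid, function(f) {
    sum(barcode$birth <= f + 1e-12 &
          (barcode$essential | barcode$death > f + 1e-12))
  }, integer(1))
}

#' @method tidy pph_barcode
#' @export
tidy.pph_barcode <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, birth = x$birth, death = x$death,
                 essential = x$essential,
                 persistence = x$death - x$birth)
}
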
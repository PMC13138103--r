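# Regular path homology of a digraph, dimensions 0 and 1.
#
# Chain spaces: Omega_0 = span of vertices, Omega_1 = span of edges, and
# Omega_2 = the delta-invariant subspace of the span of allowed 2-paths
# (u -> v -> w with both steps edges): those combinations whose boundary
#   d(u,v,w) = (v,w) - (u,w) + (u,v)
# is supported only on allowed 1-paths (i.e. actual edges; the (u,w) term
# with u = w is irregular and set to zero). Then
#   beta0 = |V| - rank d1,   beta1 = dim ker d1 - rank(d2 | Omega_2).
# All ranks are computed exactly over a large prime field (see gf-linalg.R);
# boundary matrices have entries in {-1, 0, 1}.

#' The filtration grid
#'
#' Thresholds `0, step, 2*step, ..., 1` (101 points for the default step
#' of 0.01).
#'
#' @param step grid step; must divide 1 evenly.
#' @return numeric vector of thresholds.
#' @export
filtration_grid <- function(step = 0.01) {
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9) stop("`step` must divide 1 evenly")
  seq(0L, k) * step
}

# first grid index (0-based) at which an edge of weight w is present:
# smallest t with w <= t*step + tol
entry_index <- function(w, step = 0.01, tol = 1e-12) {
  pmax(0L, pmin(as.integer(ceiling((w - tol) / step)), as.integer(round(1 / step))))
}

# ---- internal matrix builders -------------------------------------------

# edges: data frame with source/target (characters); nodes: character vector
build_d1 <- function(nodes, edges) {
  n <- length(nodes); m <- nrow(edges)
  D1 <- matrix(0, n, m)
  if (m) {
    D1[cbind(match(edges$source, nodes), seq_len(m))] <- -1
    D1[cbind(match(edges$target, nodes), seq_len(m))] <- 1
  }
  D1
}

# allowed 2-paths (u,v,w): pairs of composable edges. Returns a data frame
# with the composing edge indices e1 (u->v), e2 (v->w) and endpoints.
allowed_two_paths <- function(edges) {
  m <- nrow(edges)
  if (m == 0L) {
    return(data.frame(e1 = integer(), e2 = integer(),
                      u = character(), v = character(), w = character(),
                      stringsAsFactors = FALSE))
  }
  by_source <- split(seq_len(m), edges$source)
  rows <- lapply(seq_len(m), function(i) {
    nxt <- by_source[[edges$target[i]]]
    if (is.null(nxt)) return(NULL)
    data.frame(e1 = i, e2 = nxt,
               u = edges$source[i], v = edges$target[i],
               w = edges$target[nxt], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(e1 = integer(), e2 = integer(),
                                      u = character(), v = character(),
                                      w = character(), stringsAsFactors = FALSE)
  out
}

# Boundary data for dimension 2: the allowed part D2a (|E| x |A2|) and the
# non-allowed projection P (rows = non-edge (u,w) pairs). Omega_2 = ker P.
build_d2 <- function(edges, a2) {
  m <- nrow(edges); k <- nrow(a2)
  edge_key <- paste(edges$source, edges$target, sep = "\r")
  D2a <- matrix(0, m, k)
  na_key <- character(0)
  na_entries <- list()
  if (k) {
    for (j in seq_len(k)) {
      D2a[a2$e2[j], j] <- D2a[a2$e2[j], j] + 1  # (v,w)
      D2a[a2$e1[j], j] <- D2a[a2$e1[j], j] + 1  # (u,v)
      if (a2$u[j] != a2$w[j]) {                 # (u,w); irregular if u == w
        uw <- paste(a2$u[j], a2$w[j], sep = "\r")
        hit <- match(uw, edge_key)
        if (!is.na(hit)) {
          D2a[hit, j] <- D2a[hit, j] - 1
        } else {
          na_entries[[length(na_entries) + 1L]] <- c(uw, j)
        }
      }
    }
  }
  if (length(na_entries)) {
    na_key <- unique(vapply(na_entries, `[`, "", 1L))
    P <- matrix(0, length(na_key), k)
    for (ent in na_entries) {
      P[match(ent[1], na_key), as.integer(ent[2])] <-
        P[match(ent[1], na_key), as.integer(ent[2])] - 1
    }
  } else {
    P <- matrix(0, 0L, k)
  }
  list(D2a = D2a, P = P)
}

# Spanning set for the boundary space B1 = d2(Omega_2), as columns in edge
# coordinates (|E| rows). May be empty (0 columns).
b1_spanning_set <- function(edges, p = GF_DEFAULT_PRIME) {
  a2 <- allowed_two_paths(edges)
  if (nrow(a2) == 0L) return(matrix(0, nrow(edges), 0L))
  bd <- build_d2(edges, a2)
  if (nrow(bd$P) == 0L) return(bd$D2a %% p)
  N <- gf_nullspace(bd$P, p)
  if (ncol(N) == 0L) return(matrix(0, nrow(edges), 0L))
  gf_mul(bd$D2a %% p, N, p)
}

# ---- Betti numbers -------------------------------------------------------

#' Path-homology Betti numbers of a directed graph
#'
#' Computes `beta0` (connected components) and `beta1` (independent
#' directed cycles in the path-homology sense) of a digraph. Ranks are
#' computed exactly over a large prime field; no floating-point rank
#' estimation is involved.
#'
#' @param x a [pathway_network()], a [filtered_digraph()] (its full edge
#'   set), or a data frame of edges (`source`, `target`).
#' @param nodes node set when `x` is a plain edge table; defaults to the
#'   symbols appearing in the edges.
#' @param p prime modulus for the coefficient field.
#' @return named integer vector `c(beta0 = ..., beta1 = ...)`.
#' @examples
#' betti_numbers(toy_network())  # beta0 = 3, beta1 = 2
#' @export
betti_numbers <- function(x, nodes = NULL, p = GF_DEFAULT_PRIME) {
  if (inherits(x, "filtered_digraph")) x <- x$network
  if (inherits(x, "pathway_network")) {
    nodes <- x$nodes
    edges <- x$edges
  } else {
    edges <- tibble::as_tibble(x)
    if (nrow(edges) && !all(c("source", "target") %in% names(edges))) {
      stop("edge table must have columns `source` and `target`")
    }
    if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  }
  if (nrow(edges) && any(edges$source == edges$target)) {
    stop("self-loops violate the regular-path assumption")
  }
  betti_core(nodes, edges, p)
}

betti_core <- function(nodes, edges, p = GF_DEFAULT_PRIME) {
  n <- length(nodes); m <- nrow(edges)
  if (m == 0L) return(c(beta0 = n, beta1 = 0L))
  r1 <- gf_rank(build_d1(nodes, edges), p)
  z1 <- m - r1
  B <- b1_spanning_set(edges, p)
  r2 <- gf_rank(B, p)
  c(beta0 = as.integer(n - r1), beta1 = as.integer(z1 - r2))
}

# ---- Betti curves --------------------------------------------------------

#' Betti curves along the correlation-distance filtration
#'
#' Evaluates `beta0` and `beta1` of the subgraph containing all nodes and
#' every edge of distance `<= f` at each threshold `f` on the grid
#' `0, step, ..., 1`.
#'
#' @param fg a [filtered_digraph()].
#' @param step filtration step (default 0.01, i.e. 101 grid points).
#' @param p prime modulus for the coefficient field.
#' @return a tibble of class `betti_curve` with columns `f`, `dimension`
#'   (0 or 1) and `betti`; attributes `pathway_id` and `condition` carry
#'   provenance.
#' @export
betti_curve <- function(fg, step = 0.01, p = GF_DEFAULT_PRIME) {
  stopifnot(inherits(fg, "filtered_digraph"))
  grid <- filtration_grid(step)
  T_ <- length(grid) - 1L
  nodes <- fg$network$nodes
  edges <- fg$network$edges
  entry <- entry_index(edges$distance, step)
  crit <- sort(unique(c(0L, entry)))

  b0 <- integer(T_ + 1L); b1 <- integer(T_ + 1L)
  prev <- 0L
  last <- c(beta0 = length(nodes), beta1 = 0L)
  for (ci in crit) {
    sub <- edges[entry <= ci, , drop = FALSE]
    last <- betti_core(nodes, sub, p)
    b0[(ci + 1L):(T_ + 1L)] <- last[["beta0"]]
    b1[(ci + 1L):(T_ + 1L)] <- last[["beta1"]]
    prev <- ci
  }
  out <- tibble::tibble(
    f = rep(grid, 2L),
    dimension = rep(c(0L, 1L), each = T_ + 1L),
    betti = c(b0, b1)
  )
  structure(out,
            class = c("betti_curve", class(out)),
            pathway_id = fg$network$pathway_id,
            condition = fg$condition,
            step = step)
}

#' Extract one dimension's Betti series from a Betti curve
#'
#' @param curve a [betti_curve()].
#' @param dimension 0 or 1.
#' @return integer vector of Betti numbers along the grid.
#' @export
betti_series <- function(curve, dimension) {
  stopifnot(inherits(curve, "betti_curve"))
  curve$betti[curve$dimension == dimension]
}
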
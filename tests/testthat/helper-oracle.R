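# Independent oracle for the homology core: exact integer (rational) ranks
# via fraction-free Bareiss elimination, a from-scratch enumeration of the
# boundary matrices, and the rank identity
#   rank(d2 | Omega_2) = rank([P; D2]) - rank(P)
# (for x in ker P the full boundary is (0; D2 x), and ker[P; D2] is the
# subspace of ker P killed by D2). This shares no code path or algorithm
# with the package's GF(p) nullspace construction.

# Exact rank of an integer matrix over Q (fraction-free Bareiss; all
# divisions are exact by Sylvester's identity, entries stay integral).
bareiss_rank <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); m <- ncol(M)
  if (n == 0L || m == 0L) return(0L)
  prev <- 1
  r <- 1L
  rank <- 0L
  for (cc in seq_len(m)) {
    piv <- which(M[r:n, cc] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + r - 1L
    if (piv != r) {
      tmp <- M[r, ]; M[r, ] <- M[piv, ]; M[piv, ] <- tmp
    }
    if (r < n) {
      for (i in (r + 1L):n) {
        M[i, ] <- (M[i, ] * M[r, cc] - M[i, cc] * M[r, ]) / prev
      }
    }
    prev <- M[r, cc]
    rank <- rank + 1L
    r <- r + 1L
    if (r > n) break
  }
  rank
}

# Exhaustive-basis oracle for (beta0, beta1) of a digraph given as an edge
# data frame (source, target) plus a node vector.
oracle_betti <- function(nodes, edges) {
  n <- length(nodes)
  m <- nrow(edges)
  if (m == 0L) return(c(beta0 = n, beta1 = 0L))
  src <- match(edges$source, nodes)
  tgt <- match(edges$target, nodes)
  D1 <- matrix(0L, n, m)
  for (e in seq_len(m)) {
    D1[src[e], e] <- D1[src[e], e] - 1L
    D1[tgt[e], e] <- D1[tgt[e], e] + 1L
  }
  r1 <- bareiss_rank(D1)

  # enumerate allowed 2-paths by brute force over edge pairs
  two <- list()
  for (e1 in seq_len(m)) {
    for (e2 in seq_len(m)) {
      if (tgt[e1] == src[e2]) two[[length(two) + 1L]] <- c(e1, e2)
    }
  }
  if (length(two) == 0L) {
    return(c(beta0 = n - r1, beta1 = (m - r1)))
  }
  # rows: every distinct ordered pair (u, w) that appears in a boundary,
  # allowed (an edge) or not; columns: allowed 2-paths
  pair_key <- function(u, w) paste(u, w)
  edge_keys <- pair_key(src, tgt)
  rows <- character(0)
  cols <- list()
  for (j in seq_along(two)) {
    e1 <- two[[j]][1]; e2 <- two[[j]][2]
    u <- src[e1]; v <- tgt[e1]; w <- tgt[e2]
    terms <- list(c(pair_key(v, w), 1), c(pair_key(u, v), 1))
    if (u != w) terms <- c(terms, list(c(pair_key(u, w), -1)))
    cols[[j]] <- terms
    rows <- union(rows, vapply(terms, `[`, "", 1))
  }
  Tm <- matrix(0L, length(rows), length(two))
  for (j in seq_along(cols)) {
    for (term in cols[[j]]) {
      i <- match(term[1], rows)
      Tm[i, j] <- Tm[i, j] + as.integer(term[2])
    }
  }
  not_allowed <- !(rows %in% edge_keys)
  P <- Tm[not_allowed, , drop = FALSE]
  r2 <- bareiss_rank(Tm) - bareiss_rank(P)
  c(beta0 = n - r1, beta1 = (m - r1) - r2)
}

# random digraph without self-loops; edge probability p_edge
random_digraph <- function(n_nodes, p_edge = 0.3) {
  nodes <- paste0("v", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

random_filtered_digraph <- function(n_nodes, p_edge = 0.4) {
  g <- random_digraph(n_nodes, p_edge)
  net <- pathway_network(g$edges, nodes = g$nodes)
  d <- stats::runif(nrow(net$edges))
  # both orientations of a mutual pair share a weight, as weight_edges does
  a <- pmin(net$edges$source, net$edges$target)
  b <- pmax(net$edges$source, net$edges$target)
  key <- paste(a, b)
  d <- d[match(key, unique(key))]
  net$edges$distance <- d
  filtered_digraph(net)
}

# pointwise landscape evaluation on an arbitrary grid (brute force)
brute_landscape_level <- function(bars, k, ts) {
  vapply(ts, function(t) {
    vals <- pmax(0, pmin(t - bars$birth, bars$death - t))
    sort(vals, decreasing = TRUE)[k] %||% 0
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
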
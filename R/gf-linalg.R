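# Exact linear algebra over a prime field GF(p), stored in base double matrices.
# Default prime: all intermediate products stay below 2^53 for matrices with
# inner dimension up to ~9000, so double arithmetic is exact.
GF_DEFAULT_PRIME <- 1000003

#' Modular inverse in GF(p)
#'
#' Extended Euclid; `a` must be nonzero mod `p`.
#' @param a integer-valued scalar.
#' @param p prime modulus.
#' @return the inverse of `a` modulo `p`.
#' @keywords internal
#' @noRd
gf_inv <- function(a, p) {
  a <- a %% p
  if (a == 0) stop("gf_inv: zero is not invertible")
  # extended Euclidean algorithm
  r0 <- p; r1 <- a
  t0 <- 0; t1 <- 1
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
  }
  t0 %% p
}

# Row-reduce M over GF(p). Returns list(rank, pivots, mat) where mat is the
# reduced row-echelon form. Vectorised row elimination: products are bounded
# by (p-1)^2 < 2^53, so doubles are exact.
gf_rref <- function(M, p = GF_DEFAULT_PRIME) {
  M <- as.matrix(M) %% p
  n <- nrow(M); m <- ncol(M)
  pivots <- integer(0)
  row <- 1L
  if (n > 0L && m > 0L) {
    for (col in seq_len(m)) {
      if (row > n) break
      hit <- which(M[row:n, col] != 0)
      if (length(hit) == 0L) next
      piv <- hit[1L] + row - 1L
      if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
      M[row, ] <- (M[row, ] * gf_inv(M[row, col], p)) %% p
      others <- setdiff(which(M[, col] != 0), row)
      if (length(others)) {
        M[others, ] <- (M[others, , drop = FALSE] -
                          outer(M[others, col], M[row, ])) %% p
      }
      pivots <- c(pivots, col)
      row <- row + 1L
    }
  }
  list(rank = length(pivots), pivots = pivots, mat = M)
}

gf_rank <- function(M, p = GF_DEFAULT_PRIME) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  gf_rref(M, p)$rank
}

# Basis of the null space of M over GF(p), as columns of a matrix with
# ncol(M) rows (possibly 0 columns).
gf_nullspace <- function(M, p = GF_DEFAULT_PRIME) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1L)
  m <- ncol(M)
  if (m == 0L) return(matrix(0, 0L, 0L))
  if (nrow(M) == 0L) return(diag(1, m))
  rr <- gf_rref(M, p)
  free <- setdiff(seq_len(m), rr$pivots)
  if (length(free) == 0L) return(matrix(0, m, 0L))
  N <- matrix(0, m, length(free))
  R <- rr$mat
  for (j in seq_along(free)) {
    fc <- free[j]
    N[fc, j] <- 1
    if (length(rr$pivots)) {
      # pivot row i has leading 1 in column pivots[i]
      N[rr$pivots, j] <- (-R[seq_along(rr$pivots), fc]) %% p
    }
  }
  N
}

# Matrix product over GF(p); checks that the inner dimension keeps the exact-
# double accumulation safe (k * p^2 < 2^53).
gf_mul <- function(A, B, p = GF_DEFAULT_PRIME) {
  k <- ncol(A)
  if (k * (p - 1)^2 >= 2^53) {
    stop("gf_mul: inner dimension too large for exact double accumulation")
  }
  (A %*% B) %% p
}
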
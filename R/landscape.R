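# Persistence landscapes on the filtration grid. The k-th landscape level
# lambda_k(t) is the k-th largest tent value max(0, min(t - b, d - t)) over
# the bars (b, d); levels are stored as a K x length(grid) matrix (K = 0
# for an empty barcode). Evaluating on the same grid as the filtration
# keeps discretization error below half a grid step (each lambda_k is
# 1-Lipschitz).

#' Persistence landscape of a barcode
#'
#' @param barcode a `pph_barcode` (from [persistence_pairs()]) or any data
#'   frame with `birth` and `death` columns.
#' @param step evaluation grid step (default 0.01, the filtration grid).
#' @param dimension optional filter when `barcode` mixes dimensions.
#' @return an object of class `persistence_landscape`: list with `grid`,
#'   `levels` (K x length(grid) matrix), `dimension`, `provenance`.
#' @examples
#' L <- landscape(data.frame(birth = 0.2, death = 0.6))
#' max(L$levels)  # peak (d - b) / 2 = 0.2
#' @export
landscape <- function(barcode, step = 0.01, dimension = NULL) {
  grid <- filtration_grid(step)
  bars <- tibble::as_tibble(barcode)
  if (!is.null(dimension) && "dimension" %in% names(bars)) {
    bars <- bars[bars$dimension == dimension, , drop = FALSE]
  }
  dim_out <- if (!is.null(dimension)) as.integer(dimension)
             else if ("dimension" %in% names(bars) && nrow(bars))
               as.integer(bars$dimension[1]) else NA_integer_
  if (nrow(bars) && any(bars$birth > bars$death + 1e-12)) {
    stop("bars must satisfy birth <= death")
  }
  if (nrow(bars) == 0L) {
    levels <- matrix(0, 0L, length(grid))
  } else {
    tents <- vapply(seq_len(nrow(bars)), function(i) {
      pmax(0, pmin(grid - bars$birth[i], bars$death[i] - grid))
    }, numeric(length(grid)))              # grid x bars
    tents <- matrix(tents, nrow = length(grid))
    sorted <- apply(tents, 1, function(v) sort(v, decreasing = TRUE))
    sorted <- matrix(sorted, ncol = length(grid))  # bars x grid
    K <- max(0L, which(rowSums(sorted) > 0))
    levels <- sorted[seq_len(K), , drop = FALSE]
  }
  new_landscape(grid, levels, dim_out,
                provenance = list(pathway_id = attr(barcode, "pathway_id"),
                                  condition = attr(barcode, "condition")))
}

new_landscape <- function(grid, levels, dimension, provenance = list()) {
  structure(list(grid = grid, levels = levels,
                 dimension = dimension, provenance = provenance),
            class = "persistence_landscape")
}

#' @export
print.persistence_landscape <- function(x, ...) {
  cat(sprintf("<persistence_landscape> dim %s, %d level(s) on %d grid points\n",
              ifelse(is.na(x$dimension), "?", x$dimension),
              nrow(x$levels), length(x$grid)))
  invisible(x)
}

#' Tidy a landscape into long format
#'
#' @param x a [landscape()].
#' @param ... unused.
#' @return tibble with columns `level`, `t`, `value`.
#' @method tidy persistence_landscape
#' @export
tidy.persistence_landscape <- function(x, ...) {
  K <- nrow(x$levels)
  if (K == 0L) {
    return(tibble::tibble(level = integer(), t = numeric(), value = numeric()))
  }
  tibble::tibble(level = rep(seq_len(K), each = length(x$grid)),
                 t = rep(x$grid, K),
                 value = as.vector(t(x$levels)))
}

pad_levels <- function(levels, K, width) {
  if (nrow(levels) >= K) return(levels)
  rbind(levels, matrix(0, K - nrow(levels), width))
}

check_compatible <- function(landscapes) {
  dims <- unique(vapply(landscapes, function(l) l$dimension, integer(1)))
  dims <- dims[!is.na(dims)]
  if (length(dims) > 1L) stop("landscapes mix homology dimensions")
  glens <- unique(vapply(landscapes, function(l) length(l$grid), integer(1)))
  if (length(glens) > 1L) stop("landscapes are on different grids")
  invisible(TRUE)
}

#' Pointwise mean of persistence landscapes
#'
#' Missing levels count as zero functions; the result keeps the maximum
#' number of levels of its inputs.
#'
#' @param landscapes list of [landscape()] objects on the same grid and
#'   dimension.
#' @return a [landscape()] with provenance `"average"`.
#' @export
average_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L)
  check_compatible(landscapes)
  grid <- landscapes[[1]]$grid
  K <- max(vapply(landscapes, function(l) nrow(l$levels), integer(1)))
  acc <- matrix(0, K, length(grid))
  for (l in landscapes) acc <- acc + pad_levels(l$levels, K, length(grid))
  new_landscape(grid, acc / length(landscapes), landscapes[[1]]$dimension,
                provenance = list(pathway_id = "average",
                                  condition = landscapes[[1]]$provenance$condition))
}

#' Difference of two (averaged) landscapes
#'
#' Pointwise, level-wise `disease - control`; missing levels are
#' zero-padded. The result may be negative and no longer satisfies the
#' level ordering.
#'
#' @param disease,control [landscape()] objects on the same grid and
#'   dimension.
#' @return a [landscape()] with provenance condition `"difference"`.
#' @export
landscape_difference <- function(disease, control) {
  check_compatible(list(disease, control))
  grid <- disease$grid
  K <- max(nrow(disease$levels), nrow(control$levels))
  diff <- pad_levels(disease$levels, K, length(grid)) -
    pad_levels(control$levels, K, length(grid))
  new_landscape(grid, diff, disease$dimension,
                provenance = list(pathway_id = "average",
                                  condition = "difference"))
}

#' Landscape norms
#'
#' `sup`: largest absolute value over all levels and grid points. `one`:
#' sum over levels of the trapezoidal integral of `|lambda_k|`. `two`:
#' square root of the summed trapezoidal integrals of `lambda_k^2`.
#'
#' @param L a [landscape()].
#' @param which `"sup"`, `"one"` or `"two"`.
#' @return nonnegative scalar.
#' @export
landscape_norm <- function(L, which = c("sup", "one", "two")) {
  which <- match.arg(which)
  if (nrow(L$levels) == 0L) return(0)
  switch(which,
    sup = max(abs(L$levels)),
    one = sum(apply(abs(L$levels), 1, function(y) pracma::trapz(L$grid, y))),
    two = sqrt(sum(apply(L$levels^2, 1,
                         function(y) pracma::trapz(L$grid, y))))
  )
}
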
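#' Construct an expression matrix with a two-condition sample map
#'
#' Holds log-scale expression values (genes x samples) together with the
#' sample-to-condition assignment. Each condition's columns form the point
#' cloud used to weight pathway edges: one point per gene, one dimension
#' per sample of that condition.
#'
#' @param values genes x samples matrix with gene symbols as row names, or
#'   a data frame whose first column holds gene symbols.
#' @param conditions sample -> condition assignment: a named character
#'   vector, or a two-column data frame (`sample`, `condition`). Exactly
#'   two condition labels are required; fewer than 3 samples per condition
#'   triggers a warning (Pearson correlation needs >= 3 points).
#' @return an object of class `expression_matrix` with fields `values`
#'   (numeric matrix) and `conditions` (named character vector).
#' @export
expression_matrix <- function(values, conditions) {
  if (is.data.frame(values)) {
    genes <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    rownames(values) <- genes
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("`values` must carry gene row names")
  if (anyDuplicated(rownames(values))) stop("gene symbols must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (!all(is.finite(values))) stop("expression values must all be finite")

  if (is.data.frame(conditions)) {
    conditions <- stats::setNames(as.character(conditions[[2]]),
                                  as.character(conditions[[1]]))
  }
  if (is.null(names(conditions))) stop("`conditions` must be named by sample")
  missing <- setdiff(colnames(values), names(conditions))
  if (length(missing)) {
    stop("samples without condition label: ", paste(missing, collapse = ", "))
  }
  conditions <- conditions[colnames(values)]
  labels <- unique(conditions)
  if (length(labels) != 2L) {
    stop("exactly two condition labels required, got: ",
         paste(labels, collapse = ", "))
  }
  small <- table(conditions) < 3L
  if (any(small)) {
    warning("condition(s) with fewer than 3 samples: ",
            paste(names(which(small)), collapse = ", "))
  }
  structure(list(values = values, conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$conditions)
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Log2 TPM normalization of raw counts
#'
#' Transcripts-per-million per sample:
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`,
#' returned as `log2(TPM + 1)`. The pseudocount keeps zero counts finite on
#' the log scale.
#'
#' @param counts genes x samples matrix of nonnegative counts (row names =
#'   gene symbols), or a data frame whose first column holds gene symbols.
#' @param lengths per-gene transcript length in bases: a named numeric
#'   vector or a two-column data frame (`gene`, `length`).
#' @param conditions optional sample -> condition map; when supplied the
#'   result is an [expression_matrix()], otherwise a plain numeric matrix.
#' @return log2(TPM + 1) values.
#' @examples
#' counts <- matrix(c(10, 10, 20, 20), 2, dimnames = list(c("a", "b"), NULL))
#' log_tpm(counts, c(a = 1000, b = 1000))
#' @export
log_tpm <- function(counts, lengths, conditions = NULL) {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- genes
  }
  counts <- as.matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(as.numeric(lengths[[2]]),
                               as.character(lengths[[1]]))
  }
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) stop("lengths must be named by gene")
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("no length for gene(s): ", paste(missing, collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) {
    stop("nonpositive length for gene(s): ",
         paste(names(len)[len <= 0], collapse = ", "))
  }
  rate <- counts / len
  depth <- colSums(rate)
  zero <- depth == 0
  if (any(zero)) {
    bad <- colnames(counts)[zero]
    if (is.null(bad)) bad <- which(zero)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  tpm <- sweep(rate, 2, depth, "/") * 1e6
  out <- log2(tpm + 1)
  if (is.null(conditions)) return(out)
  expression_matrix(out, conditions)
}

#' Correlation distance between two expression profiles
#'
#' `d = 1 - |rho|` with `rho` the Pearson correlation, so that both strong
#' positive and strong negative co-expression give a small distance (a
#' negative correlation is as biologically relevant as a positive one,
#' e.g. when one gene inhibits another). If either profile has zero
#' variance the correlation is undefined; the distance is set to 1 with a
#' warning, so an uninformative gene never creates early connectivity.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a distance in `[0, 1]` (clamped at tolerance 1e-12).
#' @examples
#' correlation_distance(1:4, c(4, 3, 2, 1))  # perfect anti-correlation -> 0
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("correlation needs at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance profile: correlation undefined, distance set to 1")
    return(1)
  }
  d <- 1 - abs(stats::cor(x, y))
  min(max(d, 0), 1)
}

#' Attach condition-specific filtration weights to pathway edges
#'
#' Restricts the expression matrix to one condition's samples, drops
#' pathway genes without a measured profile (recorded on the result), and
#' weights every remaining edge by the correlation distance `1 - |rho|`
#' between its endpoint genes' profiles. Both orientations of a mutual
#' edge pair receive the same weight.
#'
#' @param network a [pathway_network()].
#' @param expr an [expression_matrix()].
#' @param condition one of the two condition labels in `expr`.
#' @return a `filtered_digraph`: the pruned network plus a `distance`
#'   column on its edge table; attribute `dropped_genes` records removals.
#' @export
weight_edges <- function(network, expr, condition) {
  stopifnot(inherits(network, "pathway_network"),
            inherits(expr, "expression_matrix"))
  if (!condition %in% expr$conditions) {
    stop("condition not present in the sample map: ", condition)
  }
  samples <- names(expr$conditions)[expr$conditions == condition]
  vals <- expr$values[, samples, drop = FALSE]

  measured <- intersect(network$nodes, rownames(vals))
  dropped <- setdiff(network$nodes, measured)
  if (length(dropped)) {
    message(sprintf("dropping %d unmeasured gene(s): %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  }
  edges <- dplyr::filter(network$edges,
                         .data$source %in% measured,
                         .data$target %in% measured)
  net <- pathway_network(edges, nodes = measured,
                         pathway_id = network$pathway_id, name = network$name)

  if (nrow(net$edges)) {
    sds <- apply(vals[unique(c(net$edges$source, net$edges$target)), ,
                      drop = FALSE], 1, stats::sd)
    flat <- names(sds)[sds == 0]
    # one unordered-pair key per mutual edge pair -> identical weight
    a <- pmin(net$edges$source, net$edges$target)
    b <- pmax(net$edges$source, net$edges$target)
    key <- paste(a, b, sep = "\r")
    uk <- !duplicated(key)
    dist_of <- vapply(which(uk), function(i) {
      if (a[i] %in% flat || b[i] %in% flat) return(1)
      d <- 1 - abs(stats::cor(vals[a[i], ], vals[b[i], ]))
      min(max(d, 0), 1)
    }, numeric(1))
    names(dist_of) <- key[uk]
    if (length(flat)) {
      warning("zero-variance profile(s), incident edge distances set to 1: ",
              paste(flat, collapse = ", "))
    }
    net$edges$distance <- unname(dist_of[key])
  } else {
    net$edges$distance <- numeric(0)
  }
  filtered_digraph(net, condition = condition, dropped_genes = dropped)
}

#' Construct a filtered digraph from a network and edge distances
#'
#' A filtered digraph is a pathway network whose every edge carries a
#' distance in `[0, 1]`; the filtration at threshold `f` keeps all nodes
#' and the edges with distance `<= f` (tolerance 1e-12).
#'
#' @param network a [pathway_network()] whose edge table either already has
#'   a `distance` column or is matched against `distances`.
#' @param distances optional data frame (`source`, `target`, `distance`).
#' @param condition condition label carried along for provenance.
#' @param dropped_genes genes removed before weighting (provenance).
#' @return an object of class `filtered_digraph`.
#' @export
filtered_digraph <- function(network, distances = NULL, condition = NA_character_,
                             dropped_genes = character()) {
  stopifnot(inherits(network, "pathway_network"))
  edges <- network$edges
  if (!is.null(distances)) {
    distances <- tibble::as_tibble(distances)
    key <- function(d) paste(d$source, d$target, sep = "\r")
    hit <- match(key(edges), key(distances))
    if (anyNA(hit)) {
      stop("missing distance for edge(s): ",
           paste(paste0(edges$source[is.na(hit)], "->",
                        edges$target[is.na(hit)]), collapse = ", "))
    }
    edges$distance <- distances$distance[hit]
    network$edges <- edges
  }
  if (!"distance" %in% names(edges)) {
    stop("no edge distances supplied")
  }
  if (nrow(edges) && (any(edges$distance < -1e-12) ||
                      any(edges$distance > 1 + 1e-12))) {
    stop("edge distances must lie in [0, 1]")
  }
  network$edges$distance <- pmin(pmax(network$edges$distance, 0), 1)
  structure(list(network = network, condition = condition,
                 dropped_genes = dropped_genes),
            class = "filtered_digraph")
}

#' @export
print.filtered_digraph <- function(x, ...) {
  cat(sprintf("<filtered_digraph> %s condition %s: %d nodes, %d weighted edges\n",
              ifelse(is.na(x$network$pathway_id), "", x$network$pathway_id),
              x$condition, length(x$network$nodes), nrow(x$network$edges)))
  if (nrow(x$network$edges) == 0L) {
    cat("  (empty edge set: Betti curves will be constant)\n")
  }
  invisible(x)
}

#' @method tidy filtered_digraph
#' @export
tidy.filtered_digraph <- function(x, ...) x$network$edges
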
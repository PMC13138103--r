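# Offline fixtures: the 10-gene illustrative network, a synthetic edge
# distance table for it, a correlation-targeted expression simulator, and
# a multi-pathway study generator with planted rewiring effects.

#' The 10-gene illustrative pathway network
#'
#' Ten genes `g1..g10` with two biologically inspired motifs: a canonical
#' feedback cycle `g1 -> g2 -> g3 -> g4 -> g1` and a directional
#' cross-talk (bi-fan) `g6 -> g7`, `g6 -> g8`, `g9 -> g7`, `g9 -> g8`
#' (feed-forward-like regulation onto shared targets). A pendant gene g5
#' hangs off the first cycle and g10 is isolated. With every edge present
#' the network has `beta0 = 3` weak components (`{g1..g5}`, `{g6..g9}`,
#' `{g10}`) and `beta1 = 2` independent directed cycles.
#'
#' @param g5_edge length-2 character vector giving the pendant edge
#'   attaching g5; the default `c("g1", "g5")` is one of the orientations
#'   consistent with the motif picture, and every Betti number above is
#'   invariant to this choice (pendant edges never create or destroy
#'   cycles).
#' @return a [pathway_network()] with 10 nodes and 9 edges.
#' @export
toy_network <- function(g5_edge = c("g1", "g5")) {
  stopifnot(length(g5_edge) == 2L, "g5" %in% g5_edge)
  edges <- tibble::tibble(
    source = c("g1", "g2", "g3", "g4", "g6", "g6", "g9", "g9", g5_edge[1]),
    target = c("g2", "g3", "g4", "g1", "g7", "g8", "g7", "g8", g5_edge[2]),
    relation = "activation"
  )
  pathway_network(edges, nodes = paste0("g", 1:10),
                  pathway_id = "toy", name = "illustrative 10-gene pathway")
}

#' Synthetic edge distances for the illustrative network
#'
#' A deterministic correlation-distance table for [toy_network()]. Only
#' two values are dictated by the motivating illustration (the strongest
#' edge `g9 -> g7` at `d = 0.184` and the weakest at `0.946`); the
#' remaining values are synthetic, chosen so the filtration reproduces the
#' qualitative reference snapshots: at `f = 0.2` only `g9 -> g7` is
#' present (`beta0 = 9`), by `f = 0.4` the bi-fan is complete
#' (`beta0 = 7`, `beta1 = 1`), and by `f = 0.95` the full network has
#' stabilized at `beta0 = 3`, `beta1 = 2`.
#'
#' @param g5_edge as in [toy_network()].
#' @return tibble with columns `source`, `target`, `distance`.
#' @export
toy_edge_weights <- function(g5_edge = c("g1", "g5")) {
  tibble::tibble(
    source = c("g9", "g6", "g6", "g9", "g1", "g2", "g3", "g4", g5_edge[1]),
    target = c("g7", "g7", "g8", "g8", "g2", "g3", "g4", "g1", g5_edge[2]),
    distance = c(0.184, 0.27, 0.33, 0.38, 0.52, 0.61, 0.74, 0.87, 0.946)
  )
}

#' The illustrative network as a filtered digraph
#'
#' Convenience wrapper combining [toy_network()] and [toy_edge_weights()].
#'
#' @param g5_edge as in [toy_network()].
#' @param condition provenance label.
#' @return a [filtered_digraph()].
#' @export
toy_filtration <- function(g5_edge = c("g1", "g5"), condition = "toy") {
  filtered_digraph(toy_network(g5_edge), toy_edge_weights(g5_edge),
                   condition = condition)
}

#' Specify a correlation-targeted expression simulation
#'
#' @param network a [pathway_network()] whose genes are simulated.
#' @param n_samples samples to draw (>= 3; the motivating illustration
#'   used 4, the full study 17 per condition).
#' @param target_correlations optional tibble (`gene1`, `gene2`, `rho`)
#'   of absolute pairwise correlation targets in `[0, 1]`; untargeted
#'   pairs are independent.
#' @param noise_sd standard deviation of independent Gaussian noise added
#'   on top of the correlated signal; positive values attenuate realized
#'   correlations by `1 / (1 + noise_sd^2)`.
#' @param seed optional integer seed.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(network, n_samples = 17, target_correlations = NULL,
                            noise_sd = 0, seed = NULL) {
  stopifnot(inherits(network, "pathway_network"))
  if (n_samples < 3L) stop("n_samples must be >= 3")
  if (!is.null(target_correlations)) {
    target_correlations <- tibble::as_tibble(target_correlations)
    if (any(target_correlations$rho < 0) || any(target_correlations$rho > 1)) {
      stop("target correlations must lie in [0, 1]")
    }
  }
  structure(list(network = network, n_samples = as.integer(n_samples),
                 target_correlations = target_correlations,
                 noise_sd = noise_sd, seed = seed),
            class = "simulation_spec")
}

#' Simulate expression profiles with prescribed pairwise correlations
#'
#' Draws one condition's gene profiles from a multivariate normal whose
#' correlation matrix carries the requested `|rho|` targets (positive
#' sign convention; the downstream distance `1 - |rho|` is sign-blind).
#' Realized correlations converge to the targets as `n_samples` grows.
#'
#' @param spec a [simulation_spec()].
#' @param sample_prefix prefix for generated sample ids.
#' @return genes x samples numeric matrix.
#' @export
simulate_expression <- function(spec, sample_prefix = "s") {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  genes <- spec$network$nodes
  G <- length(genes)
  C <- diag(1, G, G)
  dimnames(C) <- list(genes, genes)
  tc <- spec$target_correlations
  if (!is.null(tc) && nrow(tc)) {
    bad <- setdiff(unique(c(tc$gene1, tc$gene2)), genes)
    if (length(bad)) stop("target pair gene(s) not in network: ",
                          paste(bad, collapse = ", "))
    for (i in seq_len(nrow(tc))) {
      C[tc$gene1[i], tc$gene2[i]] <- tc$rho[i]
      C[tc$gene2[i], tc$gene1[i]] <- tc$rho[i]
    }
  }
  # allow exactly-singular targets (e.g. |rho| = 1) but reject genuinely
  # indefinite ones; a tiny ridge keeps the Cholesky factor computable
  min_eig <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig < -1e-8) {
    stop("target correlation structure is not positive definite; ",
         "relax the targets", call. = FALSE)
  }
  ridge <- max(0, -min_eig) + 1e-10
  R <- chol(C + diag(ridge, G))
  Z <- matrix(stats::rnorm(spec$n_samples * G), spec$n_samples, G) %*% R
  X <- t(Z)
  if (spec$noise_sd > 0) {
    X <- X + spec$noise_sd * matrix(stats::rnorm(length(X)), nrow(X))
  }
  dimnames(X) <- list(genes, paste0(sample_prefix, seq_len(spec$n_samples)))
  X
}

#' Simulate a two-condition expression study on a set of genes
#'
#' Draws independent condition-specific sample blocks with (possibly
#' different) correlation targets and returns them as one
#' [expression_matrix()].
#'
#' @param network a [pathway_network()] (or a network whose node set
#'   covers all pathways under study).
#' @param targets named list of two target tibbles (see
#'   [simulation_spec()]), one per condition; names become the condition
#'   labels (default `C` and `D`).
#' @param n_samples samples per condition (default 17, the reference
#'   study's size).
#' @param noise_sd as in [simulation_spec()].
#' @param seed optional integer seed.
#' @return an [expression_matrix()].
#' @export
simulate_study <- function(network, targets = list(C = NULL, D = NULL),
                           n_samples = 17, noise_sd = 0, seed = NULL) {
  stopifnot(length(targets) == 2L, !is.null(names(targets)))
  if (!is.null(seed)) set.seed(seed)
  labels <- names(targets)
  blocks <- lapply(seq_along(targets), function(i) {
    spec <- simulation_spec(network, n_samples = n_samples,
                            target_correlations = targets[[i]],
                            noise_sd = noise_sd)
    simulate_expression(spec, sample_prefix = paste0(labels[i], "_"))
  })
  values <- do.call(cbind, blocks)
  conditions <- stats::setNames(rep(labels, each = n_samples),
                                colnames(values))
  expression_matrix(values, conditions)
}

#' Simulate a multi-pathway study with planted topology rewiring
#'
#' Generates `n_pathways` small directed pathway networks, each containing
#' a directed feedback cycle so both homology dimensions are informative.
#' In "null" pathways both conditions share tight within-pathway
#' co-regulation (`|rho| = 0.9`), so their condition-specific filtrations
#' agree up to small sampling noise; in the `n_planted` rewired pathways
#' the disease condition keeps the tight co-expression (`|rho| = 0.9`)
#' while the control condition's genes are nearly independent
#' (`|rho| = 0.05`), so edges (and the cycle) assemble much earlier in the
#' disease filtration. Stable nulls are essential for the benchmark to
#' measure rewiring recovery rather than finite-sample correlation noise:
#' the sampling noise of a realized correlation scales as
#' `(1 - rho^2) / sqrt(n - 1)` and is smallest for tight modules.
#'
#' @param n_pathways total number of pathways (default 20).
#' @param n_planted number of rewired pathways (default 5).
#' @param n_genes genes per pathway (>= 5, default 8).
#' @param n_samples samples per condition (default 17).
#' @param seed optional integer seed.
#' @return list with `networks` (named list of [pathway_network()]),
#'   `expression` (an [expression_matrix()] over all genes) and
#'   `planted` (character vector of rewired pathway ids).
#' @export
simulate_pathway_study <- function(n_pathways = 20, n_planted = 5,
                                   n_genes = 8, n_samples = 17, seed = NULL) {
  stopifnot(n_planted <= n_pathways, n_genes >= 5L)
  if (!is.null(seed)) set.seed(seed)
  planted <- sprintf("pw%02d", seq_len(n_planted))
  ids <- sprintf("pw%02d", seq_len(n_pathways))

  networks <- list()
  all_targets_c <- list()
  all_targets_d <- list()
  for (k in seq_len(n_pathways)) {
    genes <- sprintf("%s_g%d", ids[k], seq_len(n_genes))
    # a directed 4-cycle on the first four genes plus random extra edges
    cyc <- tibble::tibble(source = genes[c(1, 2, 3, 4)],
                          target = genes[c(2, 3, 4, 1)])
    extra <- tibble::tibble(
      source = sample(genes, n_genes, replace = TRUE),
      target = sample(genes, n_genes, replace = TRUE)
    )
    extra <- extra[extra$source != extra$target, , drop = FALSE]
    net <- pathway_network(dplyr::bind_rows(cyc, extra), nodes = genes,
                           pathway_id = ids[k])
    networks[[ids[k]]] <- net
    # compound-symmetric targets within the pathway (always positive
    # definite for 0 <= rho < 1), so cross-condition rewiring changes the
    # filtration globally for the pathway
    idx <- t(utils::combn(genes, 2))
    pairs <- tibble::tibble(gene1 = idx[, 1], gene2 = idx[, 2])
    if (ids[k] %in% planted) {
      all_targets_c[[k]] <- dplyr::mutate(pairs, rho = 0.05)
      all_targets_d[[k]] <- dplyr::mutate(pairs, rho = 0.9)
    } else {
      # stable nulls: tight co-regulation in both conditions keeps the
      # realized-correlation sampling noise (sd ~ (1 - rho^2)/sqrt(n - 1))
      # small, so a null pathway's two filtrations genuinely agree
      stable <- dplyr::mutate(pairs, rho = 0.9)
      all_targets_c[[k]] <- stable
      all_targets_d[[k]] <- stable
    }
  }
  all_genes <- unlist(lapply(networks, function(n) n$nodes), use.names = FALSE)
  union_net <- pathway_network(
    dplyr::bind_rows(lapply(networks, function(n) n$edges)),
    nodes = all_genes
  )
  expr <- simulate_study(
    union_net,
    targets = list(C = dplyr::bind_rows(all_targets_c),
                   D = dplyr::bind_rows(all_targets_d)),
    n_samples = n_samples
  )
  list(networks = networks, expression = expr, planted = planted)
}
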
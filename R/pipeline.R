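# End-to-end workflow: (I) integrate expression and pathway networks,
# (II) compute persistent path homology per pathway and condition,
# (III) identify key pathways by global and per-pathway permutation
# statistics.

#' Run the full persistent path homology workflow
#'
#' For every pathway and condition: weight the edges by correlation
#' distance, compute Betti curves, barcodes and landscapes; then run the
#' global landscape permutation test per dimension and the per-pathway
#' KS / Cohen's d permutation tests with BH correction and the four-test
#' significance rule.
#'
#' @param expression an [expression_matrix()], or a genes x samples data
#'   frame / matrix combined with `conditions`.
#' @param pathways a named list of [pathway_network()] objects, a single
#'   network, or a directory containing KGML (`.xml`/`.kgml`) and/or edge
#'   list (`.tsv`) files.
#' @param conditions sample -> condition map, required when `expression`
#'   is not already an [expression_matrix()].
#' @param step filtration step (default 0.01).
#' @param dimensions homology dimensions (default `c(0, 1)`).
#' @param norms landscape norms for the global test.
#' @param n_perm_global permutations for the global landscape test
#'   (default 1000).
#' @param n_perm_pathway permutations per pathway-level test (default
#'   5000).
#' @param alpha FDR threshold for the four-test rule (default 0.05).
#' @param seed integer seed; all randomness flows from one generator so a
#'   rerun with the same config is bit-identical.
#' @param out_dir optional output directory; when given, Betti curves,
#'   barcodes, pathway results and the global test are written as CSV plus
#'   a JSON run summary.
#' @param barcode_method passed to [persistence_pairs()].
#' @return an object of class `pph_result`: list with `curves`,
#'   `barcodes`, `landscapes`, `global`, `pathway_tests`, `skipped`,
#'   `config`.
#' @export
run_pph <- function(expression, pathways, conditions = NULL,
                    step = 0.01, dimensions = c(0L, 1L),
                    norms = c("sup", "one", "two"),
                    n_perm_global = 1000, n_perm_pathway = 5000,
                    alpha = 0.05, seed = NULL, out_dir = NULL,
                    barcode_method = "rank") {
  if (!inherits(expression, "expression_matrix")) {
    if (is.null(conditions)) {
      stop("`conditions` is required when `expression` is a plain table")
    }
    expression <- expression_matrix(expression, conditions)
  }
  if (inherits(pathways, "pathway_network")) pathways <- list(pathways)
  if (is.character(pathways) && length(pathways) == 1L) {
    pathways <- read_pathway_dir(pathways)
  }
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    names(pathways) <- vapply(seq_along(pathways), function(i) {
      id <- pathways[[i]]$pathway_id
      if (is.na(id)) sprintf("pathway%03d", i) else id
    }, "")
  }
  if (length(pathways) < 1L) stop("at least one pathway is required")
  if (!is.null(seed)) set.seed(seed)

  labels <- unique(expression$conditions)
  cond_c <- labels[1]; cond_d <- labels[2]

  curves <- list(); barcodes <- list()
  landscapes <- list()
  skipped <- character(0)
  for (id in names(pathways)) {
    net <- pathways[[id]]
    net$pathway_id <- if (is.na(net$pathway_id)) id else net$pathway_id
    measured <- intersect(net$nodes, rownames(expression$values))
    if (length(measured) < 2L) {
      message("skipping pathway with <2 measured genes: ", id)
      skipped <- c(skipped, id)
      next
    }
    for (cond in labels) {
      fg <- suppressMessages(weight_edges(net, expression, cond))
      cv <- betti_curve(fg, step = step)
      curves[[paste(id, cond)]] <- cv
      for (dm in dimensions) {
        bc <- persistence_pairs(fg, dimension = dm, step = step,
                                method = barcode_method)
        barcodes[[paste(id, cond, dm)]] <- bc
        landscapes[[as.character(dm)]][[cond]][[id]] <-
          landscape(bc, step = step, dimension = dm)
      }
    }
  }
  if (length(curves) == 0L) stop("no pathway had enough measured genes")

  global <- purrr::map_dfr(as.character(dimensions), function(dm) {
    global_permutation_test(
      landscapes[[dm]][[cond_c]], landscapes[[dm]][[cond_d]],
      n_perm = n_perm_global, norms = norms
    )
  })

  pathway_tests <- purrr::map_dfr(names(pathways), function(id) {
    if (id %in% skipped) return(NULL)
    compare_pathway(curves[[paste(id, cond_c)]], curves[[paste(id, cond_d)]],
                    dimensions = dimensions, n_perm = n_perm_pathway)
  })
  pathway_tests <- pathway_significance(pathway_tests, alpha = alpha)

  curve_tbl <- purrr::map_dfr(curves, function(cv) {
    dplyr::mutate(tibble::as_tibble(cv),
                  pathway_id = attr(cv, "pathway_id"),
                  condition = attr(cv, "condition"), .before = 1)
  })
  barcode_tbl <- purrr::map_dfr(barcodes, function(bc) {
    dplyr::mutate(tibble::as_tibble(bc),
                  pathway_id = attr(bc, "pathway_id"),
                  condition = attr(bc, "condition"), .before = 1)
  })

  config <- list(step = step, dimensions = as.integer(dimensions),
                 norms = norms, n_perm_global = as.integer(n_perm_global),
                 n_perm_pathway = as.integer(n_perm_pathway), alpha = alpha,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 conditions = stats::setNames(c(cond_c, cond_d),
                                              c("control", "disease")),
                 barcode_method = barcode_method)
  result <- structure(
    list(curves = curve_tbl, barcodes = barcode_tbl, landscapes = landscapes,
         global = global, pathway_tests = pathway_tests,
         skipped = skipped, config = config),
    class = "pph_result"
  )
  if (!is.null(out_dir)) write_pph_result(result, out_dir)
  result
}

read_pathway_dir <- function(dir) {
  if (!dir.exists(dir)) stop("pathway directory not found: ", dir)
  kgml <- list.files(dir, "\\.(xml|kgml)$", full.names = TRUE)
  tsv <- list.files(dir, "\\.tsv$", full.names = TRUE)
  nets <- c(lapply(kgml, parse_kgml), lapply(tsv, read_edge_list))
  if (length(nets) == 0L) stop("no KGML or edge-list files in ", dir)
  names(nets) <- vapply(seq_along(nets), function(i) {
    id <- nets[[i]]$pathway_id
    if (is.na(id)) tools::file_path_sans_ext(basename(c(kgml, tsv)[i])) else id
  }, "")
  nets
}

write_pph_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$curves, file.path(out_dir, "betti_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(result$barcodes, file.path(out_dir, "barcodes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$global, file.path(out_dir, "global_test.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pathway_tests,
                   file.path(out_dir, "pathway_tests.csv"), row.names = FALSE)
  summary <- list(
    config = result$config,
    skipped = result$skipped,
    significant = unique(result$pathway_tests$pathway_id[
      result$pathway_tests$significant])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pph_result <- function(x, ...) {
  sig <- unique(x$pathway_tests$pathway_id[x$pathway_tests$significant])
  cat(sprintf("<pph_result> %d pathway(s), conditions %s vs %s\n",
              dplyr::n_distinct(x$pathway_tests$pathway_id),
              x$config$conditions[["control"]],
              x$config$conditions[["disease"]]))
  cat(sprintf("  global test: min q = %.4g\n", min(x$global$q)))
  cat(sprintf("  significant pathways (all four q < %.2f): %d%s\n",
              x$config$alpha, length(sig),
              if (length(sig)) paste0(" [", paste(sig, collapse = ", "), "]")
              else ""))
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a workflow result into the per-pathway test table
#'
#' @param x a `pph_result`.
#' @param ... unused.
#' @return the per-pathway statistics tibble (one row per pathway and
#'   dimension).
#' @method tidy pph_result
#' @export
tidy.pph_result <- function(x, ...) tibble::as_tibble(x$pathway_tests)

#' One-row summary of a workflow result
#'
#' @param x a `pph_result`.
#' @param ... unused.
#' @return tibble with pathway counts and the global-test minimum q.
#' @method glance pph_result
#' @export
glance.pph_result <- function(x, ...) {
  tibble::tibble(
    n_pathways = dplyr::n_distinct(x$pathway_tests$pathway_id),
    n_skipped = length(x$skipped),
    n_significant = dplyr::n_distinct(
      x$pathway_tests$pathway_id[x$pathway_tests$significant]),
    global_min_q = min(x$global$q),
    seed = x$config$seed
  )
}
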
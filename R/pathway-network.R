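#' Construct a directed pathway network
#'
#' A pathway network is a directed gene-interaction graph: a set of gene
#' symbols (nodes) and directed edges labelled by their interaction type.
#' Invariants enforced on construction: no self-loops (dropped with a
#' warning), unique nodes, every edge endpoint a node, and no duplicate
#' (source, target) pairs (relation labels are merged on collision).
#'
#' @param edges data frame with columns `source`, `target` and optionally
#'   `relation` (one of `"activation"`, `"inhibition"`, `"other"`; anything
#'   else is collapsed to `"other"`).
#' @param nodes optional character vector of node symbols; defaults to the
#'   symbols appearing in `edges`. Extra symbols give isolated nodes.
#' @param pathway_id,name optional identifiers (e.g. `"hsa04115"`).
#' @return an object of class `pathway_network` with fields `nodes`
#'   (character) and `edges` (tibble `source`, `target`, `relation`).
#' @examples
#' net <- pathway_network(data.frame(source = "a", target = "b"))
#' net
#' @export
pathway_network <- function(edges = NULL, nodes = NULL,
                            pathway_id = NA_character_, name = NA_character_) {
  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            relation = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    stop("`edges` must have columns `source` and `target`")
  }
  if (!"relation" %in% names(edges)) edges$relation <- "other"
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$relation <- normalize_relation(edges$relation)

  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s): %s", sum(loops),
                    paste(unique(edges$source[loops]), collapse = ", ")))
    edges <- edges[!loops, , drop = FALSE]
  }
  edges <- merge_duplicate_edges(edges)

  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    warning("duplicate node symbols collapsed")
    nodes <- unique(nodes)
  }
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(missing)) {
    stop("edge endpoints not in `nodes`: ", paste(missing, collapse = ", "))
  }

  structure(
    list(nodes = nodes, edges = edges,
         pathway_id = pathway_id, name = name),
    class = "pathway_network"
  )
}

normalize_relation <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "other"
  keep <- x %in% c("activation", "inhibition")
  # compound labels like "activation/inhibition" survive merging
  keep <- keep | grepl("/", x, fixed = TRUE)
  x[!keep] <- "other"
  x
}

merge_duplicate_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  key <- paste(edges$source, edges$target, sep = "\r")
  merged <- vapply(split(edges$relation, key), merge_relation_labels, "")
  first <- !duplicated(key)
  out <- edges[first, , drop = FALSE]
  out$relation <- unname(merged[key[first]])
  out
}

merge_relation_labels <- function(labels) {
  u <- sort(unique(unlist(strsplit(labels, "/", fixed = TRUE))))
  u <- u[u != "other" | length(u) == 1L]
  if (length(u) == 0L) u <- "other"
  paste(u, collapse = "/")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %s%s: %d nodes, %d directed edges\n",
              ifelse(is.na(x$pathway_id), "", paste0(x$pathway_id, " ")),
              ifelse(is.na(x$name), "", paste0("(", x$name, ")")),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
format.pathway_network <- function(x, ...) {
  sprintf("pathway_network(%d nodes, %d edges)", length(x$nodes), nrow(x$edges))
}

#' Tidy a pathway network into its edge table
#'
#' @param x a [pathway_network()].
#' @param ... unused.
#' @return a tibble with columns `source`, `target`, `relation`.
#' @method tidy pathway_network
#' @export
tidy.pathway_network <- function(x, ...) x$edges

#' Expand group nodes into their member genes
#'
#' KEGG pathways may contain nodes that stand for a group of genes with a
#' shared function. Each group node is replaced by its member genes, and
#' every edge incident to the group is duplicated onto every member, so
#' that each separated gene keeps all interactions of the original group.
#'
#' @param network a [pathway_network()] whose nodes may include group ids.
#' @param groups named list: group node id -> character vector of member
#'   gene symbols (each group must have at least one member).
#' @return a [pathway_network()] without group nodes.
#' @examples
#' net <- pathway_network(data.frame(source = c("x", "G"), target = c("G", "y")))
#' expand_group_nodes(net, list(G = c("g1", "g2")))
#' @export
expand_group_nodes <- function(network, groups) {
  stopifnot(inherits(network, "pathway_network"))
  if (length(groups) == 0L) return(network)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("`groups` must be a named list (group node -> members)")
  }
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty)) stop("empty group(s): ", paste(empty, collapse = ", "))

  edges <- network$edges
  nodes <- network$nodes
  for (g in names(groups)) {
    members <- as.character(groups[[g]])
    collide <- intersect(members, setdiff(nodes, g))
    if (length(collide)) {
      warning("group member(s) already present as nodes; merging: ",
              paste(collide, collapse = ", "))
    }
    # duplicate incident edges onto every member
    if (nrow(edges)) {
      src_rows <- edges$source == g
      if (any(src_rows)) {
        dup <- edges[rep(which(src_rows), each = length(members)), ]
        dup$source <- rep(members, times = sum(src_rows))
        edges <- dplyr::bind_rows(edges[!src_rows, , drop = FALSE], dup)
      }
      tgt_rows <- edges$target == g
      if (any(tgt_rows)) {
        dup <- edges[rep(which(tgt_rows), each = length(members)), ]
        dup$target <- rep(members, times = sum(tgt_rows))
        edges <- dplyr::bind_rows(edges[!tgt_rows, , drop = FALSE], dup)
      }
    }
    nodes <- unique(c(setdiff(nodes, g), members))
  }
  pathway_network(edges, nodes = nodes,
                  pathway_id = network$pathway_id, name = network$name)
}

#' Read a pathway network from an edge list
#'
#' @param x path to a TSV/CSV file with columns `source`, `target` and
#'   optionally `relation`, or a data frame with those columns.
#' @param ... passed to [pathway_network()] (e.g. `pathway_id`).
#' @return a [pathway_network()]; duplicate rows are collapsed, self-loop
#'   rows dropped with a warning.
#' @export
read_edge_list <- function(x, ...) {
  if (is.character(x) && length(x) == 1L) {
    sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- utils::read.delim(x, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("source", "target") %in% names(x))) {
    stop("edge list must have columns `source` and `target`")
  }
  pathway_network(x, ...)
}

#' Write a pathway network as a TSV edge list
#'
#' @param network a [pathway_network()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(network, file) {
  stopifnot(inherits(network, "pathway_network"))
  utils::write.table(network$edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a pathway network from a 0/1 adjacency matrix
#'
#' @param x CSV file with node symbols as row and column labels and entry 1
#'   for a directed edge row -> column, or such a matrix.
#' @param ... passed to [pathway_network()].
#' @return a [pathway_network()] (relation labels are `"other"`).
#' @export
read_adjacency <- function(x, ...) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.matrix(utils::read.csv(x, row.names = 1, check.names = FALSE))
  }
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("adjacency matrix must carry node symbols as dimnames")
  }
  idx <- which(x != 0, arr.ind = TRUE)
  edges <- tibble::tibble(source = rownames(x)[idx[, 1]],
                          target = colnames(x)[idx[, 2]])
  pathway_network(edges, nodes = rownames(x), ...)
}

#' Write a pathway network as a 0/1 adjacency matrix
#'
#' @param network a [pathway_network()].
#' @param file output CSV path; if `NULL` the matrix is returned.
#' @return the adjacency matrix, invisibly when written to file.
#' @export
write_adjacency <- function(network, file = NULL) {
  stopifnot(inherits(network, "pathway_network"))
  n <- length(network$nodes)
  A <- matrix(0L, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges)) {
    A[cbind(match(network$edges$source, network$nodes),
            match(network$edges$target, network$nodes))] <- 1L
  }
  if (is.null(file)) return(A)
  utils::write.csv(as.data.frame(A), file, quote = FALSE)
  invisible(A)
}
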
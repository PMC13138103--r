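# KGML (KEGG Markup Language) input and a minimal writer used to build
# offline fixtures. Only gene-type entries become nodes; compounds, maps
# and orthologs are dropped. Multi-gene entries and <entry type="group">
# elements are separated into individual gene nodes, each keeping every
# edge of the original entry.

#' Parse a KGML pathway document
#'
#' Reads a KEGG Markup Language file (or XML string) into a
#' [pathway_network()]. Gene entries contribute nodes; `relation` elements
#' between gene entries contribute directed edges. KGML relation subtypes
#' map to `"activation"` and `"inhibition"`; every other subtype (binding,
#' expression, indirect effect, ...) collapses to `"other"`. Entries that
#' name several genes, and group entries, are separated into individual
#' gene nodes while keeping all edges of the original entry.
#'
#' @param x path to a KGML file, a KGML string, or an `xml_document`.
#' @param id_map optional two-column data frame (`kegg_id`, `symbol`)
#'   translating KEGG gene identifiers (e.g. `"hsa:7157"`) to gene symbols.
#'   Unmapped identifiers keep their raw id (reported via a message).
#' @return a [pathway_network()] with `pathway_id` and `name` taken from the
#'   document's `<pathway>` attributes.
#' @export
parse_kgml <- function(x, id_map = NULL) {
  doc <- tryCatch({
    if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  }, error = function(e) {
    stop("malformed KGML document: ", conditionMessage(e), call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) {
    stop("malformed KGML document: missing <pathway> root element")
  }
  pathway_id <- sub("^path:", "", xml2::xml_attr(root, "name"))
  title <- xml2::xml_attr(root, "title")

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")

  map_id <- function(ids) {
    if (is.null(id_map)) return(ids)
    id_map <- as.data.frame(id_map)
    hit <- match(ids, id_map[[1]])
    unmapped <- ids[is.na(hit)]
    if (length(unmapped)) {
      message("unmapped KEGG id(s) kept as-is: ",
              paste(unique(unmapped), collapse = ", "))
    }
    ifelse(is.na(hit), ids, as.character(id_map[[2]][hit]))
  }

  # gene entries: one or more whitespace-separated gene ids per entry
  genes_of <- stats::setNames(vector("list", length(entries)), entry_id)
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "gene")) {
      ids <- strsplit(trimws(entry_name[i]), "\\s+")[[1]]
      genes_of[[i]] <- map_id(ids)
    }
  }
  # group entries: union of their component entries' genes
  for (i in seq_along(entries)) {
    if (identical(entry_type[i], "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "component"),
                             "id")
      genes_of[[i]] <- unique(unlist(genes_of[comp]))
    }
  }

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  edge_rows <- vector("list", length(rels))
  for (i in seq_along(rels)) {
    e1 <- xml2::xml_attr(rels[[i]], "entry1")
    e2 <- xml2::xml_attr(rels[[i]], "entry2")
    unknown <- setdiff(c(e1, e2), entry_id)
    if (length(unknown)) {
      stop("relation references unknown entry id(s): ",
           paste(unknown, collapse = ", "))
    }
    src <- genes_of[[e1]]
    tgt <- genes_of[[e2]]
    if (is.null(src) || is.null(tgt)) next  # non-gene endpoint: drop
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rels[[i]], "subtype"),
                               "name")
    rel <- if ("activation" %in% subtypes) "activation"
           else if ("inhibition" %in% subtypes) "inhibition"
           else "other"
    edge_rows[[i]] <- tidyr::expand_grid(source = src, target = tgt) |>
      dplyr::mutate(relation = rel)
  }
  edges <- dplyr::bind_rows(edge_rows)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(source = character(), target = character(),
                            relation = character())
  }
  nodes <- unique(unlist(genes_of))
  if (is.null(nodes)) nodes <- character()
  pathway_network(edges, nodes = nodes, pathway_id = pathway_id, name = title)
}

#' Write a minimal KGML fixture for a pathway network
#'
#' Emits a small, valid KGML document that [parse_kgml()] inverts (node and
#' edge sets round-trip exactly). When a `groups` map is given, the group
#' nodes are written as KGML `<entry type="group">` elements with component
#' references, so that parsing reproduces the group-expanded network.
#'
#' @param network a [pathway_network()]; node symbols are written verbatim
#'   as entry names.
#' @param file output path; if `NULL`, the KGML text is returned.
#' @param groups optional named list (group node -> member symbols) as in
#'   [expand_group_nodes()].
#' @return the KGML text (invisibly when written to `file`).
#' @export
write_kgml <- function(network, file = NULL, groups = NULL) {
  stopifnot(inherits(network, "pathway_network"))
  group_nodes <- names(groups)
  gene_nodes <- setdiff(network$nodes, group_nodes)
  members <- unique(unlist(groups))
  gene_nodes <- unique(c(gene_nodes, members))

  ids <- stats::setNames(seq_along(c(gene_nodes, group_nodes)),
                         c(gene_nodes, group_nodes))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<pathway name="path:%s" org="hsa" number="0" title="%s">',
            esc(ifelse(is.na(network$pathway_id), "hsa00000",
                       network$pathway_id)),
            esc(ifelse(is.na(network$name), "fixture", network$name)))
  )
  for (g in gene_nodes) {
    lines <- c(lines, sprintf('  <entry id="%d" name="%s" type="gene"/>',
                              ids[[g]], esc(g)))
  }
  for (g in group_nodes) {
    comp <- paste(sprintf('<component id="%d"/>', ids[groups[[g]]]),
                  collapse = "")
    lines <- c(lines, sprintf('  <entry id="%d" name="undefined" type="group">%s</entry>',
                              ids[[g]], comp))
  }
  if (nrow(network$edges)) {
    for (i in seq_len(nrow(network$edges))) {
      rel <- strsplit(network$edges$relation[i], "/", fixed = TRUE)[[1]]
      subs <- paste(sprintf('<subtype name="%s" value="--"/>', esc(rel)),
                    collapse = "")
      lines <- c(lines, sprintf(
        '  <relation entry1="%d" entry2="%d" type="PPrel">%s</relation>',
        ids[[network$edges$source[i]]], ids[[network$edges$target[i]]], subs))
    }
  }
  lines <- c(lines, "</pathway>")
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
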
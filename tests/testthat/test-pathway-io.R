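# Reading pathway networks from KGML, edge lists and adjacency matrices.

kgml_three_genes <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:hsa99999" org="hsa" number="99999" title="fixture">\n',
    '  <entry id="1" name="A" type="gene"/>\n',
    '  <entry id="2" name="B" type="gene"/>\n',
    '  <entry id="3" name="C" type="gene"/>\n',
    '  <entry id="4" name="cpd:C00001" type="compound"/>\n',
    '  <relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>\n',
    '  <relation entry1="2" entry2="3" type="PPrel">',
    '<subtype name="inhibition" value="--|"/></relation>\n',
    '  <relation entry1="1" entry2="4" type="PCrel"/>\n',
    '  <relation entry1="4" entry2="3" type="PCrel"/>\n',
    "</pathway>\n"
  )
}

test_that("parse_kgml maps gene entries and labelled relations", {
  net <- parse_kgml(kgml_three_genes())
  expect_s3_class(net, "pathway_network")
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$relation[net$edges$source == "A"], "activation")
  expect_equal(net$edges$relation[net$edges$source == "B"], "inhibition")
  expect_equal(net$pathway_id, "hsa99999")
})

test_that("parse_kgml drops compound-mediated relations entirely", {
  net <- parse_kgml(kgml_three_genes())
  # the A -> compound -> C chain must not produce any gene-gene edge
  expect_false(any(net$edges$source == "A" & net$edges$target == "C"))
})

test_that("parse_kgml discards self-loop relations with a warning", {
  kgml <- paste0(
    '<pathway name="path:x" title="t">',
    '<entry id="1" name="A" type="gene"/>',
    '<relation entry1="1" entry2="1" type="PPrel"/>',
    "</pathway>"
  )
  expect_warning(net <- parse_kgml(kgml), "self-loop")
  expect_equal(nrow(net$edges), 0L)
})

test_that("parse_kgml errors on malformed XML and unknown entry ids", {
  expect_error(parse_kgml("<pathway><entry></pathway>"), "malformed")
  kgml <- paste0(
    '<pathway name="path:x" title="t">',
    '<entry id="1" name="A" type="gene"/>',
    '<relation entry1="1" entry2="77" type="PPrel"/>',
    "</pathway>"
  )
  expect_error(parse_kgml(kgml), "77")
})

test_that("parse_kgml applies an id map and keeps unmapped ids", {
  kgml <- paste0(
    '<pathway name="path:x" title="t">',
    '<entry id="1" name="hsa:7157" type="gene"/>',
    '<entry id="2" name="hsa:581" type="gene"/>',
    '<entry id="3" name="hsa:999999" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--&gt;"/></relation>',
    "</pathway>"
  )
  map <- data.frame(kegg_id = c("hsa:7157", "hsa:581"),
                    symbol = c("TP53", "BAX"))
  expect_message(net <- parse_kgml(kgml, id_map = map), "unmapped")
  expect_setequal(net$nodes, c("TP53", "BAX", "hsa:999999"))
  expect_equal(net$edges$source, "TP53")
  expect_equal(net$edges$target, "BAX")
})

test_that("group nodes are separated with all edges kept on every member", {
  # X -> G duplicates onto both members
  net <- pathway_network(data.frame(source = "X", target = "G"))
  out <- expand_group_nodes(net, list(G = c("g1", "g2")))
  expect_setequal(paste(out$edges$source, out$edges$target),
                  c("X g1", "X g2"))

  # G -> Y and Z -> G give the four expanded edges
  net2 <- pathway_network(data.frame(source = c("G", "Z"),
                                     target = c("Y", "G")))
  out2 <- expand_group_nodes(net2, list(G = c("a", "b")))
  expect_setequal(paste(out2$edges$source, out2$edges$target),
                  c("a Y", "b Y", "Z a", "Z b"))

  # singleton group is a pure rename
  net3 <- pathway_network(data.frame(source = "X", target = "G"))
  out3 <- expand_group_nodes(net3, list(G = "g"))
  expect_equal(out3$edges$source, "X")
  expect_equal(out3$edges$target, "g")

  expect_error(expand_group_nodes(net, list(G = character())), "empty")
  # member colliding with an existing node: merge warning, and the induced
  # X -> X self-loop is dropped per the network invariants
  expect_warning(
    expect_warning(expand_group_nodes(net, list(G = c("X", "g1"))),
                   "merging"),
    "self-loop"
  )
})

test_that("expand_group_nodes never decreases the edge count", {
  set.seed(71)
  for (i in 1:20) {
    g <- random_digraph(5, 0.4)
    net <- pathway_network(g$edges, nodes = g$nodes)
    grp <- list(v1 = c("m1", "m2", "m3"))
    out <- expand_group_nodes(net, grp)
    expect_gte(nrow(out$edges), nrow(net$edges))
  }
})

test_that("edge lists round-trip and deduplicate", {
  net <- read_edge_list(data.frame(source = c("a", "b", "a"),
                                   target = c("b", "c", "b")))
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$nodes, c("a", "b", "c"))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tf)
  back <- read_edge_list(tf)
  expect_equal(back$edges, net$edges)

  expect_error(read_edge_list(data.frame(from = "a", to = "b")), "source")
  expect_warning(
    read_edge_list(data.frame(source = c("a", "a"), target = c("a", "b"))),
    "self-loop"
  )
})

test_that("adjacency matrices round-trip through edge lists", {
  set.seed(5)
  for (i in 1:10) {
    g <- random_digraph(4, 0.5)
    net <- pathway_network(g$edges, nodes = g$nodes)
    tf <- withr::local_tempfile(fileext = ".csv")
    write_adjacency(net, tf)
    back <- read_adjacency(tf)
    expect_setequal(back$nodes, net$nodes)
    expect_setequal(paste(back$edges$source, back$edges$target),
                    paste(net$edges$source, net$edges$target))
  }
})

test_that("KGML fixtures written by the package parse back identically", {
  toy <- toy_network()
  back <- parse_kgml(write_kgml(toy))
  expect_setequal(back$nodes, toy$nodes)
  expect_setequal(paste(back$edges$source, back$edges$target),
                  paste(toy$edges$source, toy$edges$target))

  # a written group entry parses to the group-expanded network
  net <- pathway_network(data.frame(source = c("X", "G"),
                                    target = c("G", "Y")),
                         nodes = c("X", "G", "Y"))
  txt <- write_kgml(net, groups = list(G = c("g1", "g2")))
  parsed <- parse_kgml(txt)
  expected <- expand_group_nodes(net, list(G = c("g1", "g2")))
  expect_setequal(paste(parsed$edges$source, parsed$edges$target),
                  paste(expected$edges$source, expected$edges$target))

  # edge-free network still yields valid KGML
  lonely <- pathway_network(NULL, nodes = c("a", "b"))
  expect_setequal(parse_kgml(write_kgml(lonely))$nodes, c("a", "b"))
})

test_that("duplicate relation labels merge on edge collision", {
  net <- pathway_network(data.frame(
    source = c("a", "a"), target = c("b", "b"),
    relation = c("activation", "inhibition")
  ))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$relation, "activation/inhibition")
})
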
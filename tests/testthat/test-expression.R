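# TPM transform, correlation distance and edge weighting.

test_that("log_tpm matches hand-computed TPM values", {
  # symmetry: equal counts and lengths split the million evenly
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  out <- log_tpm(counts, c(a = 1000, b = 1000))
  expect_equal(unname(out[, 1]), rep(log2(5e5 + 1), 2))

  # a single gene takes the whole million
  one <- matrix(7, 1, 1, dimnames = list("g", "s1"))
  expect_equal(unname(log_tpm(one, c(g = 500))[1, 1]), log2(1e6 + 1))

  # three genes, unequal lengths: spreadsheet-style recomputation
  counts <- matrix(c(100, 200, 300), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  lengths <- c(a = 1000, b = 2000, c = 500)
  rate <- c(100 / 1000, 200 / 2000, 300 / 500)
  expected <- log2(rate / sum(rate) * 1e6 + 1)
  expect_equal(unname(log_tpm(counts, lengths)[, 1]), unname(expected))
})

test_that("log_tpm rejects zero-length genes and all-zero samples", {
  counts <- matrix(c(1, 0, 2, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(log_tpm(counts, c(a = 0, b = 100)), "nonpositive")
  zero <- matrix(c(1, 1, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(log_tpm(zero, c(a = 10, b = 10)), "empty")
})

test_that("correlation distance is 1 - |rho| with symmetry and affine invariance", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_distance(x, 2 * x + 1), 0)
  expect_equal(correlation_distance(x, -x), 0)  # anti-correlation counts

  y <- c(2, 0, 5, 1)
  expect_equal(correlation_distance(x, y), 1 - abs(stats::cor(x, y)))

  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(correlation_distance(a, b), correlation_distance(b, a))
    expect_equal(correlation_distance(3.2 * a - 7, b),
                 correlation_distance(a, b), tolerance = 1e-12)
  }

  expect_error(correlation_distance(1:3, 1:4), "equal length")
  expect_error(correlation_distance(1:2, 1:2), "at least 3")
  expect_warning(d <- correlation_distance(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(d, 1)
})

make_expr <- function(values, n_c = 4, n_d = 4) {
  samples <- c(paste0("c", seq_len(n_c)), paste0("d", seq_len(n_d)))
  colnames(values) <- samples
  expression_matrix(values, setNames(rep(c("C", "D"), c(n_c, n_d)), samples))
}

test_that("weight_edges computes per-pair distances from one condition only", {
  set.seed(8)
  genes <- c("a", "b", "c")
  vals <- matrix(rnorm(24), 3, 8, dimnames = list(genes, NULL))
  expr <- make_expr(vals)
  net <- pathway_network(data.frame(source = c("a", "b"),
                                    target = c("b", "c")))
  fg <- weight_edges(net, expr, "C")
  # recompute gene-pair by gene-pair from the C columns
  cc <- vals[, 1:4]
  expect_equal(fg$network$edges$distance,
               c(1 - abs(cor(cc["a", ], cc["b", ])),
                 1 - abs(cor(cc["b", ], cc["c", ]))))

  # perturbing the other condition's columns changes nothing
  vals2 <- vals
  vals2[, 5:8] <- rnorm(12)
  fg2 <- weight_edges(net, make_expr(vals2), "C")
  expect_identical(fg$network$edges$distance, fg2$network$edges$distance)
})

test_that("weight_edges drops unmeasured genes and flags empty edge sets", {
  set.seed(9)
  vals <- matrix(rnorm(16), 2, 8, dimnames = list(c("a", "b"), NULL))
  expr <- make_expr(vals)
  net <- pathway_network(data.frame(source = c("a", "x"),
                                    target = c("b", "y")),
                         nodes = c("a", "b", "x", "y"))
  expect_message(fg <- weight_edges(net, expr, "C"), "x, y")
  expect_setequal(fg$dropped_genes, c("x", "y"))
  expect_setequal(fg$network$nodes, c("a", "b"))
  expect_equal(nrow(fg$network$edges), 1L)

  # all pathway edges unmeasured -> valid but empty filtration
  net2 <- pathway_network(data.frame(source = "x", target = "y"))
  expect_message(fg2 <- weight_edges(net2, expr, "C"))
  expect_equal(nrow(fg2$network$edges), 0L)
  cv <- betti_curve(fg2)
  expect_true(all(betti_series(cv, 0) == 0))
})

test_that("mutual edge orientations share one weight and duplicates get d = 1 at zero variance", {
  set.seed(10)
  vals <- matrix(rnorm(24), 3, 8, dimnames = list(c("a", "b", "z"), NULL))
  vals["z", 1:4] <- 5  # zero variance within condition C
  expr <- make_expr(vals)
  net <- pathway_network(data.frame(source = c("a", "b", "a"),
                                    target = c("b", "a", "z")))
  expect_warning(fg <- weight_edges(net, expr, "C"), "zero-variance")
  e <- fg$network$edges
  expect_equal(e$distance[e$source == "a" & e$target == "b"],
               e$distance[e$source == "b" & e$target == "a"])
  expect_equal(e$distance[e$target == "z"], 1)
})

test_that("identical profiles give zero distances everywhere", {
  vals <- matrix(rep(c(1, 3, 2, 5, 4, 6, 7, 8), each = 3), 3, 8, byrow = FALSE,
                 dimnames = list(c("a", "b", "c"), NULL))
  expr <- make_expr(vals)
  net <- pathway_network(data.frame(source = c("a", "b"),
                                    target = c("b", "c")))
  fg <- weight_edges(net, expr, "C")
  expect_equal(fg$network$edges$distance, c(0, 0))
})

test_that("the toy fixture's strongest edge is g9 -> g7", {
  w <- toy_edge_weights()
  expect_equal(w$distance[w$source == "g9" & w$target == "g7"], 0.184)
  expect_equal(which.min(w$distance),
               which(w$source == "g9" & w$target == "g7"))
  expect_equal(max(w$distance), 0.946)
})

test_that("expression_matrix validates its invariants", {
  vals <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  cond <- c(s1 = "C", s2 = "C", s3 = "D")
  expect_warning(expression_matrix(vals, cond), "fewer than 3")
  vals_bad <- vals; vals_bad[1, 1] <- NA
  expect_error(suppressWarnings(expression_matrix(vals_bad, cond)), "finite")
  expect_error(
    suppressWarnings(expression_matrix(vals, c(s1 = "C", s2 = "D", s3 = "E"))),
    "exactly two"
  )
})
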
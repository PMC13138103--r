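# Barcodes from the rank invariant and persistence landscapes.

test_that("the toy filtration yields exactly two dimension-1 bars", {
  bc <- persistence_pairs(toy_filtration(), dimension = 1)
  expect_equal(nrow(bc), 2L)
  expect_true(all(bc$essential))
  # cycles complete when their slowest edge enters: bi-fan at 0.38,
  # feedback cycle at 0.87
  expect_equal(sort(bc$birth), c(0.38, 0.87))
})

test_that("an edgeless graph gives one capped dimension-0 bar per node", {
  fg <- filtered_digraph(pathway_network(NULL, nodes = letters[1:7]),
                         tibble::tibble(source = character(),
                                        target = character(),
                                        distance = numeric()))
  bc <- persistence_pairs(fg, dimension = 0)
  expect_equal(nrow(bc), 7L)
  expect_true(all(bc$birth == 0))
  expect_true(all(bc$death == 1))
  expect_true(all(bc$essential))
})

test_that("bars alive at every threshold reproduce the Betti curve", {
  set.seed(61)
  for (i in 1:8) {
    fg <- random_filtered_digraph(5)
    cv <- betti_curve(fg)
    for (dm in c(0L, 1L)) {
      bc <- persistence_pairs(fg, dimension = dm)
      expect_equal(bars_alive(bc), betti_series(cv, dm),
                   info = paste("digraph", i, "dim", dm))
    }
  }
})

test_that("bar multiplicities are consistent with the rank function at interior points", {
  # total dimension-1 persistence seen through bars equals the sum of the
  # Betti curve (each unit of beta1 at step t is covered by exactly one
  # live bar), already implied by bars_alive; also check births/deaths sit
  # on the grid
  set.seed(67)
  fg <- random_filtered_digraph(6)
  for (dm in c(0L, 1L)) {
    bc <- persistence_pairs(fg, dimension = dm)
    if (nrow(bc)) {
      expect_true(all(abs(bc$birth * 100 - round(bc$birth * 100)) < 1e-9))
      expect_true(all(abs(bc$death * 100 - round(bc$death * 100)) < 1e-9))
      expect_true(all(bc$birth <= bc$death))
    }
  }
})

test_that("curve-heuristic pairing agrees with the rank invariant on live counts", {
  set.seed(73)
  for (i in 1:5) {
    fg <- random_filtered_digraph(5)
    bc <- persistence_pairs(fg, dimension = 1, method = "curve")
    cv <- betti_curve(fg)
    expect_equal(bars_alive(bc), betti_series(cv, 1))
  }
})

test_that("a single bar's landscape is the closed-form tent", {
  L <- landscape(data.frame(birth = 0.2, death = 0.6))
  expect_equal(nrow(L$levels), 1L)
  mid <- which(abs(L$grid - 0.4) < 1e-9)
  expect_equal(L$levels[1, mid], 0.2)
  expect_true(all(L$levels[1, L$grid <= 0.2 | L$grid >= 0.6] == 0))
  # tent slope 1 on the grid
  expect_true(all(abs(diff(L$levels[1, ])) <= 0.01 + 1e-12))
})

test_that("empty barcodes give the zero landscape and zero norms", {
  L <- landscape(data.frame(birth = numeric(), death = numeric()))
  expect_equal(nrow(L$levels), 0L)
  for (w in c("sup", "one", "two")) expect_equal(landscape_norm(L, w), 0)
})

test_that("two overlapping bars match brute-force pointwise max-k evaluation", {
  bars <- data.frame(birth = c(0.1, 0.3), death = c(0.5, 0.7))
  L <- landscape(bars)
  expect_equal(nrow(L$levels), 2L)
  for (k in 1:2) {
    expect_equal(L$levels[k, ], brute_landscape_level(bars, k, L$grid))
  }
})

test_that("landscape levels are ordered and 1-Lipschitz", {
  set.seed(79)
  for (i in 1:10) {
    nb <- sample(1:6, 1)
    b <- runif(nb, 0, 0.8)
    d <- b + runif(nb, 0, 1 - b)
    L <- landscape(data.frame(birth = b, death = d))
    if (nrow(L$levels) > 1) {
      expect_true(all(diff(L$levels) <= 1e-12))  # lambda_k >= lambda_{k+1}
    }
    expect_true(all(abs(t(diff(t(L$levels)))) <= 0.01 + 1e-12))
  }
})

test_that("averaging is idempotent and linear; differencing inverts padding", {
  L <- landscape(data.frame(birth = c(0.1, 0.2), death = c(0.6, 0.4)))
  zero <- landscape(data.frame(birth = numeric(), death = numeric()))

  expect_equal(average_landscapes(list(L, L))$levels, L$levels)
  half <- average_landscapes(list(L, zero))
  expect_equal(half$levels, L$levels / 2)

  expect_equal(landscape_difference(L, L)$levels,
               matrix(0, nrow(L$levels), length(L$grid)))
  expect_equal(landscape_difference(L, zero)$levels, L$levels)

  # three hand-built landscapes: mean recomputed directly
  L2 <- landscape(data.frame(birth = 0.3, death = 0.9))
  L3 <- landscape(data.frame(birth = c(0, 0.5), death = c(1, 0.7)))
  avg <- average_landscapes(list(L, L2, L3))
  K <- max(nrow(L$levels), nrow(L2$levels), nrow(L3$levels))
  pad <- function(x) rbind(x, matrix(0, K - nrow(x), length(L$grid)))
  expect_equal(avg$levels, (pad(L$levels) + pad(L2$levels) + pad(L3$levels)) / 3)

  # averaging commutes with differencing (linearity)
  d1 <- landscape_difference(average_landscapes(list(L, L2)),
                             average_landscapes(list(L3, zero)))
  d2 <- average_landscapes(list(landscape_difference(L, L3),
                                landscape_difference(L2, zero)))
  expect_equal(d1$levels, d2$levels)
})

test_that("mixed homology dimensions refuse to combine", {
  a <- landscape(data.frame(birth = 0.1, death = 0.5), dimension = 0)
  b <- landscape(data.frame(birth = 0.1, death = 0.5), dimension = 1)
  expect_error(average_landscapes(list(a, b)), "dimension")
  expect_error(landscape_difference(a, b), "dimension")
})

test_that("single-bar norms match their closed forms", {
  for (bd in list(c(0.2, 0.6), c(0, 1), c(0.35, 0.47))) {
    L <- landscape(data.frame(birth = bd[1], death = bd[2]))
    pers <- bd[2] - bd[1]
    # grid snapping moves kinks by at most half a step
    expect_equal(landscape_norm(L, "sup"), pers / 2, tolerance = 0.011)
    expect_equal(landscape_norm(L, "one"), pers^2 / 4, tolerance = 0.01)
    expect_equal(landscape_norm(L, "two"), sqrt(pers^3 / 12), tolerance = 0.01)
  }
})

test_that("trapezoidal norms match a 10x finer grid within 1 percent", {
  set.seed(83)
  for (i in 1:5) {
    nb <- sample(2:5, 1)
    b <- round(runif(nb, 0, 0.7), 2)
    d <- round(b + runif(nb, 0.1, 1 - b), 2)
    bars <- data.frame(birth = b, death = d)
    L <- landscape(bars)
    fine <- seq(0, 1, by = 0.001)
    K <- nrow(L$levels)
    one_fine <- sum(vapply(seq_len(K), function(k) {
      pracma::trapz(fine, abs(brute_landscape_level(bars, k, fine)))
    }, numeric(1)))
    two_fine <- sqrt(sum(vapply(seq_len(K), function(k) {
      pracma::trapz(fine, brute_landscape_level(bars, k, fine)^2)
    }, numeric(1))))
    expect_equal(landscape_norm(L, "one"), one_fine, tolerance = 0.01)
    expect_equal(landscape_norm(L, "two"), two_fine, tolerance = 0.01)
  }
})

test_that("scaling all persistences scales the sup norm linearly", {
  b <- c(0.1, 0.2); d <- c(0.5, 0.8)
  L1 <- landscape(data.frame(birth = b, death = d))
  mid <- (b + d) / 2
  half <- data.frame(birth = mid - (d - b) / 4, death = mid + (d - b) / 4)
  L2 <- landscape(half)
  expect_equal(landscape_norm(L2, "sup"), landscape_norm(L1, "sup") / 2,
               tolerance = 1e-9)
})

test_that("norms satisfy the triangle inequality on differences", {
  set.seed(89)
  mk <- function() {
    nb <- sample(1:4, 1)
    b <- round(runif(nb, 0, 0.8), 2)
    d <- round(b + runif(nb, 0, 1 - b), 2)
    landscape(data.frame(birth = b, death = d))
  }
  for (i in 1:10) {
    A <- mk(); B <- mk(); C <- mk()
    for (w in c("sup", "one", "two")) {
      ab <- landscape_norm(landscape_difference(A, B), w)
      bc <- landscape_norm(landscape_difference(B, C), w)
      ac <- landscape_norm(landscape_difference(A, C), w)
      expect_lte(ac, ab + bc + 1e-9)
    }
  }
})
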
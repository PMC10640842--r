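test_that("NODF matches hand values on nested and checkerboard fixtures", {
  expect_equal(nodf(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)), 100)
  expect_equal(nodf(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)), 0)
  expect_error(nodf(matrix(0, 2, 2)), "all-zero")
})

test_that("NODF equals the literal paired-overlap oracle on random matrices", {
  set.seed(41)
  checked <- 0
  while (checked < 20) {
    B <- matrix(rbinom(24, 1, 0.5), 4, 6)
    if (sum(B) == 0) next
    expect_equal(nodf(B), nodf_oracle(B))
    checked <- checked + 1
  }
})

test_that("NODF agrees with an independent community-ecology implementation", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:10) {
    B <- matrix(rbinom(30, 1, 0.45), 5, 6)
    if (sum(B) == 0) next
    expect_equal(nodf(B),
                 unname(vegan::nestednodf(B)$statistic[["NODF"]]))
  }
})

test_that("NODF and modularity are invariant under row/column permutation", {
  nw <- make_fixture_networks("random", c(5, 7), seed = 3)
  A <- nw$matrix
  set.seed(9)
  P <- A[sample(nrow(A)), sample(ncol(A))]
  expect_equal(nodf(P), nodf(A))
  expect_equal(bipartite_modularity(P, seed = 1, restarts = 10)$Q,
               bipartite_modularity(A, seed = 1, restarts = 10)$Q,
               tolerance = 1e-10)
})

test_that("max NODF matches brute-force enumeration on small problems", {
  # all feasible (dims, L) combinations up to 3x4
  for (dims in list(c(2, 2), c(2, 3), c(3, 3), c(3, 4))) {
    m <- dims[1]; n <- dims[2]
    for (L in max(m, n):(m * n)) {
      expect_equal(max_nodf(m, n, L)$nodf, max_nodf_oracle(m, n, L),
                   info = sprintf("%dx%d L=%d", m, n, L))
    }
  }
  expect_error(max_nodf(3, 3, 2), "infeasible")
  expect_error(max_nodf(3, 3, 10), "infeasible")
})

test_that("hill-climbing search equals exhaustive search at small sizes", {
  for (dims in list(c(3, 3), c(3, 4))) {
    m <- dims[1]; n <- dims[2]
    for (L in max(m, n):(m * n)) {
      expect_equal(bloomnet:::max_nodf_climb(m, n, L, 10000)$nodf,
                   bloomnet:::max_nodf_exhaustive(m, n, L)$nodf,
                   info = sprintf("climb %dx%d L=%d", m, n, L))
    }
  }
})

test_that("max NODF dominates the NODF of any matrix with same dims/fill", {
  set.seed(11)
  for (i in 1:10) {
    B <- matrix(rbinom(20, 1, 0.6), 4, 5)
    if (any(rowSums(B) == 0) || any(colSums(B) == 0)) next
    expect_gte(max_nodf(4, 5, sum(B))$nodf, nodf(B) - 1e-9)
  }
  # fully filled matrix has a unique configuration
  expect_equal(max_nodf(3, 4, 12)$nodf, nodf(matrix(1, 3, 4)))
})

test_that("NODFc normalization identities hold", {
  # a matrix attaining its own maximum: the ratio term is exactly 1
  opt <- max_nodf(4, 5, 12)$matrix
  L <- sum(opt); c_fill <- L / 20; s_geom <- sqrt(20)
  expect_equal(nodfc(opt), 1 / (c_fill * log(s_geom)))
  # invariant under transposition
  nw <- make_fixture_networks("random", c(4, 6), seed = 5)
  expect_equal(nodfc(nw$matrix), nodfc(t(nw$matrix)))
  expect_error(nodfc(matrix(1, 1, 1)), "undefined")
})

test_that("degrees use species in the realized network", {
  expect_equal(degrees(toy_network()), c(unweighted = 0.75, weighted = 1.75))
  # perfect matching k x k with unit weights
  nw <- structure(list(matrix = diag(1L, 4), plot_id = "pm", meta = NULL),
                  class = "plot_network")
  expect_equal(degrees(nw), c(unweighted = 0.5, weighted = 0.5))
})

test_that("degrees agree with an independent recount on a random network", {
  set.seed(13)
  A <- matrix(rpois(40, 1.3), 5, 8)
  A[1, colSums(A) == 0] <- 1L  # cover empty columns
  nw <- structure(list(matrix = A, plot_id = "r", meta = NULL),
                  class = "plot_network")
  L <- 0; tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] > 0) L <- L + 1
    tot <- tot + A[i, j]
  }
  S <- nrow(A) + ncol(A)
  expect_equal(degrees(nw), c(unweighted = L / S, weighted = tot / S))
  # identities: degree x S recovers links and abundance
  dg <- degrees(nw)
  expect_equal(dg[["unweighted"]] * S, L)
  expect_equal(dg[["weighted"]] * S, tot)
})

test_that("experiment-wide connectance uses bloomed plants and the pool", {
  meta <- as_plot_metadata(data.frame(
    plot = "p1", block = "b1", treatment = "C", plants_bloomed = 5L,
    display = 100))
  A <- matrix(1L, 2, 5)  # 10 links from 2 visited plants
  nw <- structure(list(matrix = A, plot_id = "p1", meta = meta),
                  class = "plot_network")
  expect_equal(connectance_experiment_wide(nw, I_total = 92), 10 / (5 * 92))
  # complete 1x1 network with a pool of 1
  one <- structure(list(matrix = matrix(1L, 1, 1), plot_id = "o",
                        meta = NULL), class = "plot_network")
  expect_equal(connectance_experiment_wide(one, I_total = 1), 1)
  expect_error(connectance_experiment_wide(one, 92, plants_bloomed = 0),
               "no plants bloomed")
})

test_that("binary metrics ignore uniform weight scaling; Q does too", {
  nw <- make_fixture_networks("random", c(4, 6), seed = 8)
  A <- nw$matrix
  A3 <- A * 3L
  expect_equal(nodf(A3), nodf(A))
  expect_equal(bipartite_modularity(A3, seed = 2, restarts = 10)$Q,
               bipartite_modularity(A, seed = 2, restarts = 10)$Q,
               tolerance = 1e-10)
})

test_that("adding a link never decreases links or connectance", {
  meta <- as_plot_metadata(data.frame(
    plot = "p1", block = "b1", treatment = "C", plants_bloomed = 4L,
    display = 10))
  set.seed(21)
  for (i in 1:5) {
    A <- matrix(rpois(12, 1), 3, 4)
    A[cbind(1:3, 1:3)] <- pmax(A[cbind(1:3, 1:3)], 1L)
    A[1, 4] <- max(A[1, 4], 1L)
    nw <- structure(list(matrix = A, plot_id = "p1", meta = meta),
                    class = "plot_network")
    empt <- which(A == 0)
    if (length(empt) == 0) next
    A2 <- A; A2[empt[1]] <- 1L
    nw2 <- structure(list(matrix = A2, plot_id = "p1", meta = meta),
                     class = "plot_network")
    expect_gte(sum(A2 > 0), sum(A > 0))
    expect_gte(connectance_experiment_wide(nw2, 92),
               connectance_experiment_wide(nw, 92))
  }
})

test_that("compute_all populates a consistent metric row", {
  meta <- as_plot_metadata(data.frame(
    plot = "toy", block = "b1", treatment = "C", plants_bloomed = 2L,
    display = 100))
  nw <- toy_network(); nw$meta <- meta
  row <- compute_all(nw, I_total = 92, seed = 1)
  expect_equal(row$links, 3)
  expect_equal(row$abundance, 7)
  expect_equal(row$species_total, 4)
  expect_equal(row$connectance, 3 / (2 * 92))
  expect_equal(row$unweighted_degree * row$species_total, row$links)
  expect_true(row$modularity >= -0.5 && row$modularity <= 1)
})
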
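test_that("modularity matches hand-derived values on reference graphs", {
  A <- two_cliques(4)
  expect_equal(newman_modularity(A, rep(1:2, each = 4)), 0.5)

  K4 <- matrix(1, 4, 4)
  diag(K4) <- 0
  expect_equal(newman_modularity(K4, c(1, 1, 2, 2)), -1 / 6)

  expect_equal(newman_modularity(A, rep(1L, 8)), 0)
})

test_that("modularity agrees with brute force and igraph on random graphs", {
  set.seed(41)
  for (n in c(10, 25, 50)) {
    A <- random_graph(n)
    p <- sample(1:3, n, replace = TRUE)
    expect_equal(newman_modularity(A, p), brute_modularity(A, p),
                 tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(newman_modularity(A, p),
                 igraph::modularity(g, p, weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
  }
})

test_that("modularity rejects degenerate graphs and stays in [-1, 1]", {
  expect_error(newman_modularity(matrix(0, 3, 3), c(1, 1, 2)), "zero")
  expect_error(newman_modularity(matrix(c(0, -1, -1, 0), 2, 2), c(1, 2)),
               "non-negative")
  set.seed(42)
  for (i in 1:20) {
    A <- random_graph(12, density = 0.5)
    p <- sample(1:4, 12, replace = TRUE)
    q <- newman_modularity(A, p)
    expect_gte(q, -1)
    expect_lte(q, 1)
  }
})

test_that("correlation graph takes absolute correlations and flags dead units", {
  set.seed(43)
  x <- rnorm(200)
  act <- cbind(x, x, -x, rnorm(200), rep(1, 200))
  A <- correlation_graph(act)
  expect_equal(A[1, 2], 1)
  expect_equal(A[1, 3], 1)  # anti-correlated pair still weight 1
  expect_equal(diag(A), rep(0, 5))
  expect_equal(attr(A, "zero_variance"), 5L)
  expect_equal(A[5, ], rep(0, 5))
  # independent columns decorrelate as T grows
  long <- matrix(rnorm(4000 * 3), 4000, 3)
  Al <- correlation_graph(long)
  expect_lt(max(Al[upper.tri(Al)]), 3 / sqrt(4000))
})

test_that("structural graph symmetrizes absolute weights and drops diagonal", {
  W <- matrix(c(0, -3, 1, 0), 2, 2)  # row-major: [[0, 1], [-3, 0]]
  expect_equal(structural_graph(W), matrix(c(0, 4, 4, 0), 2, 2))
  set.seed(44)
  S <- abs(random_graph(5))
  expect_equal(structural_graph(S), 2 * S)
  D <- diag(5) * 7
  expect_equal(structural_graph(D), matrix(0, 5, 5))
})

test_that("output separability contrasts exclusive vs uniform readouts", {
  groups <- group_assignment(4)
  exclusive <- list(Wy1 = matrix(c(1, 1, 0, 0), 1, 4),
                    Wy2 = matrix(c(0, 0, 1, 1), 1, 4))
  expect_equal(d_out(exclusive$Wy1, exclusive$Wy2, groups), 1)
  uniform <- matrix(0.5, 1, 4)
  expect_equal(d_out(uniform, uniform, groups), 0)
  # mirrored specialization is also perfect separation
  expect_equal(d_out(exclusive$Wy2, exclusive$Wy1, groups), 1)
  expect_error(d_out(matrix(0, 1, 4), matrix(0, 1, 4), groups), "undefined")
})

test_that("input separability contrasts bit-exclusive wiring", {
  groups <- group_assignment(4)
  W <- matrix(0, 4, 4)
  W[1:2, 1:2] <- 1   # group 1 reads bit-1 channels
  W[3:4, 3:4] <- 1   # group 2 reads bit-2 channels
  expect_equal(d_in(W, groups), 1)
  expect_equal(d_in(matrix(1, 4, 4), groups), 0)
  # swapping ON/OFF within a bit leaves the index unchanged
  W2 <- W[, c(2, 1, 4, 3)]
  expect_equal(d_in(W2, groups), d_in(W, groups))
})

test_that("neuron-output correlations and D_cor behave on constructed traces", {
  set.seed(45)
  y1 <- matrix(rnorm(300), 300, 1)
  y2 <- matrix(rnorm(300), 300, 1)
  act <- cbind(y1, -y1, y2, rnorm(300))
  cm <- neuron_output_correlations(act, y1, y2)
  expect_equal(cm[1, 1], 1)
  expect_equal(cm[2, 1], 1)  # sign-flipped copy still correlates fully
  expect_lt(cm[4, 1], 0.2)   # independent neuron near zero
  groups <- group_assignment(4)
  ideal <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(d_cor(ideal, groups), 1)
  expect_equal(d_cor(matrix(0.4, 4, 2), groups), 0)
  # relabeling both groups and outputs simultaneously is a symmetry
  expect_equal(d_cor(ideal[, 2:1], 3L - groups), 1)
})

test_that("R^2 matches direct arithmetic", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("working-memory success uses strict sign agreement above 90%", {
  L <- 100
  targets <- matrix(rep(c(1, -1), each = L), L, 2)
  expect_true(wm_success(targets, targets, 0))
  expect_false(wm_success(matrix(0, L, 2), targets, 0))  # sign 0 incorrect
  # exactly 90% correct fails the strict criterion
  y <- targets
  y[1:10, 1] <- -y[1:10, 1]
  y[1:10, 2] <- -y[1:10, 2]
  expect_equal(wm_correct_fraction(y, targets, 0), 0.9)
  expect_false(wm_success(y, targets, 0))
  y[10, ] <- targets[10, ]
  expect_true(wm_success(y, targets, 0))
})

test_that("greedy community detection recovers planted cliques", {
  A <- two_cliques(4)
  comm <- detect_communities(A)
  expect_equal(normalized_mi(rep(1:2, each = 4), comm), 1)
  expect_gte(newman_modularity(A, comm), 0)
})

test_that("greedy Q never exceeds the exhaustive optimum on small graphs", {
  set.seed(46)
  parts <- all_partitions(7)
  for (i in 1:3) {
    A <- random_graph(7, density = 0.5)
    if (sum(A) == 0) next
    best <- max(vapply(parts, function(p) newman_modularity(A, p), numeric(1)))
    comm <- detect_communities(A)
    expect_lte(newman_modularity(A, comm), best + 1e-12)
    expect_gte(newman_modularity(A, comm), 0)  # at least the trivial partition
  }
})

test_that("normalized MI matches closed cases and is label-invariant", {
  expect_equal(normalized_mi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(normalized_mi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(normalized_mi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_error(normalized_mi(c(1, 1, 1), c(1, 2, 1)), "single")
  set.seed(47)
  g <- sample(1:3, 30, replace = TRUE)
  c1 <- sample(1:4, 30, replace = TRUE)
  relab <- c(3, 1, 4, 2)[c1]
  expect_equal(normalized_mi(g, c1), normalized_mi(g, relab))
  expect_gte(normalized_mi(g, c1), 0)
  expect_lte(normalized_mi(g, c1), 1)
})

test_that("separability indices stay in [0, 1] on random inputs", {
  set.seed(49)
  groups <- group_assignment(10)
  for (i in 1:20) {
    w1 <- matrix(rnorm(10), 1, 10)
    w2 <- matrix(rnorm(10), 1, 10)
    cmat <- matrix(abs(rnorm(20)), 10, 2)
    win <- matrix(rnorm(40), 10, 4)
    for (v in c(d_out(w1, w2, groups), d_cor(cmat, groups),
                d_in(win, groups))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("a perfectly modular network maximizes the whole metric stack", {
  set.seed(48)
  N <- 8
  groups <- group_assignment(N)
  # block-diagonal weights (equal blocks), group-wise identical activity,
  # exclusive readout
  W <- matrix(0, N, N)
  blk <- matrix(rnorm(16, 0, 1), 4, 4)
  W[1:4, 1:4] <- blk
  W[5:8, 5:8] <- blk
  diag(W) <- 0
  s1 <- rnorm(5000)
  s2 <- rnorm(5000)
  act <- cbind(s1, s1, s1, s1, s2, s2, s2, s2)
  y1 <- matrix(s1, ncol = 1)
  y2 <- matrix(s2, ncol = 1)
  A_cor <- correlation_graph(act)
  expect_equal(newman_modularity(A_cor, groups), 0.5, tolerance = 0.05)
  # equal-weight disconnected blocks give exactly the two-component optimum
  expect_equal(newman_modularity(structural_graph(W), groups), 0.5,
               tolerance = 1e-12)
  cm <- neuron_output_correlations(act, y1, y2)
  expect_equal(d_cor(cm, groups), 1, tolerance = 0.05)
  Wy1 <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1, 8)
  Wy2 <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 1, 8)
  expect_equal(d_out(Wy1, Wy2, groups), 1)
})
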
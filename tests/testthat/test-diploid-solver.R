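two_read_graph <- function(w) {
  structure(list(m = 2L, i = 1L, j = 2L, k_sim = NA_integer_,
                 k_dissim = NA_integer_, w = w, n_edges = 1L),
            class = "read_graph")
}

triangle_graph <- function(w = -1) {
  structure(list(m = 3L, i = c(1L, 1L, 2L), j = c(2L, 3L, 3L),
                 k_sim = rep(NA_integer_, 3), k_dissim = rep(NA_integer_, 3),
                 w = rep(w, 3), n_edges = 3L),
            class = "read_graph")
}

random_graph <- function(m, seed) {
  withr::with_seed(seed, {
    pairs <- utils::combn(m, 2)
    keep <- runif(ncol(pairs)) < 0.7
    pairs <- pairs[, keep, drop = FALSE]
    structure(list(m = m, i = pairs[1, ], j = pairs[2, ],
                   k_sim = NA, k_dissim = NA,
                   w = round(runif(ncol(pairs), -1, 1), 2),
                   n_edges = ncol(pairs)),
              class = "read_graph")
  })
}

test_that("a single repulsive edge embeds antipodally", {
  emb <- solve_lowrank_sdp(two_read_graph(-1), solver_params(seed = 1))
  expect_true(emb$converged)
  expect_equal(emb$M, 1, tolerance = 1e-6)
  expect_equal(sum(emb$V[1, ] * emb$V[2, ]), -1, tolerance = 1e-6)
})

test_that("the all-repulsive triangle reaches M = 1.5 at 120-degree spread", {
  # || sum V_i ||^2 >= 0 forces sum of pairwise dots >= -3/2, attained by
  # coplanar unit vectors at 120 degrees; M = -sum w dot = 1.5
  emb <- solve_lowrank_sdp(triangle_graph(-1), solver_params(seed = 2))
  expect_equal(emb$M, 1.5, tolerance = 1e-5)
  dots <- tcrossprod(emb$V)[upper.tri(diag(3))]
  expect_equal(dots, rep(-0.5, 3), tolerance = 1e-3)
})

test_that("the relaxation upper-bounds the best integer cut (m <= 10)", {
  for (seed in 1:6) {
    g <- random_graph(sample(4:10, 1), seed = seed * 13)
    emb <- solve_lowrank_sdp(g, solver_params(seed = seed))
    expect_gte(emb$M + 1e-6, brute_maxcut(g))
  }
})

test_that("rows stay unit-norm and M never decreases across sweeps", {
  for (seed in 1:4) {
    g <- random_graph(8, seed = 100 + seed)
    emb <- solve_lowrank_sdp(g, solver_params(seed = seed))
    expect_equal(sqrt(rowSums(emb$V^2)), rep(1, g$m), tolerance = 1e-9)
    # non-decreasing up to the O(noise^2) perturbation a rank-escalation
    # restart injects (one 1e-3 noise column, hence ~1e-6 in M)
    expect_true(all(diff(emb$M_trace) > -1e-5))
  }
})

test_that("scaling all weights scales M and preserves the labeling", {
  g <- random_graph(9, seed = 77)
  g2 <- g
  g2$w <- 3.7 * g$w
  e1 <- solve_lowrank_sdp(g, solver_params(seed = 5))
  e2 <- solve_lowrank_sdp(g2, solver_params(seed = 5))
  expect_equal(e2$M, 3.7 * e1$M, tolerance = 1e-4)
  a1 <- round_hyperplane(e1, g, solver_params(seed = 6))
  a2 <- round_hyperplane(e2, g2, solver_params(seed = 6))
  expect_equal(a1$labels, a2$labels)
})

test_that("rank estimation counts singular values over the threshold", {
  V <- diag(3) * 5
  expect_equal(estimate_rank(V, 0.1), 3L)
  expect_equal(estimate_rank(cbind(V[, 1:2], V[, 2]), 0.1), 2L)
  expect_equal(estimate_rank(matrix(0, 4, 3), 0.1), 0L)
})

test_that("hyperplane rounding recovers a rank-1 sign split exactly", {
  v <- c(0.6, 0.8)
  V <- rbind(v, v, -v, v, -v)
  g <- random_graph(5, seed = 3)
  asn <- round_hyperplane(V, g, solver_params(seed = 4))
  expect_length(asn$labels, 5)
  expect_true(all(asn$labels %in% 0:1))
  expect_equal(asn$labels[1], asn$labels[2])
  expect_equal(asn$labels[3], asn$labels[5])
  expect_false(asn$labels[1] == asn$labels[3])
})

test_that("two antipodal reads on a repulsive edge cut with value 1", {
  g <- two_read_graph(-1)
  emb <- solve_lowrank_sdp(g, solver_params(seed = 9))
  asn <- round_hyperplane(emb, g, solver_params(seed = 10))
  expect_equal(asn$value, 1, tolerance = 1e-6)
  expect_false(asn$labels[1] == asn$labels[2])
})

test_that("global sign flip leaves the cut value unchanged", {
  g <- random_graph(7, seed = 21)
  asn <- round_hyperplane(solve_lowrank_sdp(g, solver_params(seed = 1)),
                          g, solver_params(seed = 2))
  flipped <- 1L - asn$labels
  obj <- function(lab) {
    x <- ifelse(lab == 0L, 1, -1)
    sum(g$w * x[g$i] * x[g$j])
  }
  expect_equal(obj(asn$labels), obj(flipped))
  expect_equal(obj(asn$labels), asn$value)
})

test_that("solve + rounding attains brute-force MAXCUT on most small graphs", {
  hits <- 0L
  trials <- 20L
  for (seed in seq_len(trials)) {
    g <- random_graph(sample(5:12, 1), seed = 1000 + seed)
    emb <- solve_lowrank_sdp(g, solver_params(seed = seed))
    asn <- round_hyperplane(emb, g, solver_params(seed = seed + 1))
    if (asn$value >= brute_maxcut(g) - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.9)
})

test_that("error-free separable reads are split exactly by the pipeline", {
  px <- perfect_diploid_fm(n = 8, reads_per_hap = 6, seed = 5)
  g <- build_read_graph(px$fm)
  emb <- solve_lowrank_sdp(g, solver_params(seed = 11))
  asn <- round_hyperplane(emb, g, solver_params(seed = 12))
  agreement <- max(mean(asn$labels == px$labels),
                   mean(asn$labels == 1L - px$labels))
  expect_equal(agreement, 1)
})
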
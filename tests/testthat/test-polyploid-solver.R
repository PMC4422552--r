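poly_graph <- function(i, j, w, m = max(c(i, j))) {
  structure(list(m = as.integer(m), i = as.integer(i), j = as.integer(j),
                 k_sim = NA, k_dissim = NA, w = as.numeric(w),
                 n_edges = length(i)),
            class = "read_graph")
}

random_graph_k <- function(m, seed) {
  withr::with_seed(seed, {
    pairs <- utils::combn(m, 2)
    keep <- runif(ncol(pairs)) < 0.8
    pairs <- pairs[, keep, drop = FALSE]
    poly_graph(pairs[1, ], pairs[2, ],
               round(runif(ncol(pairs), -1, 1), 2), m = m)
  })
}

test_that("multiplier update follows the clipped subgradient rule", {
  g <- poly_graph(1, 2, -1, m = 2)
  # s = -1 + 1/2 = -0.5: additive step alpha * s, clipped at 0
  V <- rbind(c(1, 0), c(-1, 0))
  lag <- list(lambda = 0, alpha = 0.1, eps_g = 0.01, mu = 1)
  expect_equal(update_multipliers(lag, V, K = 3, g)$lambda, -0.05)
  # satisfied constraint keeps lambda at zero (clipping)
  V2 <- rbind(c(1, 0), c(0, 1))   # dot = 0, s = +0.5
  expect_equal(update_multipliers(lag, V2, K = 3, g)$lambda, 0)
  # deep multiplier with satisfied constraint is damped exponentially
  lag2 <- list(lambda = -1, alpha = 0.1, eps_g = 0.01, mu = 2)
  expect_equal(update_multipliers(lag2, V2, K = 3, g)$lambda, -0.5)
})

test_that("multipliers never become positive", {
  g <- random_graph_k(8, seed = 3)
  lag <- list(lambda = numeric(g$n_edges), alpha = 0.5, eps_g = 0.01, mu = 1)
  withr::with_seed(4, V <- matrix(rnorm(8 * 3), 8))
  V <- V / sqrt(rowSums(V^2))
  for (it in 1:25) {
    lag <- update_multipliers(lag, V, K = 3, g)
    expect_true(all(lag$lambda <= 0))
    withr::with_seed(it, V <- matrix(rnorm(8 * 3), 8))
    V <- V / sqrt(rowSums(V^2))
  }
})

test_that("the repulsive triangle sits on the K=3 constraint boundary", {
  g <- poly_graph(c(1, 1, 2), c(2, 3, 3), rep(-1, 3))
  emb <- solve_lagrangian(g, 3, solver_params(seed = 2))
  # -1/(K-1) = -0.5 is both the feasibility boundary and the unconstrained
  # optimum here, so multipliers stay at zero and M converges to 1.5
  dots <- tcrossprod(emb$V)[upper.tri(diag(3))]
  expect_equal(dots, rep(-0.5, 3), tolerance = 5e-3)
  expect_equal(emb$M, 1.5, tolerance = 1e-2)
  expect_true(all(emb$lambda <= 0))
  expect_gte(emb$min_slack, -5e-3)
})

test_that("a single attractive edge aligns and leaves lambda at zero", {
  g <- poly_graph(1, 2, 1)
  emb <- solve_lagrangian(g, 3, solver_params(seed = 5))
  expect_equal(sum(emb$V[1, ] * emb$V[2, ]), 1, tolerance = 1e-4)
  expect_equal(emb$lambda, 0)
})

test_that("constraint violations shrink toward feasibility", {
  # planted 3-cluster instances: +1 within, -1 across; the constrained
  # optimum sits on the -1/(K-1) boundary, which the multipliers enforce
  for (seed in 1:3) {
    withr::with_seed(40 + seed, {
      grp <- sample(0:2, 12, replace = TRUE)
      pairs <- utils::combn(12, 2)
    })
    w <- ifelse(grp[pairs[1, ]] == grp[pairs[2, ]], 1, -1)
    g <- poly_graph(pairs[1, ], pairs[2, ], w, m = 12)
    emb <- solve_lagrangian(g, 3, solver_params(seed = seed))
    dots <- rowSums(emb$V[g$i, , drop = FALSE] * emb$V[g$j, , drop = FALSE])
    expect_gte(min(dots), -0.5 - 0.1)
    expect_true(all(emb$lambda <= 0))
    expect_equal(sqrt(rowSums(emb$V^2)), rep(1, g$m), tolerance = 1e-9)
  }
})

test_that("K = 2 dispatches to the diploid solver", {
  g <- random_graph_k(7, seed = 9)
  e1 <- solve_lagrangian(g, 2, solver_params(seed = 3))
  e2 <- solve_lowrank_sdp(g, solver_params(seed = 3))
  expect_equal(e1$V, e2$V)
  expect_equal(e1$M, e2$M)
})

test_that("simplex rounding recovers orthogonal prototypes", {
  K <- 3
  proto <- diag(3)
  withr::with_seed(6, grp <- sample(1:K, 12, replace = TRUE))
  V <- proto[grp, , drop = FALSE]
  g <- random_graph_k(12, seed = 10)
  asn <- round_simplex(V, K, g, solver_params(seed = 11))
  expect_true(all(asn$labels %in% 0:(K - 1)))   # argmax totality
  # recovered up to relabeling: same partition as grp
  expect_equal(length(unique(paste(asn$labels, grp))), K)
})

test_that("cluster relabeling leaves the objective unchanged", {
  g <- random_graph_k(9, seed = 15)
  asn <- round_simplex(solve_lagrangian(g, 3, solver_params(seed = 1)),
                       3, g, solver_params(seed = 2))
  perm <- c(2L, 0L, 1L)
  obj <- function(lab) {
    same <- lab[g$i] == lab[g$j]
    sum(g$w[same]) - sum(g$w[!same])
  }
  expect_equal(obj(asn$labels), obj(perm[asn$labels + 1L]))
  expect_equal(obj(asn$labels), asn$value)
})

test_that("rounding matches the exhaustive best 3-partition on most tiny graphs", {
  hits <- 0L
  trials <- 15L
  for (seed in seq_len(trials)) {
    m <- sample(4:8, 1)
    g <- random_graph_k(m, seed = 500 + seed)
    emb <- solve_lagrangian(g, 3, solver_params(seed = seed))
    asn <- round_simplex(emb, 3, g, solver_params(seed = seed + 1,
                                                  n_projections = 200))
    if (asn$value >= brute_best_kpartition(g, 3) - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.8)
})

test_that("the smoothed objective stabilizes even without monotonicity", {
  g <- random_graph_k(12, seed = 33)
  emb <- solve_lagrangian(g, 4, solver_params(seed = 4))
  expect_true(emb$converged)
  lt <- emb$L_trace
  w <- 50
  if (length(lt) >= 2 * w) {
    m1 <- mean(utils::tail(lt, w))
    m2 <- mean(utils::tail(lt, 2 * w)[seq_len(w)])
    expect_lt(abs(m1 - m2) / (abs(m1) + 1), 1e-3)
  }
})
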
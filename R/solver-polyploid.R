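#' Solve the constrained low-rank program for K > 2 clusters
#'
#' For K-ploid assembly the relaxation adds simplex inner-product constraints
#' \eqn{V_i^T V_j \ge -1/(K-1)} on every edge. The solver alternates inner
#' cyclic coordinate sweeps with effective weights \eqn{w_{ij} +
#' \lambda_{ij}} (minorize) and outer subgradient updates of the non-positive
#' multipliers \eqn{\lambda_{ij}} (maximize). The objective is not monotone
#' here, so convergence is declared when consecutive window means (50
#' iterations by default) of the Lagrangian value agree to `eps_tol`
#' (relative). The adaptive rank update mirrors the diploid solver with an
#' initial rank of `K - 1`, the natural rank of the intended solution.
#'
#' `K = 2` dispatches to [solve_lowrank_sdp()] (no constraints are needed:
#' antipodal unit vectors satisfy the bound automatically).
#'
#' @param graph A [build_read_graph()] result (connected).
#' @param K Ploidy (number of clusters), `>= 2`.
#' @param params A [solver_params()].
#' @return A `haplo_embedding` carrying additionally `lambda` (per-edge
#'   multipliers, `<= 0`), `L_trace`, and `min_slack` (the most violated
#'   constraint margin at the last iteration).
#' @export
solve_lagrangian <- function(graph, K, params = solver_params()) {
  K <- as.integer(K)
  if (K < 2L) stop("ploidy must be >= 2", call. = FALSE)
  if (K == 2L) return(solve_lowrank_sdp(graph, params))
  m <- graph$m
  if (m < 2L) stop("need at least 2 reads to embed", call. = FALSE)
  if (any(!is.finite(graph$w))) stop("non-finite edge weights", call. = FALSE)
  r0 <- max(2L, params$r_init_poly %||% (K - 1L))
  # escalate from the natural rank K-1 up to K+2 as rank deficiency
  # dictates; starting at r_init_poly = K+1 skips the escalation rounds
  rank_cap <- max(min(params$rank_cap, K + 2L), r0)
  with_params_seed(params, {
    V <- normalize_rows(matrix(rnorm(m * r0), m, r0))
    lambda <- numeric(graph$n_edges)
    iters_left <- params$max_sweeps
    total_iters <- 0L
    M_trace <- numeric()
    L_trace <- numeric()
    rank_trace <- integer()
    res <- NULL
    repeat {
      res <- cpp_lagrangian_ascent(m, graph$i, graph$j, graph$w, V, lambda,
                                   K, params$alpha, params$eps_g, params$mu,
                                   params$eps_tol_outer, params$window,
                                   iters_left)
      total_iters <- total_iters + res$iterations
      iters_left <- iters_left - res$iterations
      M_trace <- c(M_trace, res$M_trace)
      L_trace <- c(L_trace, res$L_trace)
      lambda <- res$lambda
      r_hat <- estimate_rank(res$V, params$eps_th)
      rank_trace <- c(rank_trace, r_hat)
      full_rank <- r_hat >= ncol(res$V)
      if (!res$converged || !full_rank ||
          ncol(res$V) >= min(m, rank_cap) || iters_left <= 0L) break
      V <- normalize_rows(cbind(res$V, 1e-3 * rnorm(m)))
    }
    structure(list(V = res$V, r = ncol(res$V),
                   rank_est = rank_trace[length(rank_trace)],
                   M = if (length(M_trace)) M_trace[length(M_trace)] else NA_real_,
                   M_trace = M_trace, L_trace = L_trace,
                   lambda = lambda,
                   min_slack = res$min_slack,
                   grad_ratio = NA_real_,
                   sweeps = total_iters,
                   rank_trace = rank_trace,
                   converged = res$converged),
              class = "haplo_embedding")
  })
}

#' One outer update of the Lagrange multipliers
#'
#' For each edge the constraint subgradient is \eqn{s = V_i^T V_j + 1/(K-1)}.
#' Multipliers inside the guard interval take the clipped additive step
#' \eqn{\lambda \leftarrow \min(\lambda + \alpha s, 0)}; multipliers already
#' below `-eps_g` are damped exponentially,
#' \eqn{\lambda \leftarrow \lambda\, 2^{-\mu s}}, which shrinks their
#' magnitude when the constraint is satisfied and grows it when violated.
#' The result is never positive.
#'
#' @param lag List with `lambda` (per-edge, `<= 0`), `alpha`, `eps_g`, `mu`
#'   (see [solver_params()] for defaults).
#' @param V Numeric matrix with unit-norm rows.
#' @param K Ploidy.
#' @param graph The [build_read_graph()] the multipliers live on.
#' @return `lag` with updated `lambda`.
#' @examples
#' g <- list(i = 1L, j = 2L, n_edges = 1L)
#' V <- rbind(c(1, 0), c(-1, 0))          # V_i . V_j = -1
#' lag <- list(lambda = 0, alpha = 0.1, eps_g = 0.01, mu = 1)
#' update_multipliers(lag, V, K = 3, g)$lambda   # min(0 + 0.1 * -0.5, 0)
#' @export
update_multipliers <- function(lag, V, K, graph) {
  s <- rowSums(V[graph$i, , drop = FALSE] * V[graph$j, , drop = FALSE]) +
    1 / (K - 1)
  lambda <- lag$lambda
  guard <- lambda < -lag$eps_g
  out <- pmin(lambda + lag$alpha * s, 0)
  out[guard] <- lambda[guard] * 2^(-lag$mu * s[guard])
  out <- pmin(out, 0)
  lag$lambda <- out
  lag
}

#' Allele-collision odds weights for polyploid clustering
#'
#' For a diploid, reads from different haplotypes disagree wherever both are
#' correct, so the symmetric similarity `(k_sim - k_dissim) / (k_sim +
#' k_dissim)` is (up to scale) the log-likelihood ratio of "same haplotype"
#' versus "different haplotype". For K > 2 the situation is asymmetric:
#' two distinct haplotypes share the observed allele at a heterozygous site
#' with collision probability `q` (about 1/2 for biallelic sites), so an
#' agreement is weak evidence while a disagreement is strong evidence. The
#' evidence-weighted similarity
#' \deqn{w = (k_{sim} - \rho k_{dissim}) / (k_{sim} + \rho k_{dissim})}
#' uses the odds ratio
#' \deqn{\rho = -\lograc{2e(1-e)}{1-q} \Big/ \lograc{(1-e)^2+e^2}{q},}
#' the relative log-likelihood weight of a disagreement, with `e` the
#' sequencing error rate. The diploid case (`q -> 2e(1-e)`) gives `rho = 1`,
#' recovering the symmetric weight. The polyploid solver operates on these
#' weights; the graph itself keeps the plain similarity.
#'
#' @param graph A [build_read_graph()] result.
#' @param K Ploidy.
#' @param err_rate Per-base sequencing error rate (default 0.01).
#' @param collision_prob Override for `q`; default is the biallelic value
#'   for ploidy K (probability two distinct haplotypes agree at a uniformly
#'   drawn non-constant site).
#' @return A copy of `graph` with re-weighted `w`.
#' @export
odds_edge_weights <- function(graph, K, err_rate = 0.01,
                              collision_prob = NULL) {
  e <- max(err_rate, 1e-4)
  q <- collision_prob
  if (is.null(q)) q <- biallelic_collision_prob(K)
  stopifnot(q > 0, q < 1)
  rho <- -log(2 * e * (1 - e) / (1 - q)) / log(((1 - e)^2 + e^2) / q)
  rho <- max(rho, 1)
  out <- graph
  out$w <- (graph$k_sim - rho * graph$k_dissim) /
    (graph$k_sim + rho * graph$k_dissim)
  attr(out, "rho") <- rho
  out
}

#' @rdname odds_edge_weights
#' @export
biallelic_collision_prob <- function(K) {
  k <- seq_len(K - 1)
  num <- sum(choose(K, k) * (choose(k, 2) + choose(K - k, 2)))
  num / (choose(K, 2) * (2^K - 2))
}

#' Round an embedding to K clusters by random projection
#'
#' Projects the embedding onto an `r x K` matrix `Q` of standard-normal
#' entries and assigns read `i` to the cluster with the largest entry of row
#' `i` of `P = V Q` (ties to the lowest index). Among `n_projections`
#' independent draws the labeling with the largest clustering objective --
#' intra-cluster edge weight minus inter-cluster edge weight -- is returned.
#' Empty clusters are allowed.
#'
#' @inheritParams round_hyperplane
#' @param K Number of clusters.
#' @param local_search After picking the best projection, greedily move
#'   single reads to the cluster maximizing their adjacent intra-cluster
#'   weight until no move improves the objective (off by default).
#' @return A `haplo_assignment` with labels in `0:(K-1)`.
#' @export
round_simplex <- function(embedding, K, graph, params = solver_params(),
                          local_search = FALSE) {
  round_simplex_multi(embedding, K, graph, params, n_best = 1L,
                      local_search = local_search)[[1]]
}

# as round_simplex, but keeps the n_best highest-objective distinct
# labelings (candidate starts for MEC refinement)
round_simplex_multi <- function(embedding, K, graph, params = solver_params(),
                                n_best = 1L, local_search = FALSE) {
  V <- if (inherits(embedding, "haplo_embedding")) embedding$V else embedding
  m <- nrow(V)
  r <- ncol(V)
  K <- as.integer(K)
  p <- n_projections_for(params, m)
  with_params_seed(params, {
    cand <- list()
    objs <- numeric()
    for (t in seq_len(p)) {
      Q <- matrix(rnorm(r * K), r, K)
      lab <- max.col(V %*% Q, ties.method = "first") - 1L
      obj <- cpp_cluster_objective(graph$i, graph$j, graph$w, lab)
      if (length(objs) < n_best || obj > min(objs)) {
        if (length(objs) >= n_best) {
          drop <- which.min(objs)
          cand[[drop]] <- NULL
          objs <- objs[-drop]
        }
        cand[[length(cand) + 1L]] <- lab
        objs <- c(objs, obj)
      }
    }
    ord <- order(objs, decreasing = TRUE)
    lapply(ord, function(q) {
      lab <- as.integer(cand[[q]])
      obj <- objs[q]
      if (local_search) {
        ls <- cpp_label_local_search(m, graph$i, graph$j, graph$w, lab, K, 30L)
        lab <- as.integer(ls$labels)
        obj <- cpp_cluster_objective(graph$i, graph$j, graph$w, lab)
      }
      structure(list(labels = lab, value = obj,
                     K = K, n_projections = p),
                class = "haplo_assignment")
    })
  })
}
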
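#' Solve the low-rank SDP relaxation of MAX-CUT on a read graph
#'
#' Maximizes \eqn{M = \sum_{i<j} w_{ij} V_i^T V_j} over unit-norm rows
#' \eqn{V_i} by cyclic (Gauss-Seidel) coordinate ascent with the update
#' \eqn{V_i \leftarrow \sum_{k} w_{ik} V_k} followed by row normalization.
#' The factor starts with 2 columns; whenever the converged factor is of full
#' column rank (singular values above `eps_th`), a column of small seeded
#' noise is appended and iteration resumes, until the factor becomes rank
#' deficient -- at which point the stationary point coincides with the
#' optimum of the convex SDP. Each coordinate update maximizes the objective
#' in that row, so `M` is non-decreasing across sweeps.
#'
#' @param graph A [build_read_graph()] result (connected, `m >= 2`).
#' @param params A [solver_params()].
#' @return Object of class `haplo_embedding`: `V` (m x r, unit-norm rows),
#'   `r`, `rank_est`, `M` (final objective), `M_trace`, `grad_ratio`,
#'   `sweeps`, `rank_trace`, `converged`.
#' @examples
#' fm <- frag_matrix(data.frame(read = c(1, 1, 2, 2),
#'                              snp = c(1, 2, 1, 2),
#'                              allele = c(0, 1, 1, 0)))
#' g <- build_read_graph(fm)
#' emb <- solve_lowrank_sdp(g, solver_params(seed = 1))
#' emb$M   # single edge with w = -1: antipodal optimum, M -> 1
#' @export
solve_lowrank_sdp <- function(graph, params = solver_params()) {
  m <- graph$m
  if (m < 2L) stop("need at least 2 reads to embed", call. = FALSE)
  if (any(!is.finite(graph$w))) stop("non-finite edge weights", call. = FALSE)
  with_params_seed(params, {
    V <- normalize_rows(matrix(rnorm(m * params$r_init), m, params$r_init))
    sweeps_left <- params$max_sweeps
    total_sweeps <- 0L
    M_trace <- numeric()
    rank_trace <- integer()
    res <- NULL
    repeat {
      res <- cpp_lowrank_ascent(m, graph$i, graph$j, graph$w, V,
                                params$eps_tol, sweeps_left)
      total_sweeps <- total_sweeps + res$sweeps
      sweeps_left <- sweeps_left - res$sweeps
      M_trace <- c(M_trace, res$M_trace)
      r_hat <- estimate_rank(res$V, params$eps_th)
      rank_trace <- c(rank_trace, r_hat)
      full_rank <- r_hat >= ncol(res$V)
      if (!res$converged || !full_rank ||
          ncol(res$V) >= min(m, params$rank_cap) || sweeps_left <= 0L) break
      V <- normalize_rows(cbind(res$V, 1e-3 * rnorm(m)))
    }
    structure(list(V = res$V, r = ncol(res$V),
                   rank_est = rank_trace[length(rank_trace)],
                   M = if (length(M_trace)) M_trace[length(M_trace)] else NA_real_,
                   M_trace = M_trace,
                   grad_ratio = res$grad_ratio,
                   sweeps = total_sweeps,
                   rank_trace = rank_trace,
                   converged = res$converged),
              class = "haplo_embedding")
  })
}

#' @export
print.haplo_embedding <- function(x, ...) {
  cat(sprintf(
    "<haplo_embedding> %d x %d (rank est. %d), M = %.4f, %d sweeps%s\n",
    nrow(x$V), x$r, x$rank_est, x$M, x$sweeps,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Numerical rank of an embedding factor
#'
#' The number of singular values exceeding `eps_th`; used by the adaptive
#' rank update to decide when the factor has become rank deficient.
#'
#' @param V Numeric matrix (or a `haplo_embedding`).
#' @param eps_th Threshold on singular values (default 0.1).
#' @return Integer count.
#' @export
estimate_rank <- function(V, eps_th = 0.1) {
  if (inherits(V, "haplo_embedding")) V <- V$V
  if (all(V == 0)) return(0L)
  sum(svd(V, nu = 0, nv = 0)$d > eps_th)
}

#' Round an embedding to a bipartition by random hyperplanes
#'
#' Draws `n_projections` random unit vectors; each projects the unit-norm
#' rows and labels read `i` by the sign of \eqn{V_i \cdot \eta} (ties to +).
#' The labeling with the largest cut objective
#' \eqn{\sum_{i<j} w_{ij} x_i x_j} wins.
#'
#' @param embedding A [solve_lowrank_sdp()] result (or a matrix with unit-norm
#'   rows).
#' @param graph The [build_read_graph()] the embedding was fitted to.
#' @param params A [solver_params()].
#' @return Object of class `haplo_assignment`: `labels` (0/1 per read),
#'   `value` (cut objective), `K = 2`, `n_projections`.
#' @export
round_hyperplane <- function(embedding, graph, params = solver_params()) {
  V <- if (inherits(embedding, "haplo_embedding")) embedding$V else embedding
  m <- nrow(V)
  r <- ncol(V)
  p <- n_projections_for(params, m)
  with_params_seed(params, {
    best <- NULL
    best_obj <- -Inf
    for (t in seq_len(p)) {
      eta <- rnorm(r)
      eta <- eta / sqrt(sum(eta^2))
      x <- as.integer(as.numeric(V %*% eta) < 0)   # sign(0) -> cluster 0
      obj <- cpp_cluster_objective(graph$i, graph$j, graph$w, x)
      if (obj > best_obj) {
        best_obj <- obj
        best <- x
      }
    }
    structure(list(labels = best,
                   value = best_obj, K = 2L, n_projections = p),
              class = "haplo_assignment")
  })
}

#' @export
print.haplo_assignment <- function(x, ...) {
  cat(sprintf("<haplo_assignment> %d reads in %d clusters (sizes %s), objective %.3f\n",
              length(x$labels), x$K,
              paste(tabulate(x$labels + 1L, x$K), collapse = "/"), x$value))
  invisible(x)
}
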
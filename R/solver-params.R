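#' Solver control parameters
#'
#' Collects every tunable knob of the clustering solvers in one object.
#'
#' @param eps_th Singular-value threshold for rank detection during the
#'   adaptive rank update (default 0.1).
#' @param eps_tol Stopping tolerance: the diploid solver stops when the ratio
#'   of the gradient norm to the objective drops below `eps_tol`; the
#'   polyploid solver compares consecutive 50-iteration window means of the
#'   Lagrangian (relative change) against `eps_tol`.
#' @param max_sweeps Cap on coordinate-ascent sweeps (diploid) or outer
#'   iterations (polyploid), summed across rank escalations.
#' @param r_init Initial number of embedding columns for the diploid solver
#'   (the rank budget starts at 2 and grows until rank deficiency).
#' @param rank_cap Upper bound on the escalated rank budget.
#' @param r_init_poly Initial rank budget of the polyploid solver; `NULL`
#'   means `K - 1`, the natural rank of the simplex solution, from which
#'   the budget escalates adaptively. Setting it to about `K + 1` (the
#'   rank high-ploidy solves typically escalate to) trades a little
#'   accuracy for roughly half the iterations.
#' @param max_restarts,retry_factor Restart policy of the polyploid core: a
#'   (window) solve whose refined MEC exceeds `retry_factor` times the
#'   expected noise floor `err_rate * n_calls` triggers up to
#'   `max_restarts` escalation attempts, alternating a much larger rounding
#'   budget on the current embedding with a fresh re-solve.
#' @param n_projections Number of randomized rounding projections; `NULL`
#'   means `max(proj_floor, ceiling(proj_const * log(m)))`.
#' @param proj_const,proj_floor Constants of the `O(log m)` projection-count
#'   rule. The default constant is generous: rounding is cheap relative to
#'   the solve and the best-of-many-projections labeling improves markedly
#'   up to a few hundred draws on large blocks.
#' @param alpha Subgradient step size for the Lagrange multipliers.
#' @param eps_tol_outer Convergence tolerance of the polyploid smoothed
#'   (windowed) Lagrangian test; looser than `eps_tol` because the windowed
#'   value is already an average.
#' @param eps_g Guard interval: multipliers below `-eps_g` switch to the
#'   exponential damping update.
#' @param mu Damping exponent of the multiplier update.
#' @param window Smoothing window (iterations) for the polyploid convergence
#'   test.
#' @param refine_sweeps Cap on greedy-refinement sweeps over the sites.
#' @param embed_depth_cap Optional per-SNP depth budget for the polyploid
#'   embedding stage: above it, the solve and rounding run on a random read
#'   subsample (consensus and MEC refinement always use every read).
#'   Disabled (`Inf`) by default: the coverage the protocol prescribes is
#'   exactly what the embedding needs, and capping it degrades accuracy.
#' @param window_snps,window_overlap Window length and overlap (SNP sites)
#'   for hierarchical phasing of long polyploid blocks: windows are phased
#'   independently, aligned by permutation matching over their overlaps,
#'   and the stitched haplotypes refined globally.
#' @param err_rate Assumed per-base sequencing error rate; sets the
#'   odds-ratio weighting the polyploid solver applies to disagreements
#'   (see [odds_edge_weights()]).
#' @param collision_prob Probability that two distinct haplotypes share the
#'   allele at a heterozygous site; `NULL` uses the biallelic value for the
#'   ploidy at hand.
#' @param seed Optional integer seed; when non-`NULL` every stochastic step
#'   (initialization, rounding projections) is reproducible.
#' @return A list of class `solver_params`.
#' @export
solver_params <- function(eps_th = 0.1,
                          eps_tol = 1e-5,
                          max_sweeps = 1000L,
                          r_init = 2L,
                          r_init_poly = NULL,
                          rank_cap = 12L,
                          n_projections = NULL,
                          proj_const = 30,
                          proj_floor = 50L,
                          eps_tol_outer = 1e-4,
                          alpha = 0.1,
                          eps_g = 0.01,
                          mu = 1.0,
                          window = 50L,
                          refine_sweeps = 10L,
                          embed_depth_cap = Inf,
                          window_snps = 300L,
                          window_overlap = 60L,
                          max_restarts = 3L,
                          retry_factor = 1.5,
                          err_rate = 0.01,
                          collision_prob = NULL,
                          seed = NULL) {
  stopifnot(eps_th > 0, eps_tol > 0, max_sweeps >= 1, r_init >= 2,
            alpha > 0, eps_g >= 0, mu >= 0, window >= 1)
  structure(list(eps_th = eps_th, eps_tol = eps_tol,
                 max_sweeps = as.integer(max_sweeps),
                 r_init = as.integer(r_init),
                 r_init_poly = r_init_poly,
                 rank_cap = as.integer(rank_cap),
                 n_projections = n_projections,
                 proj_const = proj_const, proj_floor = as.integer(proj_floor),
                 eps_tol_outer = eps_tol_outer, alpha = alpha, eps_g = eps_g, mu = mu,
                 window = as.integer(window),
                 refine_sweeps = as.integer(refine_sweeps),
                 embed_depth_cap = embed_depth_cap,
                 window_snps = as.integer(window_snps),
                 window_overlap = as.integer(window_overlap),
                 max_restarts = as.integer(max_restarts),
                 retry_factor = retry_factor,
                 err_rate = err_rate, collision_prob = collision_prob,
                 seed = seed),
            class = "solver_params")
}

n_projections_for <- function(params, m) {
  if (!is.null(params$n_projections)) return(as.integer(params$n_projections))
  max(params$proj_floor, as.integer(ceiling(params$proj_const * log(max(m, 2)))))
}

with_params_seed <- function(params, code) {
  if (is.null(params$seed)) code
  else withr::with_seed(as.integer(params$seed), code)
}

normalize_rows <- function(V) {
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  V / nrm
}
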
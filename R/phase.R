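#' Phase a fragment matrix into K haplotypes
#'
#' The end-to-end pipeline: filter uninformative reads and columns, split the
#' matrix into connected haplotype blocks, and for every block build the
#' weighted read graph, embed it with the low-rank SDP solver (`K = 2`) or
#' the Lagrangian scheme (`K > 2`), round the embedding to K read clusters by
#' randomized projections, derive haplotypes by per-cluster majority vote and
#' greedily refine them against the MEC objective.
#'
#' @param fragments A [frag_matrix()].
#' @param K Ploidy (>= 2).
#' @param mode Consensus mode, `"allow_homozygous"` (default; corrects
#'   falsely heterozygous sites) or `"all_heterozygous"`.
#' @param params A [solver_params()]; `params$seed` makes the run
#'   deterministic.
#' @return Object of class `haplo_phasing`: per-block tibble `blocks`,
#'   haplotype blocks (`snps` in original column indices + [hap_set()]),
#'   per-block read labels, solver diagnostics, and the filtering maps.
#' @examples
#' fm <- frag_matrix(data.frame(read = c(1, 1, 2, 2, 3, 3, 4, 4),
#'                              snp = c(1, 2, 2, 3, 1, 2, 2, 3),
#'                              allele = c(0, 1, 1, 0, 1, 0, 0, 1)))
#' res <- phase_fragments(fm, K = 2, params = solver_params(seed = 1))
#' tidy(res)
#' @export
phase_fragments <- function(fragments, K = 2L,
                            mode = c("allow_homozygous", "all_heterozygous"),
                            params = solver_params()) {
  mode <- match.arg(mode)
  K <- as.integer(K)
  if (K < 2L) stop("ploidy must be >= 2", call. = FALSE)
  run <- function() {
    filt <- filter_fragments(fragments)
    fm <- filt$fragments
    if (fm$n_reads == 0L) {
      warning("no informative reads after filtering; empty phasing",
              call. = FALSE)
      return(empty_phasing(K, mode, filt, params))
    }
    partition <- connected_components(fm)
    blocks <- split_blocks(fm, partition)
    fits <- lapply(blocks, function(blk) phase_block(blk, K, mode, params))
    build_phasing(K, mode, filt, partition, blocks, fits, params)
  }
  if (is.null(params$seed)) run()
  else withr::with_seed(as.integer(params$seed), {
    # block-level stages draw from the running RNG; disable re-seeding inside
    params$seed <- NULL
    run()
  })
}

phase_block <- function(blk, K, mode, params) {
  fm <- blk$fragments
  if (K > 2L && fm$n_snps > params$window_snps + params$window_overlap)
    return(phase_block_windowed(blk, K, mode, params))
  m <- fm$n_reads
  if (m == 1L) {
    asn <- structure(list(labels = 0L, value = 0, K = K, n_projections = 0L),
                     class = "haplo_assignment")
    emb <- NULL
    n_edges <- 0L
  } else {
    graph <- build_read_graph(fm)
    n_edges <- graph$n_edges
    if (K == 2L) {
      emb <- solve_lowrank_sdp(graph, params)
      asn <- round_hyperplane(emb, graph, params)
    } else {
      # refine the best few rounding candidates and keep the lowest MEC
      fit <- phase_poly_core(fm, K, mode, params)
      return(list(embedding = fit$embedding, assignment = fit$assignment,
                  haplotypes = fit$ref$haplotypes, mec = fit$ref$mec,
                  refine_sweeps = fit$ref$sweeps,
                  refine_changes = fit$ref$changes,
                  n_edges = fit$n_edges))
    }
  }
  haps <- derive_haplotypes(asn, fm, K, mode)
  ref <- greedy_refine(haps, fm, params)
  list(embedding = emb, assignment = asn,
       haplotypes = ref$haplotypes, mec = ref$mec,
       refine_sweeps = ref$sweeps, refine_changes = ref$changes,
       n_edges = n_edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all permutations of 1..K as rows
all_perms <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    t(apply(sub, 1, function(p) append(p, K, after = pos - 1L)))
  }))
}

# restrict a fragment matrix to columns [a, b]; reads keeping >= min_calls
# clipped calls survive
clip_fragments <- function(fm, a, b, min_calls = 2L) {
  sel <- fm$calls$snp >= a & fm$calls$snp <= b
  calls <- fm$calls[sel, , drop = FALSE]
  keep_reads <- as.integer(names(which(table(calls$read) >= min_calls)))
  calls <- calls[calls$read %in% keep_reads, , drop = FALSE]
  reads <- sort(unique(calls$read))
  frag_matrix(data.frame(read = match(calls$read, reads),
                         snp = calls$snp - a + 1L,
                         allele = calls$allele),
              n_snps = b - a + 1L,
              read_id = fm$read_id[reads],
              alphabet_size = fm$alphabet_size)
}

# majority allele per column over the whole matrix (ties: lowest code)
column_majority <- function(fm) {
  out <- integer(fm$n_snps)
  cnt <- dplyr::count(fm$calls, .data$snp, .data$allele)
  cnt <- dplyr::arrange(cnt, .data$snp, dplyr::desc(.data$n), .data$allele)
  top <- cnt[!duplicated(cnt$snp), ]
  out[top$snp] <- top$allele
  out
}

# core solve -> round -> consensus -> refine on one (sub)matrix, K > 2.
# The expected MEC of a correct phasing is about err_rate * n_calls; when
# the best refined MEC stays well above that floor the solve landed in a
# poor basin, and a re-solve from a fresh random initialization is cheaper
# than accepting the damage (restart policy; no ground truth involved).
phase_poly_core <- function(fm, K, mode, params, n_best = 3L) {
  max_restarts <- params$max_restarts
  retry_factor <- params$retry_factor
  # the embedding scales with the square of the depth; cap the depth used
  # for the solve/rounding stage (consensus, refinement and the restart
  # test always see the full matrix)
  sub_fm <- fm
  fallback <- NULL
  depth <- nrow(fm$calls) / max(fm$n_snps, 1L)
  cap <- params$embed_depth_cap
  if (is.finite(cap) && depth > cap) {
    keep <- runif(fm$n_reads) < cap / depth
    if (sum(keep) >= 2L) {
      reads <- which(keep)
      calls <- fm$calls[fm$calls$read %in% reads, , drop = FALSE]
      sub_fm <- frag_matrix(data.frame(read = match(calls$read, reads),
                                       snp = calls$snp,
                                       allele = calls$allele),
                            n_snps = fm$n_snps,
                            read_id = fm$read_id[reads],
                            alphabet_size = fm$alphabet_size)
      fallback <- column_majority(fm)
    }
  }
  graph <- build_read_graph(sub_fm)
  gw <- odds_edge_weights(graph, K, err_rate = params$err_rate,
                          collision_prob = params$collision_prob)
  mec_floor <- params$err_rate * nrow(fm$calls)
  best <- NULL
  restart_params <- params
  restart_params$max_sweeps <- max(300L, params$max_sweeps %/% 2L)
  # escalation schedule: each attempt either re-rounds the current embedding
  # with a much larger projection budget (cheap) or re-solves from a fresh
  # random initialization (expensive); hard instances respond to both
  heavy <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  resolve <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  emb <- NULL
  for (attempt in seq_len(min(1L + max_restarts, length(heavy)))) {
    pp <- if (attempt == 1L) params else restart_params
    if (resolve[attempt] || is.null(emb)) emb <- solve_lagrangian(gw, K, pp)
    if (heavy[attempt]) {
      pp$n_projections <- 3L * n_projections_for(params, graph$m)
      nb <- 3L * n_best
    } else nb <- n_best
    cands <- round_simplex_multi(emb, K, gw, pp, n_best = nb)
    for (asn_c in cands) {
      haps_c <- derive_haplotypes(asn_c, sub_fm, K, mode, fallback = fallback)
      ref_c <- greedy_refine(haps_c, fm, params)
      if (is.null(best) || ref_c$mec < best$ref$mec)
        best <- list(asn = asn_c, ref = ref_c, embedding = emb)
    }
    if (best$ref$mec <= retry_factor * mec_floor) break
  }
  list(embedding = best$embedding, assignment = best$asn, ref = best$ref,
       n_edges = graph$n_edges)
}

# hierarchical phasing of a long polyploid block: solve overlapping windows,
# align each window to the growing haplotypes by the mismatch-minimizing
# row permutation over the overlap, then refine the stitched result globally
phase_block_windowed <- function(blk, K, mode, params) {
  fm <- blk$fragments
  n <- fm$n_snps
  win <- params$window_snps
  ov <- params$window_overlap
  step <- win - ov
  starts <- seq(1L, max(n - win + 1L, 1L), by = step)
  if (utils::tail(starts, 1) + win - 1L < n)
    starts <- c(starts, n - win + 1L)
  fallback <- column_majority(fm)
  H <- matrix(NA_integer_, K, n)
  n_edges <- 0L
  emb_first <- NULL
  cut_value <- NA_real_
  asn_first <- NULL
  for (s_idx in seq_along(starts)) {
    a <- starts[s_idx]
    b <- min(a + win - 1L, n)
    sub <- clip_fragments(fm, a, b)
    if (sub$n_reads < 2L) next
    covered <- sort(unique(sub$calls$snp))
    Hw <- matrix(rep(fallback[a:b], each = K), nrow = K)
    if (length(covered) < sub$n_snps) {
      # phase only the covered columns of the window
      sub2 <- clip_fragments(sub, 1L, sub$n_snps)  # no-op; keep layout
      sub2$calls$snp <- match(sub2$calls$snp, covered)
      sub2$n_snps <- length(covered)
      fit <- phase_poly_core(sub2, K, mode, params)
      Hw[, covered] <- fit$ref$haplotypes$alleles
    } else {
      fit <- phase_poly_core(sub, K, mode, params)
      Hw <- fit$ref$haplotypes$alleles
    }
    if (is.null(emb_first)) {
      emb_first <- fit$embedding
      asn_first <- fit$assignment
      cut_value <- fit$assignment$value
    }
    n_edges <- n_edges + fit$n_edges
    if (s_idx == 1L || all(is.na(H))) {
      H[, a:b] <- Hw
    } else {
      ov_cols <- a:min(b, a + ov - 1L)
      ov_cols <- ov_cols[!is.na(H[1, ov_cols])]
      perm <- best_row_permutation(H[, ov_cols, drop = FALSE],
                                   Hw[, ov_cols - a + 1L, drop = FALSE])
      Hw <- Hw[perm, , drop = FALSE]
      mid <- if (length(ov_cols)) ov_cols[ceiling(length(ov_cols) / 2)] else a - 1L
      H[, (mid + 1L):b] <- Hw[, (mid + 1L - a + 1L):(b - a + 1L), drop = FALSE]
    }
  }
  miss <- is.na(H[1, ])
  if (any(miss)) H[, miss] <- rep(fallback[miss], each = K)
  # seam polish: overlap-based alignment can mis-join windows wherever two
  # haplotypes are locally identical; re-align every seam by the tail
  # permutation minimizing the full-matrix MEC (exhaustive over K!)
  cuts <- starts[-1]
  if (length(cuts) && K <= 6L) H <- polish_seams(H, fm, cuts)
  ref <- greedy_refine(hap_set(H), fm, params)
  # read labels from the final haplotypes (nearest by Hamming distance)
  hd <- vapply(seq_len(K), function(l) {
    h <- ref$haplotypes$alleles[l, fm$calls$snp]
    tabulate(fm$calls$read[h != fm$calls$allele], nbins = fm$n_reads)
  }, integer(fm$n_reads))
  labels <- max.col(-hd, ties.method = "first") - 1L
  asn <- structure(list(labels = as.integer(labels), value = cut_value,
                        K = K, n_projections = asn_first$n_projections %||% 0L),
                   class = "haplo_assignment")
  list(embedding = emb_first, assignment = asn,
       haplotypes = ref$haplotypes, mec = ref$mec,
       refine_sweeps = ref$sweeps, refine_changes = ref$changes,
       n_edges = n_edges)
}

# re-align stitched windows: at each seam try every permutation of the
# haplotype tails (from the seam onward) and keep the best full-matrix MEC
polish_seams <- function(H, fm, cuts, rounds = 2L) {
  K <- nrow(H)
  perms <- all_perms(K)
  csr <- calls_csr(fm)
  for (rd in seq_len(rounds)) {
    changed <- FALSE
    for (cut in cuts) {
      base <- cpp_mec(csr$read_ptr, csr$snp, csr$allele, H)
      best_mec <- base
      best_perm <- NULL
      tail_cols <- cut:ncol(H)
      for (q in seq_len(nrow(perms))) {
        pr <- perms[q, ]
        if (all(pr == seq_len(K))) next
        H2 <- H
        H2[, tail_cols] <- H[pr, tail_cols, drop = FALSE]
        mec2 <- cpp_mec(csr$read_ptr, csr$snp, csr$allele, H2)
        if (mec2 < best_mec) {
          best_mec <- mec2
          best_perm <- pr
        }
      }
      if (!is.null(best_perm)) {
        H[, tail_cols] <- H[best_perm, tail_cols, drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  H
}

# permutation of est rows minimizing total mismatches against ref rows
best_row_permutation <- function(ref, est) {
  K <- nrow(ref)
  cost <- matrix(0L, K, K)   # cost[l, r]: est row r aligned to ref row l
  for (l in seq_len(K))
    for (r in seq_len(K))
      cost[l, r] <- sum(ref[l, ] != est[r, ], na.rm = TRUE)
  perms <- all_perms(K)
  scores <- vapply(seq_len(nrow(perms)), function(q)
    sum(cost[cbind(seq_len(K), perms[q, ])]), 0L)
  perms[which.min(scores), ]
}

build_phasing <- function(K, mode, filt, partition, blocks, fits, params) {
  col_orig <- filt$col_map$original
  block_tbl <- purrr::map_dfr(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    fit <- fits[[b]]
    emb <- fit$embedding
    tibble::tibble(block = b,
                   n_snps = blk$fragments$n_snps,
                   n_reads = blk$fragments$n_reads,
                   n_edges = fit$n_edges,
                   mec = as.integer(fit$mec),
                   objective = if (is.null(emb)) NA_real_ else emb$M,
                   cut_value = fit$assignment$value,
                   rank = if (is.null(emb)) NA_integer_ else emb$rank_est,
                   sweeps = if (is.null(emb)) 0L else emb$sweeps,
                   converged = if (is.null(emb)) TRUE else emb$converged)
  })
  hap_blocks <- lapply(seq_along(blocks), function(b) {
    list(snps = as.integer(col_orig[blocks[[b]]$snps]),
         haps = fits[[b]]$haplotypes,
         mec = fits[[b]]$mec)
  })
  labels <- lapply(seq_along(blocks), function(b) {
    tibble::tibble(read_id = blocks[[b]]$fragments$read_id,
                   block = b,
                   cluster = fits[[b]]$assignment$labels)
  })
  diagnostics <- lapply(fits, function(f) {
    if (is.null(f$embedding)) NULL
    else f$embedding[c("M_trace", "rank_trace", "grad_ratio", "converged")]
  })
  structure(list(K = K, mode = mode,
                 blocks = block_tbl,
                 haplotype_blocks = hap_blocks,
                 labels = dplyr::bind_rows(labels),
                 col_map = filt$col_map,
                 reads_kept = filt$reads_kept,
                 partition = partition,
                 diagnostics = diagnostics,
                 params = params),
            class = "haplo_phasing")
}

empty_phasing <- function(K, mode, filt, params) {
  structure(list(K = K, mode = mode,
                 blocks = tibble::tibble(block = integer(), n_snps = integer(),
                                         n_reads = integer(),
                                         n_edges = integer(), mec = integer(),
                                         objective = numeric(),
                                         cut_value = numeric(),
                                         rank = integer(), sweeps = integer(),
                                         converged = logical()),
                 haplotype_blocks = list(),
                 labels = tibble::tibble(read_id = character(),
                                         block = integer(),
                                         cluster = integer()),
                 col_map = filt$col_map,
                 reads_kept = filt$reads_kept,
                 partition = NULL,
                 diagnostics = list(),
                 params = params),
            class = "haplo_phasing")
}

#' Blocks of a phasing result
#' @param phasing A `haplo_phasing`.
#' @return List of blocks (`snps`, `haps`, `mec`), the layout accepted by
#'   [write_haplotype_blocks()].
#' @export
phasing_blocks <- function(phasing) phasing$haplotype_blocks

#' @export
print.haplo_phasing <- function(x, ...) {
  cat(sprintf("<haplo_phasing> K = %d (%s), %d block(s), %d SNPs phased, total MEC %d\n",
              x$K, x$mode, nrow(x$blocks), sum(x$blocks$n_snps),
              sum(x$blocks$mec)))
  invisible(x)
}
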
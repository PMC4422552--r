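calls_csr <- function(fm) {
  # calls are sorted by (read, snp) in the constructor
  counts <- tabulate(fm$calls$read, nbins = fm$n_reads)
  list(read_ptr = c(0L, cumsum(counts)),
       snp = fm$calls$snp - 1L,
       allele = fm$calls$allele)
}

#' Derive haplotypes from a read clustering by majority vote
#'
#' For each SNP site and each cluster, the haplotype allele is the modal
#' allele code among the cluster's reads covering the site (ties go to the
#' lowest code and are flagged). In `"allow_homozygous"` mode the K calls may
#' coincide -- this is what corrects sites that were falsely genotyped as
#' heterozygous. In `"all_heterozygous"` mode (diploid only) a coincident
#' call is resolved by flipping the minority cluster's allele to the
#' complement. Clusters with no covering read at a site fall back to the
#' site's overall modal allele.
#'
#' @param assignment A `haplo_assignment` (labels in `0:(K-1)`).
#' @param fm The block-local [frag_matrix()] the labels refer to.
#' @param K Ploidy.
#' @param mode `"allow_homozygous"` (default) or `"all_heterozygous"`.
#' @param fallback Optional allele vector (length `n_snps`) used for sites
#'   covered by no read at all -- only meaningful when `fm` is a subsample
#'   of a larger matrix; by default an uncovered site is an error.
#' @return A [hap_set()] of K haplotypes; attribute `ambiguous` flags sites
#'   where some cluster's vote was tied.
#' @export
derive_haplotypes <- function(assignment, fm, K,
                              mode = c("allow_homozygous", "all_heterozygous"),
                              fallback = NULL) {
  mode <- match.arg(mode)
  K <- as.integer(K)
  labels <- assignment$labels
  stopifnot(length(labels) == fm$n_reads, all(labels >= 0L & labels < K))
  n <- fm$n_snps
  calls <- fm$calls
  uncovered <- setdiff(seq_len(n), unique(calls$snp))
  if (length(uncovered) && is.null(fallback))
    stop("site covered by no read: filter fragments first", call. = FALSE)

  votes <- calls
  votes$cluster <- labels[votes$read]
  counts <- dplyr::count(votes, .data$snp, .data$cluster, .data$allele)
  top <- counts %>%
    dplyr::group_by(.data$snp, .data$cluster) %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$allele, .by_group = TRUE) %>%
    dplyr::summarize(allele = .data$allele[1],
                     tied = dplyr::n() > 1L && .data$n[1] == .data$n[2],
                     votes = .data$n[1], .groups = "drop")
  overall <- dplyr::count(calls, .data$snp, .data$allele) %>%
    dplyr::group_by(.data$snp) %>%
    dplyr::arrange(dplyr::desc(.data$n), .data$allele, .by_group = TRUE) %>%
    dplyr::summarize(allele = .data$allele[1], .groups = "drop")

  H <- matrix(NA_integer_, K, n)
  covered_cols <- sort(unique(calls$snp))
  H[, covered_cols] <- rep(overall$allele[order(overall$snp)], each = K)
  if (length(uncovered)) H[, uncovered] <- rep(fallback[uncovered], each = K)
  vote_n <- matrix(0L, K, n)
  H[cbind(top$cluster + 1L, top$snp)] <- top$allele
  vote_n[cbind(top$cluster + 1L, top$snp)] <- top$votes
  ambiguous <- logical(n)
  ambiguous[top$snp[top$tied]] <- TRUE

  if (mode == "all_heterozygous") {
    if (K != 2L)
      stop("all_heterozygous mode is defined for K = 2", call. = FALSE)
    coincide <- H[1, ] == H[2, ]
    if (any(coincide)) {
      minority <- ifelse(vote_n[1, ] <= vote_n[2, ], 1L, 2L)
      j <- which(coincide)
      H[cbind(minority[j], j)] <- 1L - H[cbind(minority[j], j)]
    }
  }
  hs <- hap_set(H)
  attr(hs, "ambiguous") <- ambiguous
  hs
}

#' Greedy MEC refinement of assembled haplotypes
#'
#' Sweeps the sites left to right; at each site every single-haplotype allele
#' alteration is scored against the block MEC (the per-read minimum over all
#' K haplotypes is re-evaluated, which implicitly re-assigns reads) and a
#' change is accepted iff the MEC strictly decreases. Sweeps repeat until a
#' full sweep changes nothing or the sweep cap is hit; the returned MEC is
#' never larger than the input MEC, and termination is guaranteed because MEC
#' is a non-negative integer that strictly decreases with every accepted
#' move.
#'
#' Two move classes are alternated until neither lowers the MEC: single-site
#' allele alterations, and switch (recombination) moves that exchange two
#' haplotype tails at a site boundary. Tail exchanges only re-score the reads
#' straddling the boundary -- reads entirely on one side see a permuted
#' haplotype set, whose per-read minimum is identical -- and are what rescue
#' the mosaic solutions that site-wise moves alone cannot leave.
#'
#' @param haps A [hap_set()] matching the block width.
#' @param fm The block-local [frag_matrix()].
#' @param params A [solver_params()] (supplies the sweep cap).
#' @param switch_moves Include the switch-move pass (default TRUE).
#' @return List: `haplotypes` (refined [hap_set()]), `mec`, `sweeps`,
#'   `changes`.
#' @export
greedy_refine <- function(haps, fm, params = solver_params(),
                          switch_moves = TRUE) {
  stopifnot(haps$n == fm$n_snps)
  csr <- calls_csr(fm)
  a <- haps$alleles
  if (anyNA(a)) stop("cannot refine haplotypes with unphased sites", call. = FALSE)
  res <- cpp_greedy_refine(csr$read_ptr, csr$snp, csr$allele, a,
                           fm$alphabet_size, params$refine_sweeps)
  sweeps <- res$sweeps
  changes <- res$changes
  if (switch_moves) {
    repeat {
      mec_before <- res$mec
      sw <- cpp_switch_refine(csr$read_ptr, csr$snp, csr$allele, res$hap,
                              params$refine_sweeps)
      sweeps <- sweeps + sw$sweeps
      changes <- changes + sw$changes
      res <- cpp_greedy_refine(csr$read_ptr, csr$snp, csr$allele, sw$hap,
                               fm$alphabet_size, params$refine_sweeps)
      sweeps <- sweeps + res$sweeps
      changes <- changes + res$changes
      if (res$mec >= mec_before) break
    }
  }
  list(haplotypes = hap_set(res$hap), mec = res$mec,
       sweeps = sweeps, changes = changes)
}
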
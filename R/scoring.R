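#' Minimum error correction (MEC) score
#'
#' The MEC objective is
#' \deqn{Z = \sum_i \min_l \mathrm{hd}(R_i, h^l),}
#' the total number of observed read bases that must be flipped so that every
#' read is consistent with one of the K haplotypes. The per-symbol distance
#' counts a position only when both symbols are non-gap and differ, so
#' uncovered sites never contribute.
#'
#' @param fm A [frag_matrix()].
#' @param haps A [hap_set()] with `n = fm$n_snps` sites (NA sites match
#'   nothing but also cost nothing for reads not covering them; refined
#'   haplotypes are fully phased).
#' @return Integer count `Z >= 0`.
#' @examples
#' fm <- frag_matrix(data.frame(read = c(1, 1), snp = c(1, 2), allele = c(0, 1)))
#' mec_score(fm, hap_set(c("01", "10")))
#' @export
mec_score <- function(fm, haps) {
  if (haps$n != fm$n_snps)
    stop("haplotype length does not match the fragment matrix", call. = FALSE)
  m <- fm$n_reads
  if (m == 0L) return(0L)
  calls <- fm$calls
  hd <- matrix(0L, m, haps$K)
  for (l in seq_len(haps$K)) {
    h <- haps$alleles[l, calls$snp]
    mism <- !is.na(h) & h != calls$allele
    hd[, l] <- tabulate(calls$read[mism], nbins = m)
  }
  as.integer(sum(apply(hd, 1, min)))
}

swer_comparable <- function(est, truth) {
  which(heterozygous_sites(est) & heterozygous_sites(truth))
}

#' Switch error rate for a diploid block
#'
#' Over consecutive comparable sites (heterozygous in both truth and
#' estimate), counts positions where the relative phase of the estimate flips
#' against the truth; the rate divides by the number of opportunities
#' (comparable sites minus one). Swapping the two estimated haplotypes
#' globally leaves the rate unchanged.
#'
#' @param est,truth [hap_set()] objects with `K = 2` over the same site set.
#' @return List: `switches`, `opportunities`, `mismatches` (always 0 for
#'   diploid comparisons), `swer` (`NA` when there are no opportunities).
#' @export
switch_error_diploid <- function(est, truth) {
  stopifnot(est$K == 2L, truth$K == 2L, est$n == truth$n)
  idx <- swer_comparable(est, truth)
  if (length(idx) < 2L)
    return(list(switches = 0L, opportunities = 0L, mismatches = 0L,
                swer = NA_real_))
  phase <- as.integer(est$alleles[1, idx] != truth$alleles[1, idx])
  switches <- sum(abs(diff(phase)))
  opp <- length(idx) - 1L
  list(switches = as.integer(switches), opportunities = opp,
       mismatches = 0L, swer = switches / opp)
}

#' Switch error rate for a K-ploid block
#'
#' Finds the minimum number of switches -- pairwise exchanges of haplotype
#' assignments between consecutive sites -- needed to align the estimated
#' haplotypes to the truth, by dynamic programming over the permutation of
#' `1..K` mapping estimated to true rows. Allele mismatches under the running
#' permutation (residual genotype errors) are charged equally inside the DP
#' and reported separately. Opportunities are `(comparable sites - 1) * (K -
#' 1)`: `K - 1` exchanges suffice to realize any permutation between adjacent
#' sites. With `K = 2` the value reduces exactly to
#' [switch_error_diploid()].
#'
#' @param est,truth [hap_set()] objects with the same K and site set.
#' @return List as in [switch_error_diploid()].
#' @export
switch_error_polyploid <- function(est, truth) {
  stopifnot(est$K == truth$K, est$n == truth$n)
  K <- est$K
  if (K > 8L) stop("permutation DP refused for K > 8", call. = FALSE)
  idx <- swer_comparable(est, truth)
  if (length(idx) < 2L)
    return(list(switches = 0L, opportunities = 0L, mismatches = 0L,
                swer = NA_real_))
  dp <- cpp_swer_dp(est$alleles[, idx, drop = FALSE],
                    truth$alleles[, idx, drop = FALSE])
  opp <- (length(idx) - 1L) * (K - 1L)
  list(switches = as.integer(dp$switches), opportunities = opp,
       mismatches = as.integer(dp$mismatches),
       swer = dp$switches / opp)
}

#' Score a phasing result against truth and/or reads
#'
#' Produces the per-block score table: MEC (when `fragments` are supplied)
#' and switch errors (when `truth` is supplied). The overall switch error
#' rate is total switches over total opportunities, pooled across blocks.
#'
#' @param phasing A [phase_fragments()] result.
#' @param truth Optional [hap_set()] of true haplotypes over the original
#'   site set.
#' @param fragments Optional original [frag_matrix()] for MEC re-scoring
#'   (the phasing already carries its per-block MEC).
#' @return A tibble of class `haplo_scores` with one row per block and
#'   columns `block`, `n_sites`, `mec`, `comparable`, `switches`,
#'   `opportunities`, `mismatches`, `swer`; attribute `overall` holds the
#'   pooled rates.
#' @export
score_phasing <- function(phasing, truth = NULL, fragments = NULL) {
  blocks <- phasing_blocks(phasing)
  rows <- purrr::map_dfr(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    out <- tibble::tibble(block = b, n_sites = length(blk$snps),
                          mec = as.integer(blk$mec),
                          comparable = NA_integer_, switches = NA_integer_,
                          opportunities = NA_integer_,
                          mismatches = NA_integer_, swer = NA_real_)
    if (!is.null(truth)) {
      tr <- hap_set(truth$alleles[, blk$snps, drop = FALSE])
      sw <- if (phasing$K == 2L) switch_error_diploid(blk$haps, tr)
            else switch_error_polyploid(blk$haps, tr)
      out$comparable <- length(swer_comparable(blk$haps, tr))
      out$switches <- sw$switches
      out$opportunities <- sw$opportunities
      out$mismatches <- sw$mismatches
      out$swer <- sw$swer
    }
    out
  })
  overall <- list(
    mec = sum(rows$mec),
    switches = if (is.null(truth)) NA_integer_ else sum(rows$switches),
    opportunities = if (is.null(truth)) NA_integer_ else sum(rows$opportunities),
    swer = if (is.null(truth) || sum(rows$opportunities) == 0) NA_real_
           else sum(rows$switches) / sum(rows$opportunities))
  if (!is.null(fragments)) {
    # independent re-score of the MEC on the original matrix
    overall$mec_full <- phasing_mec(phasing, fragments)
  }
  structure(rows, class = c("haplo_scores", class(rows)), overall = overall)
}

#' @export
print.haplo_scores <- function(x, ...) {
  NextMethod()
  ov <- attr(x, "overall")
  cat(sprintf("-- overall: MEC %d, SWER %s\n", ov$mec,
              if (is.na(ov$swer)) "n/a" else sprintf("%.4f", ov$swer)))
  invisible(x)
}

# MEC of the full phasing against an arbitrary fragment matrix: embeds each
# block's haplotypes at their original columns (gaps elsewhere).
phasing_mec <- function(phasing, fm) {
  blocks <- phasing_blocks(phasing)
  total <- 0L
  for (blk in blocks) {
    sel <- fm$calls$snp %in% blk$snps
    calls <- fm$calls[sel, , drop = FALSE]
    reads <- sort(unique(calls$read))
    remap_read <- match(calls$read, reads)
    remap_snp <- match(calls$snp, blk$snps)
    sub <- frag_matrix(data.frame(read = remap_read, snp = remap_snp,
                                  allele = calls$allele),
                       n_snps = length(blk$snps),
                       read_id = fm$read_id[reads],
                       alphabet_size = fm$alphabet_size)
    total <- total + mec_score(sub, blk$haps)
  }
  total
}
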
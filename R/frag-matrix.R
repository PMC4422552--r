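#' Sparse read-by-SNP fragment matrix
#'
#' The central data container: an `m` reads by `n` SNP sites sparse matrix of
#' observed allele codes, stored in long (triplet) form. Sites a read does not
#' cover are simply absent, which plays the role of the gap symbol.
#'
#' @param calls A data frame with integer columns `read` (1..m), `snp`
#'   (1..n_snps) and `allele` (code in `0:(alphabet_size - 1)`). One row per
#'   observed read base; (read, snp) pairs must be unique.
#' @param n_snps Number of SNP columns. Defaults to the largest covered index.
#' @param read_id Character vector of read names (length m). Defaults to
#'   `"read1".."readm"`.
#' @param alphabet_size Size of the reduced allele alphabet (2 for diploid,
#'   3 for triploid, 4 otherwise; see [alphabet_size_for()]).
#' @param qual Optional per-read quality strings, parsed from fragment files
#'   and retained but unused by the solvers.
#'
#' @return An object of class `frag_matrix` with fields `calls` (tibble),
#'   `n_reads`, `n_snps`, `read_id`, `alphabet_size`, `qual`.
#' @examples
#' fm <- frag_matrix(data.frame(read = c(1, 1, 2, 2),
#'                              snp  = c(1, 2, 2, 3),
#'                              allele = c(0, 1, 1, 0)))
#' fm
#' @export
frag_matrix <- function(calls, n_snps = NULL, read_id = NULL,
                        alphabet_size = 2L, qual = NULL) {
  calls <- tibble::tibble(read = as.integer(calls$read),
                          snp = as.integer(calls$snp),
                          allele = as.integer(calls$allele))
  m <- if (nrow(calls)) max(calls$read) else 0L
  if (!is.null(read_id)) m <- max(m, length(read_id))
  if (is.null(n_snps)) n_snps <- if (nrow(calls)) max(calls$snp) else 0L
  n_snps <- as.integer(n_snps)
  if (nrow(calls)) {
    if (min(calls$snp) < 1L || max(calls$snp) > n_snps)
      stop("SNP indices must lie in [1, n_snps]", call. = FALSE)
    if (min(calls$allele) < 0L || max(calls$allele) >= alphabet_size)
      stop("allele codes must lie in [0, alphabet_size)", call. = FALSE)
    if (anyDuplicated(calls[c("read", "snp")]))
      stop("duplicated (read, snp) call", call. = FALSE)
    calls <- dplyr::arrange(calls, .data$read, .data$snp)
  }
  if (is.null(read_id)) read_id <- paste0("read", seq_len(m))
  structure(list(calls = calls,
                 n_reads = as.integer(m),
                 n_snps = n_snps,
                 read_id = as.character(read_id),
                 alphabet_size = as.integer(alphabet_size),
                 qual = qual),
            class = "frag_matrix")
}

#' @export
print.frag_matrix <- function(x, ...) {
  cat(sprintf("<frag_matrix> %d reads x %d SNPs, %d calls, alphabet %d\n",
              x$n_reads, x$n_snps, nrow(x$calls), x$alphabet_size))
  invisible(x)
}

#' @export
as_tibble.frag_matrix <- function(x, ...) {
  dplyr::mutate(x$calls, read_id = x$read_id[.data$read], .before = 1)
}

#' Reduced alphabet size implied by the ploidy
#'
#' Genotype calls let the four-letter base alphabet collapse: a diploid site
#' carries two alleles (codes 0/1), a triploid at most three; beyond ploidy 4
#' no further reduction is possible.
#'
#' @param K Ploidy (>= 2).
#' @return Integer alphabet size `min(4, K)`.
#' @export
alphabet_size_for <- function(K) {
  K <- as.integer(K)
  if (K < 2L) stop("ploidy must be >= 2", call. = FALSE)
  min(4L, K)
}

#' Number of SNP sites covered by each read
#' @param fm A [frag_matrix()].
#' @return Integer vector of length `n_reads`.
#' @export
read_coverage <- function(fm) {
  tabulate(fm$calls$read, nbins = fm$n_reads)
}

#' Map raw base observations to reduced allele codes
#'
#' Converts per-site base calls (over A, C, G, T) into integer allele codes by
#' position within the site's genotype. Bases that are not part of the
#' genotype at their site are treated as sequencing errors and dropped (they
#' become gaps).
#'
#' @param raw_calls Data frame with columns `read`, `snp`, `base` (single
#'   characters in `A,C,G,T,-`).
#' @param genotype List (length `n_snps`) of character vectors: the distinct
#'   bases present among the K haplotypes at each site, in code order.
#' @param K Ploidy; fixes the reduced alphabet size via [alphabet_size_for()].
#' @param read_id Optional read names.
#' @return A [frag_matrix()] with integer allele codes.
#' @examples
#' raw <- data.frame(read = c(1, 1, 2), snp = c(1, 2, 1),
#'                   base = c("A", "G", "C"))
#' reduce_alphabet(raw, genotype = list(c("A", "G"), c("A", "G")), K = 2)
#' @export
reduce_alphabet <- function(raw_calls, genotype, K, read_id = NULL) {
  ab <- alphabet_size_for(K)
  n_snps <- length(genotype)
  sizes <- lengths(genotype)
  if (any(sizes > 4L))
    stop("invalid genotype: more than 4 distinct bases at a site", call. = FALSE)
  if (any(sizes > ab))
    stop(sprintf("invalid genotype: more than %d alleles at a site for K = %d",
                 ab, K), call. = FALSE)
  snp <- as.integer(raw_calls$snp)
  if (length(snp) && (min(snp) < 1L || max(snp) > n_snps))
    stop("SNP index outside genotype range", call. = FALSE)
  code <- integer(length(snp))
  for (j in unique(snp)) {
    sel <- snp == j
    code[sel] <- match(raw_calls$base[sel], genotype[[j]]) - 1L
  }
  keep <- !is.na(code)   # off-genotype bases and '-' are neglected
  m <- max(c(as.integer(raw_calls$read), 0L))
  if (is.null(read_id)) read_id <- paste0("read", seq_len(m))
  frag_matrix(data.frame(read = raw_calls$read[keep], snp = snp[keep],
                         allele = code[keep]),
              n_snps = n_snps, read_id = read_id, alphabet_size = ab)
}
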
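#' A set of K phased haplotypes
#'
#' Holds the K allele strings of one haplotype block as a `K x n` integer
#' matrix of allele codes (`NA` marks an unphased site). A site is homozygous
#' when all K alleles agree -- with genotyping errors present, the consensus
#' step may legitimately call such sites even though every column of the
#' fragment matrix was nominally heterozygous.
#'
#' @param alleles Integer matrix (K rows, n columns) of allele codes, or a
#'   character vector of K strings over `0-9` and `-`.
#' @return Object of class `hap_set` with fields `alleles`, `K`, `n`.
#' @examples
#' hap_set(c("0101", "1010"))
#' @export
hap_set <- function(alleles) {
  if (is.character(alleles)) {
    chars <- strsplit(alleles, "")
    if (length(unique(lengths(chars))) > 1)
      stop("all haplotype strings must have equal length", call. = FALSE)
    alleles <- do.call(rbind, lapply(chars, function(ch) {
      a <- suppressWarnings(as.integer(ch))
      a[ch == "-"] <- NA_integer_
      a
    }))
  }
  alleles <- matrix(as.integer(alleles), nrow = nrow(alleles))
  structure(list(alleles = alleles, K = nrow(alleles), n = ncol(alleles)),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> K = %d, %d sites, %d homozygous\n",
              x$K, x$n, sum(homozygous_sites(x))))
  shown <- min(x$n, 60L)
  for (l in seq_len(x$K)) {
    s <- x$alleles[l, seq_len(shown)]
    cat(" ", paste0(ifelse(is.na(s), "-", s), collapse = ""),
        if (shown < x$n) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
as_tibble.hap_set <- function(x, ...) {
  tibble::tibble(snp = rep(seq_len(x$n), each = x$K),
                 haplotype = rep(seq_len(x$K), x$n),
                 allele = as.integer(x$alleles[cbind(rep(seq_len(x$K), x$n),
                                                     rep(seq_len(x$n), each = x$K))]))
}

#' Which sites of a haplotype set are homozygous?
#' @param hs A [hap_set()].
#' @return Logical vector of length n: all K alleles equal (and phased).
#' @export
homozygous_sites <- function(hs) {
  if (hs$n == 0) return(logical(0))
  apply(hs$alleles, 2, function(a) !anyNA(a) && length(unique(a)) == 1L)
}

#' Which sites are heterozygous (non-constant allele vector)?
#' @param hs A [hap_set()].
#' @return Logical vector of length n.
#' @export
heterozygous_sites <- function(hs) {
  if (hs$n == 0) return(logical(0))
  apply(hs$alleles, 2, function(a) !anyNA(a) && length(unique(a)) > 1L)
}
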
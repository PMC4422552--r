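#' Build the weighted read-similarity graph of a haplotype block
#'
#' Every pair of reads overlapping in at least one SNP site is connected by an
#' edge carrying
#' \deqn{w_{ij} = (k_{sim} - k_{dissim}) / (k_{sim} + k_{dissim}),}
#' where \eqn{k_{sim}} counts overlap positions with identical allele codes
#' and \eqn{k_{dissim}} those with different codes (positions where either
#' read has a gap never count). Weights lie in `[-1, 1]`; reads from the same
#' haplotype should attract (`w > 0`) and reads from different haplotypes
#' repel (`w < 0`). Zero-weight edges (equal agreement and disagreement) are
#' retained: they certify connectivity and may carry Lagrange multipliers in
#' the polyploid solver.
#'
#' Overlap counts come from sparse cross-products of per-allele indicator
#' matrices, so construction is near-linear in the number of overlapping
#' pairs.
#'
#' @param fm A block-local [frag_matrix()] (see [split_blocks()]).
#' @return Object of class `read_graph`: `m` (vertices), parallel edge vectors
#'   `i`, `j` (1-based, `i < j`), `k_sim`, `k_dissim`, `w`, and `n_edges`.
#' @examples
#' fm <- frag_matrix(data.frame(read = c(1, 1, 2, 2),
#'                              snp = c(1, 2, 1, 2),
#'                              allele = c(0, 1, 0, 0)))
#' build_read_graph(fm)$w   # 1 agreement, 1 disagreement -> 0
#' @export
build_read_graph <- function(fm) {
  m <- fm$n_reads
  calls <- fm$calls
  if (m == 0L || nrow(calls) == 0L) {
    return(structure(list(m = m, i = integer(), j = integer(),
                          k_sim = integer(), k_dissim = integer(),
                          w = numeric(), n_edges = 0L),
                     class = "read_graph"))
  }
  A <- Matrix::sparseMatrix(i = calls$read, j = calls$snp, x = 1,
                            dims = c(m, fm$n_snps))
  total <- Matrix::tcrossprod(A)
  sim <- NULL
  for (code in unique(calls$allele)) {
    sel <- calls$allele == code
    Mc <- Matrix::sparseMatrix(i = calls$read[sel], j = calls$snp[sel], x = 1,
                               dims = c(m, fm$n_snps))
    cc <- Matrix::tcrossprod(Mc)
    sim <- if (is.null(sim)) cc else sim + cc
  }
  # both cross-products are symmetric with sorted upper-triangle storage;
  # a linear merge pairs each overlap count with its agreement count
  total <- methods::as(Matrix::forceSymmetric(total, uplo = "U"),
                       "CsparseMatrix")
  sim <- methods::as(Matrix::forceSymmetric(sim, uplo = "U"),
                     "CsparseMatrix")
  cnt <- cpp_edge_counts(total@p, total@i, total@x, sim@p, sim@i, sim@x, m)
  kt <- cnt$k_total
  ks <- cnt$k_sim
  kd <- kt - ks
  structure(list(m = m,
                 i = cnt$i, j = cnt$j,
                 k_sim = ks, k_dissim = kd,
                 w = (ks - kd) / kt,
                 n_edges = length(kt)),
            class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("<read_graph> %d reads, %d edges (mean |w| = %.3f)\n",
              x$m, x$n_edges, if (x$n_edges) mean(abs(x$w)) else NA_real_))
  invisible(x)
}

#' Edge list of a read graph as a tibble
#'
#' @param g A [build_read_graph()] result.
#' @return Tibble with columns `i`, `j`, `k_sim`, `k_dissim`, `w`; suitable
#'   for debugging dumps (e.g. `readr`/`write.table` TSV output).
#' @export
graph_edges <- function(g) {
  tibble::tibble(i = g$i, j = g$j, k_sim = g$k_sim,
                 k_dissim = g$k_dissim, w = g$w)
}
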
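#' Filter uninformative reads and SNP columns
#'
#' Reads covering fewer than two SNP sites carry no phase information and are
#' discarded; columns left uncovered by any remaining read are removed and the
#' surviving columns renumbered. The rule is applied to a fixed point, so
#' filtering an already-filtered matrix is the identity.
#'
#' @param fm A [frag_matrix()].
#' @return List with `fragments` (filtered [frag_matrix()]), `col_map`
#'   (tibble `snp` = new index, `original` = input index) and `reads_kept`
#'   (original indices of surviving reads).
#' @export
filter_fragments <- function(fm) {
  calls <- fm$calls
  read_keep <- seq_len(fm$n_reads)
  col_orig <- seq_len(fm$n_snps)
  repeat {
    m <- length(read_keep)
    cov <- tabulate(calls$read, nbins = m)
    ok <- cov >= 2L
    if (all(ok) ) {
      covered <- sort(unique(calls$snp))
      if (length(covered) == length(col_orig)) break
    }
    read_keep <- read_keep[ok]
    new_read <- cumsum(ok)
    calls <- calls[ok[calls$read], , drop = FALSE]
    calls$read <- new_read[calls$read]
    covered <- sort(unique(calls$snp))
    new_col <- integer(length(col_orig))
    new_col[covered] <- seq_along(covered)
    calls$snp <- new_col[calls$snp]
    col_orig <- col_orig[covered]
    if (all(cov[ok] >= 2L)) break
  }
  out <- frag_matrix(calls,
                     n_snps = length(col_orig),
                     read_id = fm$read_id[read_keep],
                     alphabet_size = fm$alphabet_size,
                     qual = fm$qual[read_keep])
  list(fragments = out,
       col_map = tibble::tibble(snp = seq_along(col_orig),
                                original = as.integer(col_orig)),
       reads_kept = as.integer(read_keep))
}

#' Partition SNP columns into connected haplotype blocks
#'
#' Two SNP columns belong to the same block when some chain of reads connects
#' them (each read links all the sites it covers). Discovery uses a simple
#' first-in first-out queue over the column graph; block labels 1, 2, ... are
#' assigned in first-discovery order.
#'
#' @param fm A filtered [frag_matrix()] (see [filter_fragments()]).
#' @return Object of class `block_partition`: list with `block` (integer label
#'   per SNP column), `n_blocks`, and `sizes`.
#' @export
connected_components <- function(fm) {
  n <- fm$n_snps
  labels <- integer(n)
  if (n > 0L && nrow(fm$calls)) {
    # adjacency: consecutive covered columns within each read chain the block
    by_read <- split(fm$calls$snp, fm$calls$read)
    a <- unlist(lapply(by_read, function(s) s[-length(s)]), use.names = FALSE)
    b <- unlist(lapply(by_read, function(s) s[-1L]), use.names = FALSE)
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    adj <- split(c(b, a), c(a, b))
    adj_idx <- as.integer(names(adj))
    nbrs <- vector("list", n)
    nbrs[adj_idx] <- lapply(adj, unique)
    queue <- integer(n)
    blk <- 0L
    for (start in seq_len(n)) {
      if (labels[start] != 0L) next
      blk <- blk + 1L
      labels[start] <- blk
      queue[1L] <- start
      head_ <- 1L; tail_ <- 1L
      while (head_ <= tail_) {
        v <- queue[head_]; head_ <- head_ + 1L
        for (u in nbrs[[v]]) {
          if (labels[u] == 0L) {
            labels[u] <- blk
            tail_ <- tail_ + 1L
            queue[tail_] <- u
          }
        }
      }
    }
  }
  structure(list(block = labels,
                 n_blocks = max(labels, 0L),
                 sizes = tabulate(labels)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d blocks over %d SNPs; largest %d\n",
              x$n_blocks, length(x$block), max(x$sizes, 0L)))
  invisible(x)
}

#' Split a fragment matrix into per-block sub-matrices
#'
#' @param fm A filtered [frag_matrix()].
#' @param partition A [connected_components()] result for `fm`.
#' @return List (one element per block) of lists with `fragments` (block-local
#'   [frag_matrix()]), `snps` (block-local -> `fm` column index) and `reads`
#'   (`fm` read indices). No read spans two blocks.
#' @export
split_blocks <- function(fm, partition) {
  lapply(seq_len(partition$n_blocks), function(b) {
    cols <- which(partition$block == b)
    local_col <- integer(fm$n_snps)
    local_col[cols] <- seq_along(cols)
    sel <- fm$calls$snp %in% cols
    calls <- fm$calls[sel, , drop = FALSE]
    reads <- sort(unique(calls$read))
    local_read <- integer(fm$n_reads)
    local_read[reads] <- seq_along(reads)
    calls <- data.frame(read = local_read[calls$read],
                        snp = local_col[calls$snp],
                        allele = calls$allele)
    list(fragments = frag_matrix(calls, n_snps = length(cols),
                                 read_id = fm$read_id[reads],
                                 alphabet_size = fm$alphabet_size),
         snps = cols,
         reads = reads)
  })
}

#' Fraction of SNP columns in the largest connected block
#'
#' Connectivity summary of a simulated (or real) fragment matrix: the share of
#' retained SNP columns that fall in the single largest haplotype block.
#'
#' @param fm A filtered [frag_matrix()].
#' @return A rate in `[0, 1]` (1 for a fully connected instance).
#' @export
largest_block_fraction <- function(fm) {
  if (fm$n_snps == 0L) return(NA_real_)
  p <- connected_components(fm)
  max(p$sizes) / fm$n_snps
}
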
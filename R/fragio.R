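#' Read a SNP-fragment file
#'
#' Parses the whitespace-separated fragment interchange format in which each
#' line describes one read (or mate pair) as runs of contiguous allele calls:
#'
#' ```
#' <n_pieces> <read_id> <start_1> <alleles_1> ... <start_p> <alleles_p> [quals]
#' ```
#'
#' SNP indices are 1-based. A trailing token after the declared pieces is
#' taken to be the per-base quality string; it is parsed and retained on the
#' returned object but not used by the solvers. In `"strict"` mode any other
#' surplus column is an error; `"lenient"` mode ignores unknown columns.
#'
#' @param path Path to the fragment file.
#' @param n_snps Total number of SNP sites; defaults to the largest index seen.
#' @param alphabet_size Allele alphabet size (codes `0:(alphabet_size-1)`).
#' @param dialect `"strict"` or `"lenient"`.
#' @return A [frag_matrix()].
#' @examples
#' f <- tempfile()
#' writeLines(c("1 readA 3 010", "2 readB 1 01 9 1"), f)
#' read_fragments(f, alphabet_size = 2)
#' @export
read_fragments <- function(path, n_snps = NULL, alphabet_size = 2L,
                           dialect = c("strict", "lenient")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("fragment file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(frag_matrix(data.frame(read = integer(), snp = integer(),
                                  allele = integer()),
                       n_snps = if (is.null(n_snps)) 0L else n_snps,
                       read_id = character(),
                       alphabet_size = alphabet_size))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  m <- length(toks)
  reads <- vector("list", m)
  ids <- character(m)
  quals <- rep(NA_character_, m)
  digits <- as.character(0:(alphabet_size - 1L))
  for (ln in seq_len(m)) {
    tk <- toks[[ln]]
    np <- suppressWarnings(as.integer(tk[1]))
    if (is.na(np) || np < 1L)
      stop(sprintf("line %d: invalid piece count '%s'", ln, tk[1]), call. = FALSE)
    need <- 2L + 2L * np
    if (length(tk) < need)
      stop(sprintf("line %d: expected %d fields for %d pieces, found %d",
                   ln, need, np, length(tk)), call. = FALSE)
    extra <- length(tk) - need
    if (extra == 1L) {
      quals[ln] <- tk[need + 1L]
    } else if (extra > 1L && dialect == "strict") {
      stop(sprintf("line %d: %d unexpected trailing fields", ln, extra),
           call. = FALSE)
    } else if (extra >= 1L && dialect == "lenient") {
      quals[ln] <- tk[need + 1L]
    }
    ids[ln] <- tk[2]
    starts <- suppressWarnings(as.integer(tk[seq(3L, by = 2L, length.out = np)]))
    runs <- tk[seq(4L, by = 2L, length.out = np)]
    if (anyNA(starts) || any(starts < 1L))
      stop(sprintf("line %d: non-numeric or non-positive piece start", ln),
           call. = FALSE)
    chars <- strsplit(runs, "")
    if (any(!unlist(chars) %in% digits))
      stop(sprintf("line %d: allele outside alphabet {%s}",
                   ln, paste(digits, collapse = ",")), call. = FALSE)
    ends <- starts + lengths(chars) - 1L
    if (np > 1L && any(starts[-1L] <= ends[-np]))
      stop(sprintf("line %d: pieces out of order or overlapping", ln),
           call. = FALSE)
    reads[[ln]] <- list(
      snp = sequence(lengths(chars), from = starts),
      allele = as.integer(unlist(chars)))
  }
  snp <- unlist(lapply(reads, `[[`, "snp"))
  if (!is.null(n_snps) && length(snp) && max(snp) > n_snps)
    stop(sprintf("SNP index %d beyond declared n_snps = %d", max(snp), n_snps),
         call. = FALSE)
  calls <- data.frame(
    read = rep.int(seq_len(m), vapply(reads, function(r) length(r$snp), 0L)),
    snp = snp,
    allele = unlist(lapply(reads, `[[`, "allele")))
  frag_matrix(calls, n_snps = n_snps, read_id = ids,
              alphabet_size = alphabet_size, qual = quals)
}

#' Write a fragment matrix to the fragment file format
#'
#' Inverse of [read_fragments()]: contiguous covered runs become pieces.
#' Reads with no calls are skipped.
#'
#' @param fm A [frag_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(fm, path) {
  by_read <- split(fm$calls[c("snp", "allele")], fm$calls$read)
  lines <- vapply(names(by_read), function(rr) {
    d <- by_read[[rr]]
    i <- as.integer(rr)
    brk <- c(0L, which(diff(d$snp) != 1L), nrow(d))
    pieces <- vapply(seq_len(length(brk) - 1L), function(p) {
      rows <- (brk[p] + 1L):brk[p + 1L]
      paste(d$snp[rows[1]], paste0(d$allele[rows], collapse = ""))
    }, "")
    qual <- fm$qual[i]
    paste(c(length(pieces), fm$read_id[i], pieces,
            if (!is.null(qual) && !is.na(qual)) qual), collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write whole-genome truth haplotypes
#'
#' Truth haplotype files hold one line per haplotype: a string of allele
#' codes with `-` for unphased sites.
#'
#' @param path File path.
#' @return `read_haplotypes()`: a [hap_set()].
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hap_set(trimws(lines))
}

#' @rdname read_haplotypes
#' @param hs A [hap_set()].
#' @export
write_haplotypes <- function(hs, path) {
  a <- hs$alleles
  a[is.na(a)] <- -1L
  lines <- apply(a, 1, function(row)
    paste0(ifelse(row < 0, "-", row), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write phased haplotype blocks
#'
#' One `BLOCK` header per connected component, then one line per site holding
#' the original 1-based SNP index and the K phased allele codes, and a
#' `********` terminator:
#'
#' ```
#' BLOCK 1 sites 2 mec 0
#' 3 0 1
#' 4 1 0
#' ********
#' ```
#'
#' @param blocks List of blocks, each a list with elements `snps` (original
#'   1-based SNP indices), `haps` (a [hap_set()]) and `mec` (count); or a
#'   `haplo_phasing` result, whose blocks are written.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_haplotype_blocks <- function(blocks, path) {
  if (inherits(blocks, "haplo_phasing")) blocks <- phasing_blocks(blocks)
  con <- file(path, "w")
  on.exit(close(con))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (length(blk$snps) != blk$haps$n)
      stop("block ", b, ": haplotype length does not match its SNP map",
           call. = FALSE)
    writeLines(sprintf("BLOCK %d sites %d mec %d",
                       b, blk$haps$n, as.integer(blk$mec)), con)
    a <- blk$haps$alleles
    a_chr <- matrix(ifelse(is.na(a), "-", a), nrow = nrow(a))
    for (j in seq_len(blk$haps$n))
      writeLines(paste(c(blk$snps[j], a_chr[, j]), collapse = " "), con)
    writeLines("********", con)
  }
  invisible(path)
}

#' Read a phased haplotype block file
#'
#' @param path Path written by [write_haplotype_blocks()].
#' @return List of blocks (`snps`, `haps`, `mec`).
#' @export
read_haplotype_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  blocks <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^BLOCK ", ln)) {
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(snps = integer(), rows = list(),
                  mec = as.integer(tk[match("mec", tk) + 1L]))
    } else if (grepl("^\\*+$", ln)) {
      mat <- do.call(cbind, cur$rows)
      blocks[[length(blocks) + 1L]] <-
        list(snps = cur$snps, haps = hap_set(mat), mec = cur$mec)
      cur <- NULL
    } else {
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      cur$snps <- c(cur$snps, as.integer(tk[1]))
      vals <- suppressWarnings(as.integer(tk[-1]))
      cur$rows[[length(cur$rows) + 1L]] <- vals
    }
  }
  blocks
}
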
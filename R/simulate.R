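#' Simulation parameters
#'
#' The generator emulates a long-insert paired-end sequencing design over a
#' single chromosome: SNP sites spaced by i.i.d. geometric gaps (human-like
#' rate of one SNP per ~300 bp), mate pairs of two 500 bp reads whose insert
#' (outer span) is normal with mean 10 kb and 10% standard deviation, uniform
#' per-base sequencing errors, and a fraction of sites planted as falsely
#' heterozygous to mimic genotyping errors.
#'
#' @param n_snps Number of SNP sites (default 1000).
#' @param K Ploidy (default 2).
#' @param p_snp Per-base SNP probability; mean gap `1/p_snp` (default 1/300).
#' @param read_len Read length in bases (default 500).
#' @param insert_mean Mean insert (outer fragment span), default 10000.
#' @param insert_sd Insert standard deviation, default 10% of the mean.
#' @param coverage Target per-base sequencing depth (default 30).
#' @param seq_err Per-base probability that a covered allele is replaced by a
#'   uniformly different allele (default 0.01).
#' @param geno_err Fraction of sites planted as falsely heterozygous: their
#'   true allele vector is constant, so a correct assembly calls them
#'   homozygous (default 0.01).
#' @param biallelic For K > 2, restrict true alleles to {0, 1} (default
#'   TRUE, the typical polyploid benchmark); multiallelic truth draws from
#'   the full reduced alphabet.
#' @param seed Optional seed making the whole simulation reproducible.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_snps = 1000L, K = 2L, p_snp = 1 / 300,
                       read_len = 500L, insert_mean = 10000,
                       insert_sd = 0.1 * insert_mean, coverage = 30,
                       seq_err = 0.01, geno_err = 0.01,
                       biallelic = TRUE, seed = NULL) {
  stopifnot(p_snp > 0, p_snp <= 1, seq_err >= 0, seq_err <= 1,
            geno_err >= 0, geno_err <= 1, coverage > 0,
            insert_mean >= read_len, K >= 2)
  structure(list(n_snps = as.integer(n_snps), K = as.integer(K),
                 p_snp = p_snp, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, seq_err = seq_err, geno_err = geno_err,
                 biallelic = isTRUE(biallelic), seed = seed),
            class = "sim_params")
}

with_sim_seed <- function(params, code) {
  if (is.null(params$seed)) code
  else withr::with_seed(as.integer(params$seed), code)
}

# non-constant allele vectors over {0, .., a-1}^K, uniformly
draw_het_columns <- function(n, K, alphabet) {
  H <- matrix(sample.int(alphabet, n * K, replace = TRUE) - 1L, K, n)
  repeat {
    const <- which(matrixStats_colAllEqual(H))
    if (!length(const)) break
    H[, const] <- matrix(sample.int(alphabet, length(const) * K,
                                    replace = TRUE) - 1L, K)
  }
  H
}

matrixStats_colAllEqual <- function(H) {
  colSums(H == rep(H[1, ], each = nrow(H))) == nrow(H)
}

#' Simulate true haplotypes and SNP coordinates
#'
#' Inter-SNP gaps are i.i.d. geometric with rate `p_snp` (support >= 1 base,
#' mean ~ `1/p_snp`). Diploid truth pairs a random allele string with its
#' complement; polyploid biallelic truth draws each site's allele vector
#' uniformly from the non-constant vectors of `{0,1}^K`. A `geno_err`
#' fraction of sites is planted as falsely heterozygous: the true vector is
#' constant there (the site should not have entered the SNP set), which
#' exercises homozygous-site correction downstream.
#'
#' @param params A [sim_params()].
#' @return Object of class `sim_truth`: `haplotypes` ([hap_set()]),
#'   `positions` (genome coordinates of the SNPs), `false_het` (logical),
#'   `params`.
#' @export
simulate_truth <- function(params = sim_params()) {
  with_sim_seed(params, {
    n <- params$n_snps
    K <- params$K
    gaps <- rgeom(n, params$p_snp) + 1L
    positions <- cumsum(gaps)
    alphabet <- alphabet_size_for(K)
    draw_ab <- if (params$biallelic || K == 2L) 2L else alphabet
    if (K == 2L) {
      h1 <- rbinom(n, 1L, 0.5)
      H <- rbind(h1, 1L - h1)
    } else {
      H <- draw_het_columns(n, K, draw_ab)
    }
    false_het <- runif(n) < params$geno_err
    if (any(false_het)) {
      hom <- sample.int(draw_ab, sum(false_het), replace = TRUE) - 1L
      H[, false_het] <- rep(hom, each = K)
    }
    rownames(H) <- NULL
    structure(list(haplotypes = hap_set(H), positions = positions,
                   false_het = false_het, params = params),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> K = %d, %d SNPs over %d bp (%d planted homozygous)\n",
              x$params$K, x$params$n_snps, max(x$positions), sum(x$false_het)))
  invisible(x)
}

#' Simulate paired-end reads over simulated truth
#'
#' Mate pairs start uniformly on the genome; the insert (outer span) is
#' normal with the configured mean and sd, truncated below at the read
#' length. Each pair copies the covered SNP alleles from one of the K
#' haplotypes chosen uniformly, then corrupts each copied allele with
#' probability `seq_err` to a uniformly different allele. The number of
#' pairs is set so the expected per-base depth equals `coverage`. Reads
#' covering no SNP are dropped at emission (single-SNP reads survive until
#' [filter_fragments()]).
#'
#' @param truth A [simulate_truth()] result.
#' @param params The matching [sim_params()]; defaults to `truth$params`.
#' @return List: `fragments` ([frag_matrix()]), `source` (true haplotype of
#'   origin, one of `1..K`, per emitted read), `genome_length`.
#' @export
simulate_reads <- function(truth, params = truth$params) {
  with_sim_seed(params, {
    # separate stream from simulate_truth when a seed is set
    if (!is.null(params$seed)) set.seed(as.integer(params$seed) + 1L)
    pos <- truth$positions
    K <- params$K
    L <- max(pos) + round(1 / params$p_snp)
    n_pairs <- as.integer(ceiling(params$coverage * L / (2 * params$read_len)))
    insert <- pmax(round(rnorm(n_pairs, params$insert_mean, params$insert_sd)),
                   params$read_len)
    start <- floor(runif(n_pairs, 1, pmax(L - insert, 1) + 1))
    src <- sample.int(K, n_pairs, replace = TRUE)
    rl <- params$read_len
    # covered SNP index ranges for both mates
    lo1 <- findInterval(start - 1L, pos) + 1L
    hi1 <- findInterval(start + rl - 1L, pos)
    s2 <- start + insert - rl
    lo2 <- pmax(findInterval(s2 - 1L, pos) + 1L, hi1 + 1L)  # avoid double-count
    hi2 <- findInterval(s2 + rl - 1L, pos)
    n1 <- pmax(hi1 - lo1 + 1L, 0L)
    n2 <- pmax(hi2 - lo2 + 1L, 0L)
    keep1 <- n1 > 0L
    keep2 <- n2 > 0L
    pair <- c(rep.int(seq_len(n_pairs)[keep1], n1[keep1]),
              rep.int(seq_len(n_pairs)[keep2], n2[keep2]))
    snp <- c(sequence(n1[keep1], from = lo1[keep1]),
             sequence(n2[keep2], from = lo2[keep2]))
    ord <- order(pair, snp)
    pair <- pair[ord]
    snp <- snp[ord]
    emitted <- sort(unique(pair))
    read <- match(pair, emitted)
    H <- truth$haplotypes$alleles
    allele <- H[cbind(src[pair], snp)]
    alphabet <- alphabet_size_for(K)
    # errors flip within the site's genotype alphabet (off-genotype bases
    # would be neglected by the alphabet reduction anyway)
    err_ab <- if (params$biallelic || K == 2L) 2L else alphabet
    err <- runif(length(allele)) < params$seq_err
    if (any(err)) {
      shift <- sample.int(err_ab - 1L, sum(err), replace = TRUE)
      allele[err] <- (allele[err] + shift) %% err_ab
    }
    fm <- frag_matrix(data.frame(read = read, snp = snp, allele = allele),
                      n_snps = params$n_snps,
                      read_id = paste0("sim", emitted),
                      alphabet_size = alphabet)
    list(fragments = fm, source = src[emitted], genome_length = L)
  })
}
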
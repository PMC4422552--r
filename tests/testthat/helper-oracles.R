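# Shared fixtures and brute-force oracles. Everything is generated in code;
# oracles are deliberately naive (enumeration / union-find) and independent
# of the package's algorithms.

# small fragment matrix from a dense matrix with NA as gap
fm_from_dense <- function(M, alphabet_size = 2L) {
  idx <- which(!is.na(M), arr.ind = TRUE)
  frag_matrix(data.frame(read = idx[, 1], snp = idx[, 2],
                         allele = M[idx]),
              n_snps = ncol(M),
              read_id = paste0("r", seq_len(nrow(M))),
              alphabet_size = alphabet_size)
}

# random sparse diploid-style fragment matrix
random_fm <- function(m, n, density = 0.6, alphabet = 2L) {
  M <- matrix(NA_integer_, m, n)
  for (i in seq_len(m)) {
    len <- max(2L, stats::rbinom(1, n, density))
    start <- sample.int(max(1L, n - len + 1L), 1)
    cols <- start:min(n, start + len - 1L)
    M[i, cols] <- sample.int(alphabet, length(cols), replace = TRUE) - 1L
  }
  M
}

# union-find oracle for SNP-column connectivity
uf_components <- function(fm) {
  n <- fm$n_snps
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  by_read <- split(fm$calls$snp, fm$calls$read)
  for (cols in by_read) {
    if (length(cols) < 2) next
    for (k in 2:length(cols)) {
      ra <- find(cols[1]); rb <- find(cols[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, 1L)
}

# exhaustive MAXCUT over all 2^m sign vectors; returns best cut value
brute_maxcut <- function(graph) {
  m <- graph$m
  best <- -Inf
  for (mask in 0:(2^m - 1)) {
    x <- ifelse(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0, 1, -1)
    cut <- sum(graph$w * x[graph$i] * x[graph$j])
    if (cut > best) best <- cut
  }
  best
}

# exhaustive best K-partition clustering objective
brute_best_kpartition <- function(graph, K) {
  m <- graph$m
  best <- -Inf
  lab <- integer(m)
  recurse <- function(pos) {
    if (pos > m) {
      same <- lab[graph$i] == lab[graph$j]
      obj <- sum(graph$w[same]) - sum(graph$w[!same])
      if (obj > best) best <<- obj
      return(invisible())
    }
    for (c in 0:(K - 1)) {
      lab[pos] <<- c
      recurse(pos + 1)
    }
  }
  recurse(1)
  best
}

# exhaustive diploid MEC over every haplotype pair in {0,1}^n x {0,1}^n
# (homozygous sites allowed, as greedy refinement may call them)
brute_mec_pairs <- function(fm) {
  n <- fm$n_snps
  m <- fm$n_reads
  H <- as.matrix(expand.grid(rep(list(0:1), n)))   # 2^n x n
  A0 <- A1 <- matrix(0, m, n)
  A0[cbind(fm$calls$read, fm$calls$snp)] <- as.integer(fm$calls$allele == 0L)
  A1[cbind(fm$calls$read, fm$calls$snp)] <- as.integer(fm$calls$allele == 1L)
  # hd(read, candidate) = observed-0 sites where h = 1, plus vice versa
  hd <- A0 %*% t(H) + A1 %*% (1 - t(H))            # m x 2^n
  best <- Inf
  for (a in seq_len(nrow(H))) {
    z <- min(colSums(matrix(pmin(hd[, a], hd), nrow = m)))
    if (z < best) best <- z
  }
  best
}

# exhaustive minimum switch count over all permutation sequences (tiny n, K)
brute_min_switches <- function(est, truth) {
  K <- est$K
  n <- est$n
  perms <- perm_matrix(K)
  P <- nrow(perms)
  emis <- function(p, j) sum(est$alleles[perms[p, ], j] != truth$alleles[, j])
  tdist <- function(p, q) {
    a <- perms[p, ]; b <- perms[q, ]
    rel <- b[order(a)]
    seen <- logical(K); cycles <- 0L
    for (k in seq_len(K)) {
      if (seen[k]) next
      cycles <- cycles + 1L
      c <- k
      while (!seen[c]) { seen[c] <- TRUE; c <- rel[c] }
    }
    K - cycles
  }
  best <- Inf
  seqs <- rep(list(seq_len(P)), n)
  grid <- do.call(expand.grid, seqs)
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(grid[r, ])
    cost <- sum(vapply(seq_len(n), function(j) emis(path[j], j), 0))
    if (n > 1)
      cost <- cost + sum(vapply(2:n, function(j) tdist(path[j - 1], path[j]), 0L))
    if (cost < best) best <- cost
  }
  best
}

perm_matrix <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(K - 1)
  do.call(rbind, lapply(seq_len(K), function(pos) {
    t(apply(sub, 1, function(p) append(p, K, after = pos - 1)))
  }))
}

# tiny error-free two-haplotype read set; one full-span read per haplotype
# guarantees both clusters cover every site
perfect_diploid_fm <- function(n = 6, reads_per_hap = 4, seed = 1) {
  withr::with_seed(seed, {
    h1 <- sample(0:1, n, replace = TRUE)
    H <- rbind(h1, 1L - h1)
    M <- matrix(NA_integer_, 2 * reads_per_hap, n)
    for (i in seq_len(2 * reads_per_hap)) {
      hap <- if (i <= reads_per_hap) 1 else 2
      start <- sample.int(n - 1L, 1)
      len <- sample(2:min(4, n - start + 1L), 1)
      cols <- start:(start + len - 1L)
      M[i, cols] <- H[hap, cols]
    }
    M[1, ] <- H[1, ]
    M[reads_per_hap + 1L, ] <- H[2, ]
    list(fm = fm_from_dense(M), truth = hap_set(H),
         labels = rep(0:1, each = reads_per_hap))
  })
}
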
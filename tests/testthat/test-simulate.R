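test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_snps = 50, coverage = 8, seed = 123)
  t1 <- simulate_truth(p)
  t2 <- simulate_truth(p)
  expect_equal(t1$haplotypes$alleles, t2$haplotypes$alleles)
  expect_equal(t1$positions, t2$positions)
  r1 <- simulate_reads(t1, p)
  r2 <- simulate_reads(t2, p)
  expect_equal(r1$fragments$calls, r2$fragments$calls)
  expect_equal(r1$source, r2$source)
})

test_that("inter-SNP gaps have the configured geometric mean", {
  p <- sim_params(n_snps = 10000, p_snp = 1 / 300, seed = 7)
  tr <- simulate_truth(p)
  gaps <- diff(tr$positions)
  # mean gap ~ 1/p = 300; geometric sd ~ sqrt(1-p)/p, se = sd/sqrt(n)
  se <- (sqrt(1 - p$p_snp) / p$p_snp) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 300), 3 * se + 1)
  expect_true(all(gaps >= 1))
})

test_that("diploid truth is complementary; planted sites are constant", {
  p <- sim_params(n_snps = 400, K = 2, geno_err = 0.1, seed = 5)
  tr <- simulate_truth(p)
  H <- tr$haplotypes$alleles
  expect_true(all(H[1, !tr$false_het] != H[2, !tr$false_het]))
  expect_true(all(H[1, tr$false_het] == H[2, tr$false_het]))
  expect_gt(sum(tr$false_het), 0)
})

test_that("polyploid biallelic truth has no constant unplanted columns", {
  p <- sim_params(n_snps = 300, K = 4, geno_err = 0, seed = 9)
  tr <- simulate_truth(p)
  H <- tr$haplotypes$alleles
  expect_true(all(H %in% 0:1))
  expect_true(all(apply(H, 2, function(x) length(unique(x))) > 1))
})

test_that("error-free reads have zero MEC against the truth", {
  p <- sim_params(n_snps = 120, K = 3, coverage = 12, seq_err = 0,
                  geno_err = 0, seed = 21)
  tr <- simulate_truth(p)
  rd <- simulate_reads(tr, p)
  expect_equal(mec_score(rd$fragments, tr$haplotypes), 0L)
})

test_that("realized SNP depth is close to the nominal coverage", {
  p <- sim_params(n_snps = 500, coverage = 20, seed = 31)
  tr <- simulate_truth(p)
  rd <- simulate_reads(tr, p)
  depth <- tabulate(rd$fragments$calls$snp, nbins = p$n_snps)
  expect_lt(abs(mean(depth) - p$coverage) / p$coverage, 0.1)
})

test_that("the long-insert protocol produces a dominant connected block", {
  p <- sim_params(n_snps = 300, coverage = 10, seed = 41)
  tr <- simulate_truth(p)
  rd <- simulate_reads(tr, p)
  fm <- filter_fragments(rd$fragments)$fragments
  expect_gte(largest_block_fraction(fm), 0.99)
})

test_that("reads cite their source haplotype faithfully at zero error", {
  p <- sim_params(n_snps = 100, K = 2, coverage = 10, seq_err = 0,
                  geno_err = 0, seed = 51)
  tr <- simulate_truth(p)
  rd <- simulate_reads(tr, p)
  calls <- rd$fragments$calls
  src <- rd$source[calls$read]
  expect_true(all(calls$allele == tr$haplotypes$alleles[cbind(src, calls$snp)]))
})

test_that("planted falsely-heterozygous sites are called homozygous", {
  # desk-scale check of homozygous-site correction at diploid coverage 30
  p <- sim_params(n_snps = 300, K = 2, coverage = 30, seq_err = 0.01,
                  geno_err = 0.05, seed = 61)
  tr <- simulate_truth(p)
  rd <- simulate_reads(tr, p)
  res <- phase_fragments(rd$fragments, K = 2, mode = "allow_homozygous",
                         params = solver_params(seed = 62))
  called_hom <- logical(p$n_snps)
  for (blk in phasing_blocks(res))
    called_hom[blk$snps] <- homozygous_sites(blk$haps)
  planted <- which(tr$false_het)
  expect_gt(length(planted), 5)
  expect_gte(mean(called_hom[planted]), 0.9)
})

test_that("assembled diploid phase is near-perfect at coverage 30", {
  # scaled-down version of the full-pipeline property (n = 200, 3 seeds)
  swers <- vapply(1:3, function(seed) {
    p <- sim_params(n_snps = 200, K = 2, coverage = 30, seq_err = 0.01,
                    seed = 70 + seed)
    tr <- simulate_truth(p)
    rd <- simulate_reads(tr, p)
    res <- phase_fragments(rd$fragments, K = 2,
                           params = solver_params(seed = 80 + seed))
    attr(score_phasing(res, truth = tr$haplotypes), "overall")$swer
  }, 0)
  expect_true(all(swers < 0.01))
})
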
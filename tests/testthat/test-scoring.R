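test_that("MEC counts only covered disagreeing positions", {
  haps <- hap_set(c("0101", "1010"))
  fm0 <- fm_from_dense(rbind(c(0L, 1L, NA, NA), c(NA, 0L, 1L, 0L)))
  expect_equal(mec_score(fm0, haps), 0L)   # substrings of the haplotypes
  fm1 <- fm_from_dense(rbind(c(0L, 0L, NA, NA)))   # one flipped base
  expect_equal(mec_score(fm1, haps), 1L)
  # a read covering nothing contributes nothing
  fm2 <- frag_matrix(data.frame(read = 1L, snp = 1L, allele = 0L),
                     n_snps = 4, read_id = c("a"))
  expect_equal(mec_score(fm2, haps), 0L)
  expect_error(mec_score(fm_from_dense(rbind(c(0L, 1L))), haps), "length")
})

test_that("diploid switch errors count relative phase flips", {
  tr <- hap_set(c("010101", "101010"))
  expect_equal(switch_error_diploid(tr, tr)$swer, 0)
  swapped <- hap_set(tr$alleles[2:1, ])
  expect_equal(switch_error_diploid(swapped, tr)$swer, 0)   # label invariance
  # single phase flip from site 4 onward: 1 switch over 5 opportunities
  est <- hap_set(rbind(c(0L, 1L, 0L, 0L, 1L, 0L),
                       c(1L, 0L, 1L, 1L, 0L, 1L)))
  r <- switch_error_diploid(est, tr)
  expect_equal(r$switches, 1L)
  expect_equal(r$opportunities, 5L)
  expect_equal(r$swer, 0.2)
})

test_that("homozygous sites are excluded from switch comparison", {
  tr <- hap_set(rbind(c(0L, 0L, 1L, 0L), c(1L, 0L, 0L, 1L)))   # site 2 hom
  est <- hap_set(rbind(c(0L, 1L, 1L, 0L), c(1L, 1L, 0L, 1L)))  # est hom at 2? no: het
  r <- switch_error_diploid(est, tr)
  expect_equal(r$opportunities, 2L)   # 3 comparable het sites
  expect_equal(r$switches, 0L)
  # degenerate: no comparable sites -> flagged undefined rate
  r0 <- switch_error_diploid(hap_set(c("00", "00")), hap_set(c("01", "10")))
  expect_equal(r0$opportunities, 0L)
  expect_true(is.na(r0$swer))
})

test_that("polyploid DP equals the diploid scan at K = 2", {
  withr::with_seed(31, {
    for (trial in 1:8) {
      n <- 8
      h1 <- sample(0:1, n, replace = TRUE)
      tr <- hap_set(rbind(h1, 1L - h1))
      e1 <- sample(0:1, n, replace = TRUE)
      est <- hap_set(rbind(e1, 1L - e1))
      a <- switch_error_diploid(est, tr)
      b <- switch_error_polyploid(est, tr)
      expect_equal(b$switches, a$switches)
      expect_equal(b$opportunities, a$opportunities)
    }
  })
})

test_that("row permutations of the truth cost zero switches", {
  withr::with_seed(17, {
    H <- matrix(sample(0:1, 3 * 7, replace = TRUE), 3)
  })
  H[, 1] <- c(0L, 1L, 0L)   # ensure non-constant columns exist
  tr <- hap_set(H)
  est <- hap_set(H[c(3, 1, 2), ])
  expect_equal(switch_error_polyploid(est, tr)$switches, 0L)
})

test_that("a planted two-row tail swap costs exactly one switch", {
  withr::with_seed(23, {
    repeat {
      H <- matrix(sample(0:1, 3 * 6, replace = TRUE), 3)
      if (all(apply(H, 2, function(x) length(unique(x)) > 1))) break
    }
  })
  tr <- hap_set(H)
  H2 <- H
  H2[1:2, 4:6] <- H[2:1, 4:6]
  r <- switch_error_polyploid(hap_set(H2), tr)
  expect_equal(r$switches, 1L)
  expect_equal(r$opportunities, (6L - 1L) * 2L)
})

test_that("the permutation DP matches brute force on tiny instances", {
  withr::with_seed(41, {
    for (trial in 1:6) {
      n <- 4
      K <- 3
      H <- matrix(sample(0:1, K * n, replace = TRUE), K)
      E <- matrix(sample(0:1, K * n, replace = TRUE), K)
      dp <- haploclust:::cpp_swer_dp(E, H)
      expect_equal(dp$total, brute_min_switches(hap_set(E), hap_set(H)))
    }
  })
})

test_that("K > 8 is refused", {
  H <- matrix(0L, 9, 3)
  expect_error(switch_error_polyploid(hap_set(H), hap_set(H)), "K > 8")
})

test_that("score_phasing aggregates switches over blocks", {
  px <- perfect_diploid_fm(n = 8, reads_per_hap = 6, seed = 13)
  res <- phase_fragments(px$fm, K = 2, params = solver_params(seed = 3))
  sc <- score_phasing(res, truth = px$truth, fragments = px$fm)
  expect_s3_class(sc, "haplo_scores")
  ov <- attr(sc, "overall")
  expect_equal(ov$mec, 0L)
  expect_equal(ov$swer, 0)
  g <- glance(sc)
  expect_equal(g$swer, 0)
})
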
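test_that("fragment lines decode into covered runs", {
  f <- withr::local_tempfile()
  writeLines(c("1 readA 3 010",
               "2 readB 1 01 9 1"), f)
  fm <- read_fragments(f, alphabet_size = 2)
  expect_equal(fm$n_reads, 2L)
  expect_equal(fm$read_id, c("readA", "readB"))
  a <- fm$calls[fm$calls$read == 1, ]
  expect_equal(a$snp, 3:5)
  expect_equal(a$allele, c(0L, 1L, 0L))
  b <- fm$calls[fm$calls$read == 2, ]
  expect_equal(b$snp, c(1L, 2L, 9L))   # mate pair with a gap
  expect_equal(b$allele, c(0L, 1L, 1L))
})

test_that("empty file gives an empty matrix", {
  f <- withr::local_tempfile(lines = character())
  fm <- read_fragments(f)
  expect_equal(fm$n_reads, 0L)
  expect_equal(fm$n_snps, 0L)
  expect_equal(nrow(fm$calls), 0L)
})

test_that("malformed lines are rejected with their line number", {
  f <- withr::local_tempfile()
  writeLines(c("1 ok 1 01", "2 bad 1 01"), f)
  expect_error(read_fragments(f), "line 2")
  writeLines("1 bad x 01", f)
  expect_error(read_fragments(f), "line 1")
  writeLines("1 bad 1 07", f)
  expect_error(read_fragments(f), "alphabet")
  writeLines("1 far 12 01", f)
  expect_error(read_fragments(f, n_snps = 5), "beyond")
  writeLines("1 ok 1 01 junk extra", f)
  expect_error(read_fragments(f, dialect = "strict"), "trailing")
  expect_silent(read_fragments(f, dialect = "lenient"))
})

test_that("quality strings are retained but unused", {
  f <- withr::local_tempfile()
  writeLines("1 readQ 1 010 ABC", f)
  fm <- read_fragments(f)
  expect_equal(fm$qual, "ABC")
  expect_equal(fm$calls$allele, c(0L, 1L, 0L))
})

test_that("write -> parse round-trips a fragment matrix", {
  withr::with_seed(42, {
    M <- random_fm(8, 10)
  })
  fm <- fm_from_dense(M)
  f <- withr::local_tempfile()
  write_fragments(fm, f)
  fm2 <- read_fragments(f, n_snps = 10)
  expect_equal(fm2$calls, fm$calls)
  expect_equal(fm2$read_id, fm$read_id)
})

test_that("alphabet reduction maps bases to genotype positions", {
  geno <- list(c("A", "G"), c("C", "T"))
  raw <- data.frame(read = c(1, 1, 2, 2),
                    snp = c(1, 2, 1, 2),
                    base = c("G", "C", "A", "G"))
  fm <- reduce_alphabet(raw, geno, K = 2)
  expect_equal(fm$alphabet_size, 2L)
  # read 2's G at site 2 is off-genotype: neglected (gap)
  expect_equal(nrow(fm$calls), 3L)
  expect_equal(fm$calls$allele[fm$calls$read == 1], c(1L, 0L))
  # no emitted code ever reaches the alphabet size
  expect_true(all(fm$calls$allele < fm$alphabet_size))
})

test_that("higher ploidy keeps the four-letter alphabet", {
  geno <- list(c("A", "C", "G", "T"))
  raw <- data.frame(read = 1:4, snp = 1, base = c("A", "C", "G", "T"))
  fm <- reduce_alphabet(raw, geno, K = 4)
  expect_equal(fm$alphabet_size, 4L)
  expect_equal(sort(fm$calls$allele), 0:3)
  expect_error(reduce_alphabet(raw, list(c("A", "C", "G", "T", "N")), K = 6),
               "invalid genotype")
})

test_that("haplotype block files round-trip", {
  blocks <- list(
    list(snps = c(3L, 4L), haps = hap_set(c("01", "10")), mec = 0L),
    list(snps = c(7L, 8L, 9L), haps = hap_set(c("012", "120", "201")), mec = 2L))
  f <- withr::local_tempfile()
  write_haplotype_blocks(blocks, f)
  back <- read_haplotype_blocks(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$snps, blocks[[1]]$snps)
  expect_equal(back[[2]]$haps$alleles, blocks[[2]]$haps$alleles)
  expect_equal(vapply(back, `[[`, 0L, "mec"), c(0L, 2L))
  # zero blocks -> empty file, empty list
  write_haplotype_blocks(list(), f)
  expect_length(read_haplotype_blocks(f), 0L)
  # length mismatch is a contract violation
  bad <- list(list(snps = 1:3, haps = hap_set(c("01", "10")), mec = 0L))
  expect_error(write_haplotype_blocks(bad, f), "match")
})

test_that("truth haplotype files round-trip with unphased markers", {
  hs <- hap_set(rbind(c(0L, 1L, NA), c(1L, 0L, NA)))
  f <- withr::local_tempfile()
  write_haplotypes(hs, f)
  expect_equal(readLines(f), c("01-", "10-"))
  back <- read_haplotypes(f)
  expect_equal(back$alleles, hs$alleles)
})
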
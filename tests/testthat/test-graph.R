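test_that("single-SNP reads and uncovered columns are filtered out", {
  M <- rbind(c(0L, 1L, NA, NA),
             c(NA, 1L, 0L, NA),
             c(NA, NA, NA, 0L))   # read 3 covers one SNP only
  fm <- fm_from_dense(M)
  filt <- filter_fragments(fm)
  expect_equal(filt$fragments$n_reads, 2L)
  # column 4 was covered only by the dropped read: removed, indices shift
  expect_equal(filt$fragments$n_snps, 3L)
  expect_equal(filt$col_map$original, 1:3)
  expect_equal(filt$reads_kept, 1:2)
})

test_that("filtering is idempotent", {
  withr::with_seed(11, M <- random_fm(10, 8, density = 0.3))
  fm <- fm_from_dense(M)
  f1 <- filter_fragments(fm)
  f2 <- filter_fragments(f1$fragments)
  expect_equal(f2$fragments$calls, f1$fragments$calls)
  expect_equal(f2$col_map$snp, f2$col_map$original)
})

test_that("components join columns chained by reads", {
  fm <- fm_from_dense(rbind(c(0L, 1L, NA),
                            c(NA, 1L, 0L)))
  p <- connected_components(fm)
  expect_equal(p$n_blocks, 1L)
  expect_equal(p$block, rep(1L, 3))

  fm2 <- fm_from_dense(rbind(c(0L, 1L, NA, NA),
                             c(NA, NA, 1L, 0L)))
  p2 <- connected_components(fm2)
  expect_equal(p2$n_blocks, 2L)
  expect_equal(p2$block, c(1L, 1L, 2L, 2L))
})

test_that("components match a union-find oracle on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      M <- random_fm(25, 50, density = 0.05)
    })
    fm <- filter_fragments(fm_from_dense(M))$fragments
    if (fm$n_snps == 0) next
    p <- connected_components(fm)
    roots <- uf_components(fm)
    # identical partitions up to label names
    expect_equal(match(p$block, unique(p$block)),
                 match(roots, unique(roots)))
  }
})

test_that("edge weights follow the similarity formula", {
  # 3 agreements, 1 disagreement -> (3-1)/(3+1)
  fm <- fm_from_dense(rbind(c(0L, 1L, 0L, 1L),
                            c(0L, 1L, 0L, 0L)))
  g <- build_read_graph(fm)
  expect_equal(g$n_edges, 1L)
  expect_equal(g$w, 0.5)
  expect_equal(g$k_sim, 3L)
  expect_equal(g$k_dissim, 1L)

  # identical overlap -> +1; fully discordant -> -1
  g1 <- build_read_graph(fm_from_dense(rbind(c(0L, 1L), c(0L, 1L))))
  expect_equal(g1$w, 1)
  g2 <- build_read_graph(fm_from_dense(rbind(c(0L, 1L), c(1L, 0L))))
  expect_equal(g2$w, -1)

  # no overlapping position -> no edge
  g3 <- build_read_graph(fm_from_dense(rbind(c(0L, 1L, NA, NA),
                                             c(NA, NA, 1L, 0L))))
  expect_equal(g3$n_edges, 0L)

  # gap positions are excluded from both counts
  g4 <- build_read_graph(fm_from_dense(rbind(c(0L, 1L, 0L),
                                             c(0L, NA, 1L))))
  expect_equal(g4$k_sim, 1L)
  expect_equal(g4$k_dissim, 1L)
  expect_equal(g4$w, 0)   # balanced overlap is kept as an explicit zero edge
})

test_that("the graph is symmetric under read permutation", {
  withr::with_seed(7, M <- random_fm(12, 9))
  fm <- fm_from_dense(M)
  g <- build_read_graph(fm)
  perm <- withr::with_seed(8, sample(nrow(M)))
  fmp <- fm_from_dense(M[perm, , drop = FALSE])
  gp <- build_read_graph(fmp)
  key <- function(g, map = seq_len(g$m)) {
    i <- map[g$i]; j <- map[g$j]
    o <- order(pmin(i, j), pmax(i, j))
    d <- data.frame(i = pmin(i, j)[o], j = pmax(i, j)[o], w = g$w[o])
    rownames(d) <- NULL
    d
  }
  expect_equal(key(gp, perm), key(g), tolerance = 1e-12)
})

test_that("error-free diploid reads give +/-1 weights by haplotype", {
  px <- perfect_diploid_fm(n = 6, reads_per_hap = 5, seed = 3)
  g <- build_read_graph(px$fm)
  lab <- px$labels
  same <- lab[g$i] == lab[g$j]
  expect_true(all(g$w[same] == 1))
  expect_true(all(g$w[!same] == -1))
})

test_that("largest_block_fraction measures column connectivity", {
  fm1 <- fm_from_dense(rbind(c(0L, 1L, 0L), c(0L, 1L, 0L)))
  expect_equal(largest_block_fraction(fm1), 1)
  fm2 <- fm_from_dense(rbind(c(0L, 1L, NA, NA), c(NA, NA, 1L, 0L)))
  expect_equal(largest_block_fraction(fm2), 0.5)
  for (seed in 1:3) {
    withr::with_seed(seed, M <- random_fm(15, 30, density = 0.07))
    fm <- filter_fragments(fm_from_dense(M))$fragments
    if (fm$n_snps == 0) next
    roots <- uf_components(fm)
    expect_equal(largest_block_fraction(fm),
                 max(table(roots)) / fm$n_snps)
  }
})

test_that("split_blocks keeps reads within a single block", {
  withr::with_seed(5, M <- random_fm(20, 24, density = 0.08))
  fm <- filter_fragments(fm_from_dense(M))$fragments
  p <- connected_components(fm)
  blocks <- split_blocks(fm, p)
  expect_length(blocks, p$n_blocks)
  seen_reads <- unlist(lapply(blocks, `[[`, "reads"))
  expect_equal(sort(seen_reads), seq_len(fm$n_reads))   # each read exactly once
  for (b in seq_along(blocks)) {
    expect_equal(sort(unique(p$block[blocks[[b]]$snps])), b)
  }
})
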
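test_that("HiC-Pro triplet parsing handles counts, empty files and errors", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "m_abs.bed")
  mtx <- file.path(dir, "m.matrix")
  writeLines(c("chr1\t0\t40000\t1", "chr1\t40000\t80000\t2"), bed)
  writeLines(c("1\t1\t10", "1\t2\t4", "2\t2\t8"), mtx)
  m <- read_hicpro_matrix(bed, mtx)
  expect_equal(nrow(m$entries), 3L)
  expect_equal(sum(m$entries$count), 22)
  expect_equal(m$total_valid_pairs, 22)

  writeLines(character(), mtx)
  m0 <- read_hicpro_matrix(bed, mtx)
  expect_equal(nrow(m0$entries), 0L)

  writeLines("1\t7\t3", mtx)
  expect_error(read_hicpro_matrix(bed, mtx), "unknown bin id")

  writeLines(c("chr1\t0\t40000\t1", "chr1\t40000\t100000\t2",
               "chr1\t100000\t120000\t3"), bed)
  writeLines("1\t1\t5", mtx)
  expect_error(read_hicpro_matrix(bed, mtx), "inconsistent bin width")
})

test_that("inter-chromosomal triplets are dropped with a warning", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "m_abs.bed")
  mtx <- file.path(dir, "m.matrix")
  writeLines(c("chr1\t0\t40000\t1", "chr2\t0\t40000\t2"), bed)
  writeLines(c("1\t1\t3", "1\t2\t9"), mtx)
  expect_warning(m <- read_hicpro_matrix(bed, mtx), "inter-chromosomal")
  expect_equal(nrow(m$entries), 1L)
})

test_that("write/read round-trip is entry-exact and honors the stats sidecar", {
  dir <- withr::local_tempdir()
  for (seed in 1:5) {
    m <- mk_random_matrix(n_bins = 50, seed = seed)
    paths <- write_hicpro_matrix(m, file.path(dir, paste0("rt", seed)))
    back <- read_hicpro_matrix(paths["bins"], paths["matrix"], paths["stats"])
    expect_identical(back$entries, m$entries)
    expect_equal(back$total_valid_pairs, m$total_valid_pairs)
    expect_identical(back$layout$chromosomes$name, m$layout$chromosomes$name)
    expect_equal(back$layout$chromosomes$length, m$layout$chromosomes$length)
    expect_equal(back$layout$bin_size, m$layout$bin_size)
  }
})

test_that("down-sampling is identity at 1, empty at 0, binomial in between", {
  m <- mk_random_matrix(n_bins = 30, seed = 3)
  expect_identical(downsample_pairs(m, 1, seed = 1)$entries, m$entries)
  expect_equal(nrow(downsample_pairs(m, 0, seed = 1)$entries), 0L)
  expect_error(downsample_pairs(m, 1.5, seed = 1), "fraction")

  layout <- mk_layout(c(chr1 = 8e4))
  big <- contact_matrix(layout, data.frame(bin1 = 1, bin2 = 2, count = 10000))
  thin <- downsample_pairs(big, 0.5, seed = 7)
  expect_lt(abs(thin$total_valid_pairs - 5000), 4 * sqrt(10000 * 0.25))
  # deterministic given the seed, leaves global RNG untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  again <- downsample_pairs(big, 0.5, seed = 7)
  expect_identical(thin$entries, again$entries)
  expect_equal(runif(1), before)

  non_int <- contact_matrix(layout, data.frame(bin1 = 1, bin2 = 2,
                                               count = 1.5))
  expect_error(downsample_pairs(non_int, 0.5, seed = 1), "integer")
})

test_that("distance-decay profile reflects the planted decay", {
  layout <- mk_layout(c(chr1 = 4e5))  # 10 bins
  pairs <- expand.grid(bin1 = 1:10, bin2 = 1:10)
  pairs <- pairs[pairs$bin1 < pairs$bin2, ]
  # uniform counts -> constant profile
  uni <- contact_matrix(layout, transform(pairs, count = 7))
  pu <- distance_decay_profile(uni)
  expect_true(all(pu$mean_count == 7))
  # counts = 100 / (d in bins) -> profile proportional to 1/d
  dec <- contact_matrix(layout,
                        transform(pairs, count = 100 / (bin2 - bin1)))
  pd <- distance_decay_profile(dec)
  expect_equal(pd$mean_count, 100 / (pd$distance / 4e4))
  # single entry -> single point; empty matrix -> empty profile
  one <- contact_matrix(layout, data.frame(bin1 = 1, bin2 = 3, count = 5))
  expect_equal(nrow(distance_decay_profile(one)), 1L)
  empty <- contact_matrix(layout, data.frame(bin1 = integer(),
                                             bin2 = integer(),
                                             count = numeric()))
  expect_equal(nrow(distance_decay_profile(empty)), 0L)
})

test_that("matrix correlation is 1 for self and scaled copies, near 0 for noise", {
  m <- mk_random_matrix(n_bins = 40, seed = 11)
  expect_equal(matrix_correlation(m, m), 1)
  doubled <- contact_matrix(m$layout, transform(m$entries, count = count * 2))
  expect_equal(matrix_correlation(m, doubled, "pearson"), 1)
  expect_equal(matrix_correlation(m, doubled, "spearman"), 1)
  # dense independent matrices, so near-zero correlation is structural
  a <- mk_random_matrix(n_bins = 60, seed = 21, density = 0.95)
  b <- mk_random_matrix(n_bins = 60, seed = 22, density = 0.95)
  expect_gt(nrow(merge(a$entries, b$entries, by = c("bin1", "bin2"))), 100)
  expect_lt(abs(matrix_correlation(a, b)), 0.15)
})
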
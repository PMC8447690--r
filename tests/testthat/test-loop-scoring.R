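test_that("promoter and distal windows follow the strand and clip at bounds", {
  g <- mk_genes(c(100000, 100000, 2000), strand = c("+", "-", "+"))
  pw <- promoter_window(g)
  expect_equal(pw$start, c(96000, 99001, 0))
  expect_equal(pw$end, c(101000, 104001, 3000))

  gp <- mk_genes(500000, strand = "+")
  dw <- distal_windows(gp)
  up <- dw[dw$side == "upstream", ]; dn <- dw[dw$side == "downstream", ]
  expect_equal(c(up$start, up$end), c(400000, 490000))
  expect_equal(c(dn$start, dn$end), c(510000, 600000))

  gm <- mk_genes(500000, strand = "-")
  dwm <- distal_windows(gm)
  upm <- dwm[dwm$side == "upstream", ]
  expect_equal(c(upm$start, upm$end), c(510001, 600001))

  # clipping: upstream window of a gene near the chromosome start
  gc <- mk_genes(50000, strand = "+")
  dwc <- distal_windows(gc)
  upc <- dwc[dwc$side == "upstream", ]
  expect_equal(c(upc$start, upc$end), c(0, 40000))
})

test_that("anchor role assignment demotes distal roles under a promoter", {
  # g1 at 100 kb, g2 at 190 kb: the distal window of g1 contains the
  # promoter of g2
  g <- mk_genes(c(100000, 190000), strand = "+")
  r1 <- assign_anchor("chr1", 96500, 97500, g)
  expect_equal(r1$gene_id, "g001")
  expect_equal(r1$role, "promoter")

  r2 <- assign_anchor("chr1", 186500, 187500, g)  # promoter(g2) & distal(g1)
  expect_equal(r2$gene_id, "g002")
  expect_equal(r2$role, "promoter")

  # between the genes, distal of both, no promoter: both roles kept
  r3 <- assign_anchor("chr1", 140000, 141000, g)
  expect_setequal(r3$gene_id, c("g001", "g002"))
  expect_true(all(r3$role == "distal"))
})

test_that("P1D1 loops require promoter and distal of the same gene; VPPM is exact", {
  g <- mk_genes(c(100000, 600000), strand = "+")
  sif_good <- mk_sif("chr1", 97000, 98000, 150000, 152000,
                     valid_pairs = 100)
  tab <- call_p1d1_loops(sif_good, g, total_valid_pairs = 5e7)
  expect_equal(nrow(tab$loops), 1L)
  expect_equal(tab$loops$vppm, 2.0)
  expect_equal(tab$loops$gene_id, "g001")

  # promoter of g1 with distal of g2: no loop
  sif_cross <- mk_sif("chr1", 97000, 98000, 530000, 532000)
  expect_equal(nrow(call_p1d1_loops(sif_cross, g, 5e7)$loops), 0L)

  expect_error(call_p1d1_loops(sif_good, g, total_valid_pairs = 0),
               "total_valid_pairs")

  # a loop containing the whole library scores exactly 1e6
  whole <- mk_sif("chr1", 97000, 98000, 150000, 152000, valid_pairs = 5e7)
  expect_equal(call_p1d1_loops(whole, g, 5e7)$loops$vppm, 1e6)
})

test_that("loop calling matches the exhaustive all-pairs oracle", {
  for (seed in 1:30) {
    sc <- mk_loop_scenario(seed)
    tab <- call_p1d1_loops(sc$sifs, sc$genes, total_valid_pairs = 1e6)
    expect_identical(canonical_loops(tab),
                     oracle_p1d1(sc$sifs, sc$genes, 1e6),
                     label = sprintf("seed %d", seed))
  }
  # one larger planted scenario
  sc <- mk_loop_scenario(999, n_genes = 200, n_sifs = 500, span = 2e7)
  tab <- call_p1d1_loops(sc$sifs, sc$genes, total_valid_pairs = 1e6)
  expect_identical(canonical_loops(tab), oracle_p1d1(sc$sifs, sc$genes, 1e6))
})

test_that("strand reflection leaves the loop set invariant", {
  sc <- mk_loop_scenario(7)
  span <- 5e6
  refl <- function(x) span - x
  genes_r <- sc$genes
  genes_r$tss <- refl(sc$genes$tss) - 1
  genes_r$strand <- ifelse(sc$genes$strand == "+", "-", "+")
  sifs_r <- sc$sifs
  sifs_r$start1 <- refl(sc$sifs$end2); sifs_r$end1 <- refl(sc$sifs$start2)
  sifs_r$start2 <- refl(sc$sifs$end1); sifs_r$end2 <- refl(sc$sifs$start1)
  fwd <- call_p1d1_loops(sc$sifs, sc$genes, 1e6)
  rev <- call_p1d1_loops(sifs_r, gene_table(genes_r), 1e6)
  key <- function(t) sort(sprintf("%s|%d", t$loops$gene_id, t$loops$sif))
  expect_identical(key(fwd), key(rev))
})

test_that("gene-level VPPM sums match independent recomputation", {
  for (seed in c(2, 12, 22)) {
    sc <- mk_loop_scenario(seed, n_genes = 60, n_sifs = 200)
    tab <- call_p1d1_loops(sc$sifs, sc$genes, total_valid_pairs = 2e6)
    gv <- gene_vppm_table(tab)
    by_hand <- tapply(tab$loops$vppm, tab$loops$gene_id, sum)
    expect_equal(gv$vppm, as.numeric(by_hand[gv$gene_id]))
    expect_true(all(gv$vppm >= 0 & gv$vppm <= 1e6))
  }
})

test_that("SIF tables validate, filter inclusively and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sifs.tsv")
  writeLines(c("chr1\t100\t200\tchr1\t5000\t6000\t12\t0.05",
               "chr1\t100\t200\tchr2\t5000\t6000\t9\t0.01"), f)
  expect_warning(s <- read_sifs(f), "inter-chromosomal")
  expect_equal(nrow(s), 1L)

  writeLines("chr1\t100\t200\tchr1\t5000\t6000\t12\t1.5", f)
  expect_error(read_sifs(f), "fdr")
  writeLines("chr1\t100\t200\tchr1\t5000\t6000\t-3\t0.5", f)
  expect_error(read_sifs(f), "valid_pairs")

  sifs <- mk_sif("chr1", c(0, 0, 0), c(100, 100, 100),
                 c(1000, 1000, 1000), c(2000, 2000, 2000),
                 valid_pairs = 5, fdr = c(0.05, 0.10, 0.2))
  kept <- filter_sifs(sifs)
  expect_equal(kept$fdr, c(0.05, 0.10))  # 0.1 itself is kept

  set.seed(31)
  n <- 100
  s1 <- sort(round(runif(n, 0, 1e6)))
  rt <- mk_sif("chr1", s1, s1 + 500, s1 + 2000, s1 + 3000,
               valid_pairs = sample.int(100, n, TRUE),
               fdr = round(runif(n), 6))
  write_sifs(rt, f)
  back <- read_sifs(f)
  expect_equal(back, rt)
})
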
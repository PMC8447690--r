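test_that("degenerate and single-signal inputs behave as defined", {
  v <- setNames(rep(5, 10), sprintf("g%02d", 1:10))
  a <- mk_vppm_table(v, "a"); b <- mk_vppm_table(v, "b")
  expect_error(strengthened_looping_genes(a, b), "identical")

  v2 <- v; v2["g03"] <- 9
  res <- strengthened_looping_genes(a, mk_vppm_table(v2, "b"))
  expect_equal(res$slg_b, "g03")
  expect_length(res$slg_a, 0L)
})

test_that("planted strong genes are the SLGs; the noise side stays clean", {
  set.seed(10)
  n <- 1000
  diffs <- rnorm(n, 0, 0.1)
  planted <- sample(n, 50)
  diffs[planted] <- 5
  ids <- sprintf("g%04d", seq_len(n))
  a <- mk_vppm_table(setNames(rep(10, n), ids), "a")
  b <- mk_vppm_table(setNames(10 + diffs, ids), "b")
  res <- strengthened_looping_genes(a, b)
  expect_true(all(ids[planted] %in% res$slg_b))
  expect_false(any(ids[planted] %in% res$slg_a))
  # no noise gene reaches the cutoff next to a 50-sigma planted effect
  expect_setequal(res$slg_b, ids[planted])
})

test_that("raising a gene's VPPM never expels it from the strengthened set", {
  for (seed in 1:50) {
    set.seed(seed)
    ids <- sprintf("g%02d", 1:20)
    va <- setNames(runif(20, 0, 10), ids)
    vb <- setNames(runif(20, 0, 10), ids)
    res <- strengthened_looping_genes(mk_vppm_table(va, "a"),
                                      mk_vppm_table(vb, "b"))
    if (!length(res$slg_b)) next
    g <- res$slg_b[1]
    vb2 <- vb
    vb2[g] <- vb2[g] + runif(1, 0.1, 20)
    res2 <- strengthened_looping_genes(mk_vppm_table(va, "a"),
                                       mk_vppm_table(vb2, "b"))
    expect_true(g %in% res2$slg_b, label = sprintf("seed %d", seed))
  }
})

test_that("swapping the conditions swaps the SLG sets exactly", {
  for (seed in c(4, 14, 24)) {
    set.seed(seed)
    ids <- sprintf("g%03d", 1:100)
    a <- mk_vppm_table(setNames(rexp(100, 0.2), ids), "a")
    b <- mk_vppm_table(setNames(rexp(100, 0.2), ids), "b")
    fwd <- strengthened_looping_genes(a, b)
    rev <- strengthened_looping_genes(b, a)
    expect_identical(fwd$slg_b, rev$slg_a)
    expect_identical(fwd$slg_a, rev$slg_b)
    expect_length(intersect(fwd$slg_a, fwd$slg_b), 0L)
    expect_true(all(fwd$table$score >= 0 & fwd$table$score <= 1,
                    na.rm = TRUE))
  }
})

test_that("absent genes count as zero VPPM and both policies agree on signal", {
  a <- mk_vppm_table(c(g1 = 4, g2 = 1, g3 = 2), "a")
  b <- mk_vppm_table(c(g2 = 1, g3 = 12, g4 = 3), "b")
  res <- strengthened_looping_genes(a, b)
  expect_equal(res$table$gene_id, c("g1", "g2", "g3", "g4"))
  expect_equal(res$table$diff, c(-4, 0, 10, 3))
  res2 <- strengthened_looping_genes(a, b, policy = "per_sign_z_minmax")
  expect_identical(res$slg_b, res2$slg_b)
  expect_true("g3" %in% res$slg_b)
})

test_that("loop partitioning splits common from condition-unique loops", {
  sc <- mk_loop_scenario(55, n_genes = 30, n_sifs = 100)
  tab <- call_p1d1_loops(sc$sifs, sc$genes, 1e6, sample_id = "a")
  # identical tables -> all loops common
  part <- partition_loops(tab, tab)
  expect_equal(nrow(part$unique_a), 0L)
  expect_equal(nrow(part$unique_b), 0L)
  expect_equal(nrow(part$common), nrow(tab$loops))
  expect_equal(part$common$vppm_a, part$common$vppm_b)

  # disjoint gene sets -> nothing common
  tab2 <- tab
  tab2$loops$gene_id <- paste0("x_", tab2$loops$gene_id)
  part2 <- partition_loops(tab, tab2)
  expect_equal(nrow(part2$common), 0L)
  expect_equal(nrow(part2$unique_a), nrow(tab$loops))
  expect_equal(nrow(part2$unique_b), nrow(tab$loops))
})

test_that("planted unique fractions surface in the partition sizes", {
  # one loop per gene so condition-unique loops can never cross-match
  spec <- scenario_spec(seed = 77, n_genes = 60, frac_unique_a = 0.3,
                        frac_unique_b = 0.2, frac_strengthened = 0,
                        loops_per_gene_rate = 0, n_decoys = 0)
  genome <- simulate_genome(spec)
  sim <- simulate_sif_tables(genome$genes, spec)
  la <- call_p1d1_loops(sim$sif_a, genome$genes, 2e6, sample_id = "a")
  lb <- call_p1d1_loops(sim$sif_b, genome$genes, 2e6, sample_id = "b")
  part <- partition_loops(la, lb)
  truth <- sim$truth$loops
  expect_equal(nrow(part$common), sum(truth$cond == "common"))
  expect_equal(nrow(part$unique_a), sum(truth$cond == "a_only"))
  expect_equal(nrow(part$unique_b), sum(truth$cond == "b_only"))
})

test_that("strength distributions separate shifted groups by rank-sum", {
  sc <- mk_loop_scenario(66, n_genes = 50, n_sifs = 150)
  # overlapping SIF subsets: shared rows are identical in both samples
  tab_a <- call_p1d1_loops(sc$sifs[1:120, ], sc$genes, 1e6, sample_id = "a")
  tab_b <- call_p1d1_loops(sc$sifs[31:150, ], sc$genes, 1e6, sample_id = "b")
  part <- partition_loops(tab_a, tab_b)
  # identical common groups: rank-sum p-value ~ 1
  sd <- strength_distributions(part, tab_a, tab_b)
  expect_gt(sd$p_values["common_a", "common_b"], 0.5)

  # a +10 VPPM shift at n = 200 per group is overwhelmingly significant
  set.seed(1)
  x <- runif(200, 0, 5)
  p <- stats::wilcox.test(x, x + 10, exact = FALSE)$p.value
  expect_lt(p, 1e-6)

  # an empty class is an error
  empty_part <- list(unique_a = tab_a$loops[0, ], common = part$common,
                     unique_b = part$unique_b)
  expect_error(strength_distributions(empty_part, tab_a, tab_b),
               "empty loop class")
})
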
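test_that("gene placement respects bounds, spacing and determinism", {
  spec <- scenario_spec(seed = 9, n_genes = 20, chrom_length = 1e7)
  g1 <- simulate_genome(spec)
  expect_equal(nrow(g1$genes), 20L)
  expect_true(all(g1$genes$tss >= 0 & g1$genes$tss < 1e7))
  expect_true(all(diff(g1$genes$tss) >= 250000))
  g2 <- simulate_genome(spec)
  expect_identical(g1$genes, g2$genes)

  too_many <- scenario_spec(seed = 1, n_genes = 200, chrom_length = 1e7)
  expect_error(simulate_genome(too_many), "cannot place")
})

test_that("planted domain changes are unambiguous and fully recoverable", {
  # empty plan: the two conditions are identical
  same <- simulate_domain_pair(scenario_spec(seed = 3, change_plan = c(no_change = 4)))
  expect_equal(same$a$calls, same$b$calls)

  # split plan: each planted A TAD is covered by >= 2 B TADs
  sp <- simulate_domain_pair(scenario_spec(seed = 3, change_plan = c(split = 3)))
  expect_equal(nrow(sp$truth), 3L)
  a_tads <- sp$a$calls[sp$a$calls$state == "tad", ]
  b_tads <- sp$b$calls[sp$b$calls$state == "tad", ]
  expect_equal(nrow(a_tads), 3L)
  expect_equal(nrow(b_tads), 6L)

  # closed loop: the classifier recovers the planted multiset exactly
  plan <- c(no_change = 2, conserve_expand = 2, conserve_shrink = 2,
            shift = 2, split = 2, fuse = 2, neo = 2, del = 2)
  pair <- simulate_domain_pair(scenario_spec(seed = 13, chrom_length = 4e7,
                                             change_plan = plan))
  got <- summarize_changes(classify_changes(pair$a, pair$b))$counts
  expect_equal(got[names(plan)], plan[names(plan)],
               ignore_attr = TRUE)
  expect_equal(sort(table(pair$truth$type)), sort(plan), ignore_attr = TRUE)

  # an over-full plan fails loudly
  expect_error(simulate_domain_pair(scenario_spec(
    seed = 1, chrom_length = 5e6, n_genes = 5,
    change_plan = c(split = 10))), "does not fit")
})

test_that("contact matrices show the planted decay, enrichment and depth", {
  spec <- scenario_spec(seed = 21)
  genome <- simulate_genome(spec)
  domains <- simulate_domain_pair(spec, genome$layout)$a

  # beta = 1: within/between means agree at matched distances
  flat <- scenario_spec(seed = 21, tad_enrichment = 1)
  m1 <- simulate_contact_matrix(genome$layout, domains, flat)
  r1 <- within_between_ratio(m1, domains, max_d_bins = 10)
  expect_gt(r1, 0.9); expect_lt(r1, 1.1)

  # beta = 3: ratio near 3
  m3 <- simulate_contact_matrix(genome$layout, domains, spec)
  r3 <- within_between_ratio(m3, domains, max_d_bins = 10)
  expect_gt(r3, 2.5); expect_lt(r3, 3.5)

  # doubling depth doubles the realized total within 4 sigma
  deep <- scenario_spec(seed = 21, depth = 4e6)
  md <- simulate_contact_matrix(genome$layout, domains, deep, seed = 101)
  expect_lt(abs(md$total_valid_pairs - 2 * spec$depth), 4 * sqrt(4e6))

  # determinism given the seed
  again <- simulate_contact_matrix(genome$layout, domains, spec)
  expect_identical(again$entries, m3$entries)
})

test_that("planted SIFs become loops and decoys never do", {
  spec <- scenario_spec(seed = 31, n_decoys = 0)
  genome <- simulate_genome(spec)
  sim <- simulate_sif_tables(genome$genes, spec)
  tab <- call_p1d1_loops(sim$sif_a, genome$genes, spec$depth)
  expect_equal(nrow(tab$loops), sim$truth$n_planted_a)

  spec_d <- scenario_spec(seed = 31, n_decoys = 30)
  sim_d <- simulate_sif_tables(genome$genes, spec_d)
  n_planted <- sim_d$truth$n_planted_a
  decoys_only <- sim_d$sif_a[-seq_len(n_planted), , drop = FALSE]
  expect_gt(nrow(decoys_only), 0L)
  expect_equal(nrow(call_p1d1_loops(decoys_only, genome$genes,
                                    spec$depth)$loops), 0L)
})

test_that("planted DE genes are exactly what the filter recovers", {
  spec <- scenario_spec(seed = 41)
  genome <- simulate_genome(spec)
  none <- simulate_deg_table(genome$genes, scenario_spec(seed = 41,
                                                         frac_de = 0))
  expect_length(filter_degs(rename_deg(none$table)), 0L)
  all_de <- simulate_deg_table(genome$genes, scenario_spec(seed = 41,
                                                           frac_de = 1))
  expect_setequal(filter_degs(rename_deg(all_de$table)),
                  genome$genes$gene_id)
  mixed <- simulate_deg_table(genome$genes, spec)
  expect_setequal(filter_degs(rename_deg(mixed$table)), mixed$truth)
})

test_that("an emitted scenario is byte-identical across runs and parses back", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- scenario_spec(seed = 51, n_genes = 20)
  s1 <- simulate_scenario(spec, d1)
  s2 <- simulate_scenario(spec, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # truth consistency: emitted files parse back to the planted objects
  genes <- read_genes_bed(s1$paths$genes)
  expect_equal(genes$tss, s1$genes$tss)
  expect_equal(genes$strand, s1$genes$strand)
  doms <- read_topdom(s1$paths$domains_a)
  expect_equal(doms$calls, s1$domains$a$calls)
  sifs <- read_sifs(s1$paths$sifs_a)
  expect_equal(nrow(sifs), nrow(s1$sifs$sif_a))
  mat <- read_hicpro_matrix(paste0(s1$paths$matrix_a, "_abs.bed"),
                            paste0(s1$paths$matrix_a, ".matrix"),
                            paste0(s1$paths$matrix_a, "_stats.txt"))
  expect_equal(mat$entries, s1$matrices$a$entries)
  expect_equal(mat$total_valid_pairs, s1$matrices$a$total_valid_pairs)
})

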
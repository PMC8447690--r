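test_that("overlap graph connects TADs as expected", {
  a <- mk_domains(data.frame(chrom = "chr1", start = c(0, 2e6),
                             end = c(1e6, 3e6)))
  b_disjoint <- mk_domains(data.frame(chrom = "chr1", start = 4e6, end = 5e6))
  g <- build_overlap_graph(a, b_disjoint)
  expect_length(g$components, 0L)
  expect_equal(nrow(g$unmatched_a), 2L)
  expect_equal(nrow(g$unmatched_b), 1L)

  g2 <- build_overlap_graph(a, a)
  expect_length(g2$components, 2L)
  expect_true(all(vapply(g2$components,
                         function(cp) nrow(cp$a) == 1 && nrow(cp$b) == 1,
                         TRUE)))

  b_split <- mk_domains(data.frame(chrom = "chr1", start = c(0, 5e5),
                                   end = c(5e5, 1e6)))
  g3 <- build_overlap_graph(mk_domains(data.frame(chrom = "chr1", start = 0,
                                                  end = 1e6)), b_split)
  expect_length(g3$components, 1L)
  expect_equal(nrow(g3$components[[1]]$a), 1L)
  expect_equal(nrow(g3$components[[1]]$b), 2L)
})

test_that("definitional change types come out of single-event inputs", {
  tad <- function(s, e) mk_domains(data.frame(chrom = "chr1", start = s,
                                              end = e))
  types <- function(ch) ch$events$type

  # identity -> all no_change
  a <- mk_domains(data.frame(chrom = "chr1", start = c(0, 2e6, 5e6),
                             end = c(1e6, 3e6, 6e6)))
  expect_true(all(types(classify_changes(a, a)) == "no_change"))

  # TAD -> gap is del; gap -> TAD is neo
  gap_only <- domain_call_set(data.frame(chrom = "chr1", start = 0,
                                         end = 2e7, state = "gap"))
  expect_equal(types(classify_changes(tad(1e6, 2e6), gap_only)), "del")
  expect_equal(types(classify_changes(gap_only, tad(2e6, 2.4e6))), "neo")

  # growth within 300 kb is conserve_expand with the right delta
  ch <- classify_changes(tad(0, 1e6), tad(0, 1.2e6))
  expect_equal(ch$events$type, "conserve_expand")
  expect_equal(ch$events$length_delta, 2e5)

  # displacement beyond 300 kb is a shift
  expect_equal(types(classify_changes(tad(0, 1.2e6), tad(4e5, 1.6e6))),
               "shift")

  # one-to-many and many-to-one
  expect_equal(types(classify_changes(tad(0, 1.6e6),
                                      tad(c(0, 8e5), c(7.6e5, 1.6e6)))),
               "split")
  expect_equal(types(classify_changes(tad(c(0, 8e5), c(7.6e5, 1.6e6)),
                                      tad(0, 1.6e6))),
               "fuse")
})

test_that("classification agrees with the brute-force oracle on random sets", {
  for (seed in 1:60) {
    a <- mk_domains(mk_random_tads(seed * 2 + 1))
    b <- mk_domains(mk_random_tads(seed * 2 + 2))
    ch <- classify_changes(a, b)
    expect_identical(canonical_events(ch), oracle_classify(a, b),
                     label = sprintf("seed %d", seed))
    # partition property: every TAD in exactly one event
    expect_equal(sum(ch$events$n_a),
                 sum(a$calls$state == "tad"))
    expect_equal(sum(ch$events$n_b),
                 sum(b$calls$state == "tad"))
  }
})

test_that("swapping conditions mirrors the event types on planted scenarios", {
  mirror <- c(no_change = "no_change", conserve_expand = "conserve_shrink",
              conserve_shrink = "conserve_expand", shift = "shift",
              split = "fuse", fuse = "split", neo = "del", del = "neo")
  for (seed in c(3, 17, 29)) {
    pair <- simulate_domain_pair(scenario_spec(seed = seed))
    fwd <- summarize_changes(classify_changes(pair$a, pair$b))$counts
    rev <- summarize_changes(classify_changes(pair$b, pair$a))$counts
    expect_equal(unname(rev[mirror[names(fwd)]]), unname(fwd))
  }
})

test_that("change summaries count, normalize and split RC/DC correctly", {
  a <- mk_domains(mk_random_tads(101))
  b <- mk_domains(mk_random_tads(102))
  sm <- summarize_changes(classify_changes(a, b))
  expect_equal(sum(sm$fractions), 1, tolerance = 1e-9)
  expect_equal(sm$rc_fraction + sm$dc_fraction, 1, tolerance = 1e-9)
  expect_equal(sum(sm$counts), sm$n_events)

  ten <- mk_domains(data.frame(chrom = "chr1",
                               start = seq(0, 9) * 2e6,
                               end = seq(0, 9) * 2e6 + 1e6))
  expect_equal(summarize_changes(classify_changes(ten, ten))$rc_fraction, 1)

  # one event of each type -> uniform fractions, RC = 3/8
  pair <- simulate_domain_pair(scenario_spec(seed = 8))
  sm8 <- summarize_changes(classify_changes(pair$a, pair$b))
  expect_equal(unname(sm8$fractions), rep(0.125, 8))
  expect_equal(sm8$rc_fraction, 0.375)
})
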
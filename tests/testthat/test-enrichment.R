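series3 <- function(c0, c1, c2) {
  round_series(list(make_table(c0, "pan0"), make_table(c1, "pan1"),
                    make_table(c2, "pan2")))
}

test_that("fold enrichment follows the pseudo-count ratio formula", {
  # equal totals of 1000 reads so CPM is proportional to counts
  s <- series3(c(A = 100L, Z = 900L), c(A = 100L, Z = 900L),
               c(A = 400L, Z = 600L))
  expect_equal(unname(fold_enrichment(s, "A", "pan0", "pan2",
                                      pseudo_cpm = 0)), 4)
  expect_equal(unname(fold_enrichment(s, "A", "pan0", "pan1",
                                      pseudo_cpm = 0)), 1)
  # absent from the source round: infinite at pseudo 0, finite otherwise
  s2 <- series3(c(Z = 1000L), c(Z = 1000L), c(B = 50L, Z = 950L))
  expect_equal(unname(fold_enrichment(s2, "B", "pan0", "pan2",
                                      pseudo_cpm = 0)), Inf)
  expect_true(is.finite(fold_enrichment(s2, "B", "pan0", "pan2")))
  # the printed arithmetic: cpm 0 -> 50 with pseudo 1 gives 51
  s3 <- series3(c(Z = 1e6), c(Z = 1e6), c(B = 50L, Z = 999950L))
  expect_equal(unname(fold_enrichment(s3, "B", "pan0", "pan2",
                                      pseudo_cpm = 1)), 51)
  expect_error(fold_enrichment(s, "A", "pan0", "nope"), "unknown round")
  expect_error(fold_enrichment(s, "A", "pan0", "pan2", pseudo_cpm = -1),
               ">= 0")
})

test_that("fold enrichment with a pseudo count is finite and monotone", {
  s <- series3(c(A = 10L, Z = 990L), c(A = 10L, Z = 990L),
               c(A = 5L, B = 20L, C = 100L, Z = 875L))
  f <- fold_enrichment(s, c("A", "B", "C"), "pan1", "pan2")
  expect_true(all(is.finite(f)))
  # cpm_to increases A -> B -> C while cpm_from is fixed
  expect_true(f[["A"]] < f[["B"]] && f[["B"]] < f[["C"]])
})

test_that("enriched classification applies the copy-number and abundance rules", {
  # equal totals (1000) in all rounds; final raw counts are decisive
  s <- series3(c(B = 100L, Z = 900L),   # A and C absent from pan0
               c(A = 4L, B = 50L, Z = 946L),
               c(A = 12L, B = 40L, C = 9L, Z = 939L))
  enr <- classify_enriched(s)
  expect_true("A" %in% enr)     # rising, count 12 >= 10
  expect_false("B" %in% enr)    # falling abundance
  expect_false("C" %in% enr)    # count 9 < 10
  expect_false("Z" %in% enr)

  # invariant under uniform scaling of sequencing depth (the CPM
  # comparisons are depth-free; counts stay above the copy floor)
  s1b <- series3(c(B = 100L, Z = 900L), c(A = 12L, B = 50L, Z = 938L),
                 c(A = 30L, B = 40L, Z = 930L))
  scb <- series3(c(B = 300L, Z = 2700L), c(A = 36L, B = 150L, Z = 2814L),
                 c(A = 90L, B = 120L, Z = 2790L))
  expect_equal(classify_enriched(scb), classify_enriched(s1b))
  expect_equal(classify_enriched(s1b), "A")

  expect_error(
    classify_enriched(round_series(list(make_table(c(A = 1L), "x"),
                                        make_table(c(A = 1L), "y")))),
    "predecessors")
})

test_that("abundance ranking is dense-free with lexicographic tie-break", {
  r <- rank_by_abundance(make_table(c(A = 10L, B = 5L, C = 1L), "p"))
  expect_equal(r, c(A = 1L, B = 2L, C = 3L))
  r2 <- rank_by_abundance(make_table(c(B = 5L, A = 5L), "p"))
  expect_equal(r2[order(names(r2))], c(A = 1L, B = 2L))
  expect_equal(unname(rank_by_abundance(make_table(c(Q = 3L), "p"))), 1L)
  expect_error(rank_by_abundance(count_peptides(character(), "p")), "empty")
})

test_that("the adjusted inverse enrichment score is the stated arithmetic", {
  expect_equal(adjusted_inverse_enrichment(1, 10000, 50), 2.5)
  expect_equal(adjusted_inverse_enrichment(7, 0, 0), 7.0)
  expect_equal(adjusted_inverse_enrichment(3, 100, 10), 3.11)
  expect_error(adjusted_inverse_enrichment(0, 1, 1), "rank2")
  expect_error(adjusted_inverse_enrichment(1, Inf, 1), "finite")
})

test_that("overall ranking orders scores ascending with documented tie-breaks", {
  rec <- data.frame(peptide = c("A", "B", "C"),
                    rank2 = c(1L, 2L, 3L),
                    enr_i_adj = c(2.5, 7.0, 3.11))
  out <- rank_overall(rec)
  expect_equal(out$peptide, c("A", "C", "B"))
  expect_equal(out$overall_rank, 1:3)

  tied <- data.frame(peptide = c("B", "A"), rank2 = c(2L, 5L),
                     enr_i_adj = c(1, 1))
  expect_equal(rank_overall(tied)$peptide, c("B", "A"))  # by rank2

  set.seed(2)
  n <- 50L
  rnd <- data.frame(peptide = random_peptides(n), rank2 = sample(n),
                    enr_i_adj = runif(n))
  expect_setequal(rank_overall(rnd)$overall_rank, seq_len(n))
  expect_error(rank_overall(data.frame(peptide = "A", rank2 = 1L,
                                       enr_i_adj = NaN)), "finite")
})

test_that("with zero weights the overall rank reduces to final-round rank", {
  d <- test_design()
  cfg <- sim_config(n_unique_members = 400L, reads_per_round = 4000L,
                    bottleneck_size = 10000L, seed = 31L)
  sim <- simulate_biopanning(cfg, d)
  tabs <- lapply(sim$labels, function(l)
    count_peptides(sim$truth[[l]]$peptide, l))
  et <- enrichment_table(round_series(tabs), w02 = 0, w12 = 0)
  expect_equal(et$overall_rank, et$rank2)
})

test_that("a neutral spike-in depletes in expectation under selection", {
  d <- test_design()
  deltas <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_unique_members = 50L, spike_fraction = 0.08,
                      reads_per_round = 2000L, bottleneck_size = 5000L,
                      n_hits = 10L, hit_weight = 4, seed = 100L + seed)
    sim <- simulate_biopanning(cfg, d)
    t0 <- count_peptides(sim$truth$pan0$peptide, "pan0")
    t2 <- count_peptides(sim$truth$pan2$peptide, "pan2")
    unname(cpm(t2, "CAAAAA") - cpm(t0, "CAAAAA"))
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("the enrichment table is complete, consistent and serializable", {
  s <- series3(c(A = 50L, B = 100L, Z = 850L),
               c(A = 100L, B = 100L, Z = 800L),
               c(A = 300L, B = 50L, Z = 650L))
  et <- enrichment_table(s)
  expect_setequal(et$peptide, c("A", "B", "Z"))
  expect_setequal(et$overall_rank, 1:3)
  expect_true(all(c("cpm_pan0", "cpm_pan1", "cpm_pan2", "fold_01",
                    "fold_12", "fold_02", "rank2", "enr_i_adj",
                    "enriched") %in% names(et)))
  expect_equal(et$enriched, et$peptide %in% classify_enriched(s))
  # inverse interpretation flips the enrichment terms
  et_inv <- enrichment_table(s, enr_interpretation = "inverse_fold")
  a <- which(et$peptide == "A"); ai <- which(et_inv$peptide == "A")
  expect_equal(et_inv$enr02[ai], 1 / et$enr02[a])
  path <- tempfile(fileext = ".tsv")
  write_enrichment_tsv(et, path)
  back <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  expect_equal(back$peptide, et$peptide)
  expect_equal(back$enr_i_adj, et$enr_i_adj, tolerance = 1e-9)
  unlink(path)
})
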
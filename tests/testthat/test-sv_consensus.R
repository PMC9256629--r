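# Multi-caller SV consensus: merging, support rules, multi-range
# consistency, cross-pedigree filter and end-to-end recovery.

sv_row <- function(start, end, caller, svtype = "DEL", fam = "F1",
                   chrom = "chr1", plus = 5L, minus = 5L) {
  tibble::tibble(family_id = fam, chrom = chrom, start = start, end = end,
                 svtype = svtype, length = end - start, caller = caller,
                 plus_reads = plus, minus_reads = minus)
}

test_that("merge_at_range joins calls within d and separates beyond", {
  pair <- dplyr::bind_rows(sv_row(1000, 2000, "delly"),
                           sv_row(1010, 1990, "lumpy"))
  m50 <- merge_at_range(pair, 50)
  expect_equal(nrow(m50), 1)
  expect_equal(m50$support, 2L)
  expect_equal(m50$start, 1005L)  # per-coordinate median
  expect_equal(m50$end, 1995L)
  m5 <- merge_at_range(pair, 5)
  expect_equal(nrow(m5), 2)
  # different types never merge
  mixed <- dplyr::bind_rows(sv_row(1000, 2000, "delly"),
                            sv_row(1000, 2000, "lumpy", svtype = "DUP"))
  expect_equal(nrow(merge_at_range(mixed, 50)), 2)
})

test_that("support counts distinct callers, not calls", {
  dup_calls <- dplyr::bind_rows(sv_row(1000, 2000, "delly"),
                                sv_row(1001, 2001, "delly"),
                                sv_row(1002, 2002, "lumpy"))
  m <- merge_at_range(dup_calls, 50)
  expect_equal(nrow(m), 1)
  expect_equal(m$support, 2L)
  expect_equal(m$n_calls, 3L)
})

test_that("merging matches the transitive-closure oracle and ignores input order", {
  for (seed in 1:5) {
    calls <- random_sv_calls(40, seed = seed)
    for (d in c(10, 250, 1000)) {
      got <- merge_at_range(calls, d)
      comp <- oracle_merge_components(calls, d)
      expect_equal(nrow(got), length(unique(comp)))
      perm <- calls[withr::with_seed(seed + 100, sample.int(nrow(calls))), ]
      expect_equal(merge_at_range(perm, d), got)
    }
  }
})

test_that("clusters at a smaller distance refine clusters at a larger one", {
  calls <- random_sv_calls(60, seed = 7)
  c10 <- oracle_merge_components(calls, 10)
  c500 <- oracle_merge_components(calls, 500)
  # every d=10 cluster sits inside a single d=500 cluster
  expect_true(all(tapply(c500, c10, function(x) length(unique(x))) == 1))
  expect_gte(nrow(merge_at_range(calls, 10)), nrow(merge_at_range(calls, 500)))
})

test_that("support filter applies the size-dependent caller rules", {
  mk <- function(svtype, length, support, plus = 5L, minus = 5L) {
    tibble::tibble(family_id = "F1", chrom = "chr1", svtype = svtype,
                   start = 1000L, end = 1000L + length, length = length,
                   support = support, callers = list(letters[seq_len(support)]),
                   plus_reads = plus, minus_reads = minus, n_calls = support)
  }
  expect_true(support_filter(mk("DEL", 250, 4))$retained)
  expect_false(support_filter(mk("DEL", 500, 4))$retained)
  expect_true(support_filter(mk("DEL", 500, 6))$retained)
  expect_true(support_filter(mk("DUP", 1200, 4))$retained)
  expect_false(support_filter(mk("DUP", 2000, 4))$retained)
  expect_true(support_filter(mk("DUP", 2000, 5))$retained)
  # both strands required
  expect_false(support_filter(mk("DEL", 250, 6, minus = 0L))$retained)
  expect_equal(support_filter(mk("DEL", 250, 6, minus = 0L))$reason,
               "strand support")
  # strict mode: flat >= 5
  strict <- merge_config(strict_support = TRUE)
  expect_false(support_filter(mk("DEL", 250, 4), strict)$retained)
  expect_true(support_filter(mk("DEL", 2000, 5), strict)$retained)
  expect_error(support_filter(mk("BND", 250, 6)), "unknown svtype")
})

test_that("multi-range consistency keeps events seen at >= 2 ranges", {
  ev <- tibble::tibble(family_id = "F1", chrom = "chr1", svtype = "DEL",
                       start = 1000L, end = 1200L, length = 200L,
                       support = 6L, callers = list(letters[1:6]),
                       plus_reads = 5L, minus_reads = 5L, n_calls = 6L)
  per_range <- list(`150` = ev, `50` = ev, `10` = ev[0, ])
  kept <- multi_range_consistency(per_range, merge_config())
  expect_equal(nrow(kept), 1)
  expect_setequal(kept$ranges_detected[[1]], c(150, 50))
  only50 <- list(`150` = ev[0, ], `50` = ev, `10` = ev[0, ])
  expect_equal(nrow(multi_range_consistency(only50, merge_config())), 0)
  all7 <- setNames(rep(list(ev), 7),
                   as.character(c(1000, 500, 250, 150, 50, 25, 10)))
  kept7 <- multi_range_consistency(all7, merge_config())
  expect_equal(length(kept7$ranges_detected[[1]]), 7)
})

test_that("cross-pedigree filter discards recurrent events in all matching families", {
  mk <- function(fam, len) {
    tibble::tibble(family_id = fam, chrom = "chr1", svtype = "DEL",
                   start = 1000L, end = 1000L + len, length = len,
                   support = 6L, callers = list(letters[1:6]),
                   plus_reads = 5L, minus_reads = 5L, n_calls = 6L)
  }
  both <- dplyr::bind_rows(mk("F1", 100), mk("F2", 105))
  expect_equal(nrow(cross_pedigree_filter(both, merge_config())), 0)
  diff_len <- dplyr::bind_rows(mk("F1", 100), mk("F2", 150))
  expect_equal(nrow(cross_pedigree_filter(diff_len, merge_config())), 2)
  single <- mk("F1", 100)
  expect_equal(nrow(cross_pedigree_filter(single, merge_config())), 1)
})

test_that("full consensus recovers planted SVs through jitter and false positives", {
  cfg <- simulation_config(n_families_per_cohort = 2, dnm_rate_mean = 5,
                           inherited_variants_per_trio = 0, n_true_svs = 5,
                           sv_caller_sensitivity = 1,
                           breakpoint_jitter_sd = 20, fp_sv_rate = 5,
                           n_contigs = 3, contig_length = 400000, seed = 21)
  sim <- simulate_study(cfg)
  res <- run_sv_consensus(sim$bundle$sv_calls, sim$bundle$pedigree)
  truth <- sim$truth$svs
  expect_equal(nrow(res$consensus), nrow(truth))
  # each recovered event matches one planted event within the merge range
  for (i in seq_len(nrow(truth))) {
    hit <- res$consensus$family_id == truth$family_id[i] &
      res$consensus$chrom == truth$chrom[i] &
      res$consensus$svtype == truth$svtype[i] &
      abs(res$consensus$start - truth$start[i]) <= 50 &
      abs(res$consensus$end - truth$end[i]) <= 50
    expect_equal(sum(hit), 1)
  }
  expect_true(all(res$consensus$support >= 4))
  # strict mode output is contained in default-mode-or-size-rule-failures
  strict <- run_sv_consensus(sim$bundle$sv_calls, sim$bundle$pedigree,
                             merge_config(strict_support = TRUE))
  expect_true(all(
    paste(strict$consensus$family_id, strict$consensus$start) %in%
      paste(res$consensus$family_id, res$consensus$start) |
      strict$consensus$support >= 5))
})

test_that("an SV planted in two families is removed by the cross-pedigree rule", {
  cfg <- simulation_config(n_families_per_cohort = 1, dnm_rate_mean = 5,
                           inherited_variants_per_trio = 0, n_true_svs = 2,
                           sv_caller_sensitivity = 1, breakpoint_jitter_sd = 0,
                           fp_sv_rate = 0, contig_length = 300000, seed = 31)
  sim <- simulate_study(cfg)
  ped <- sim$bundle$pedigree  # FAM001 (control) and FAM002 (NTV)
  # plant the same two events in both families
  truth <- sim$truth$svs[sim$truth$svs$family_id == "FAM001", ]
  shared <- dplyr::mutate(truth, family_id = "FAM002")
  calls <- simulate_sv_callsets(dplyr::bind_rows(truth, shared), cfg, seed = 5)
  res <- run_sv_consensus(calls, ped)
  expect_equal(nrow(res$consensus), 0)
  # a private event alongside the shared ones survives
  private <- dplyr::mutate(truth[1, ], start = .data$start + 50000L,
                           end = .data$end + 50000L, family_id = "FAM001")
  calls2 <- simulate_sv_callsets(dplyr::bind_rows(truth, shared, private),
                                 cfg, seed = 5)
  res2 <- run_sv_consensus(calls2, ped)
  expect_equal(nrow(res2$consensus), 1)
  expect_equal(res2$consensus$family_id, "FAM001")
})
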
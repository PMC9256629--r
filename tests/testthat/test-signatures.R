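# Catalogue construction, NNLS fitting, per-mutation assignment,
# downscaling and the cohort signature comparison.

test_that("context classification enforces the pyrimidine-strand convention", {
  expect_equal(names(classify_context("ACA", "T")), "A[C>T]A")
  # purine-centred: AGA + T reverse-complements to TCT + A
  expect_equal(names(classify_context("AGA", "T")), "T[C>A]T")
  expect_error(classify_context("ACA", "C"), "alt base equals")
  expect_error(classify_context("ANA", "T"), "ACGT")
})

test_that("classification is invariant under reverse-complementing the input", {
  bases <- c("A", "C", "G", "T")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  combos <- withr::with_seed(5, {
    tibble::tibble(
      trip = replicate(200, paste(sample(bases, 3, replace = TRUE),
                                  collapse = ""))
    )
  })
  for (i in seq_len(nrow(combos))) {
    trip <- combos$trip[i]
    mid <- substr(trip, 2, 2)
    alt <- sample(setdiff(bases, mid), 1)
    a <- classify_context(trip, alt)
    b <- classify_context(rc(trip), chartr("ACGT", "TGCA", alt))
    expect_equal(unname(a), unname(b))
  }
})

test_that("catalogue counts SNVs by channel and skips contig edges", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AACAACAT"))
  dnms <- tibble::tibble(chrom = "chr1", pos = c(3L, 6L), ref = "C",
                         alt = "T", vclass = "SNV")
  cat96 <- build_catalogue(dnms, genome)
  expect_equal(sum(cat96$count), 2)
  expect_equal(cat96$count[cat96$channel == "A[C>T]A"], 2L)
  # indels are excluded, edges skipped with a message
  with_indel <- dplyr::bind_rows(
    dnms, tibble::tibble(chrom = "chr1", pos = 4L, ref = "AA", alt = "A",
                         vclass = "indel"))
  expect_equal(sum(build_catalogue(with_indel, genome)$count), 2)
  at_edge <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                            vclass = "SNV")
  expect_message(res <- build_catalogue(at_edge, genome), "contig edge")
  expect_equal(sum(res$count), 0)
})

test_that("generator channels agree with genome-context classification", {
  cfg <- simulation_config(n_families_per_cohort = 2, dnm_rate_mean = 50,
                           indel_fraction = 0, inherited_variants_per_trio = 0,
                           n_true_svs = 0, fp_sv_rate = 0,
                           contig_length = 100000, seed = 17)
  sim <- simulate_study(cfg)
  truth <- sim$truth$dnms
  cat96 <- build_catalogue(truth, sim$bundle$genome, owner = "truth")
  expect_equal(sum(cat96$count), nrow(truth))
  want <- table(factor(truth$channel, levels = sbs96_channels()))
  expect_equal(cat96$count, as.integer(want), ignore_attr = TRUE)
})

test_that("NNLS recovers exact cone members and mixtures", {
  M <- synthetic_signature_matrix(5, seed = 2)
  pure <- setNames(100 * M[, 3], rownames(M))
  fit <- fit_exposures(pure, M)
  expect_equal(fit$exposure, c(0, 0, 100, 0, 0), tolerance = 1e-8)
  mix <- setNames(60 * M[, 1] + 40 * M[, 2], rownames(M))
  fit2 <- fit_exposures(mix, M)
  expect_equal(fit2$exposure[1:2], c(60, 40), tolerance = 1e-6)
  expect_lt(glance(fit2)$residual, 1e-8)
  zero <- setNames(rep(0, 96), rownames(M))
  expect_warning(fit0 <- fit_exposures(zero, M), "zero catalogue")
  expect_true(all(fit0$exposure == 0))
})

test_that("fitted residual is locally optimal against random feasible points", {
  M <- synthetic_signature_matrix(5, seed = 4)
  counts <- withr::with_seed(9, {
    p <- as.numeric(M %*% c(0.5, 0.2, 0.1, 0.1, 0.1))
    setNames(as.numeric(rmultinom(1, 500, p)), rownames(M))
  })
  fit <- fit_exposures(counts, M)
  best <- sqrt(sum((M %*% fit$exposure - counts)^2))
  withr::with_seed(10, {
    for (i in 1:50) {
      e <- runif(5, 0, 200)
      expect_gte(sqrt(sum((M %*% e - counts)^2)), best - 1e-6)
    }
  })
})

test_that("mixture fractions are recovered within 0.05 MAE over 20 replicates", {
  M <- synthetic_signature_matrix(5, seed = 6)
  w_true <- c(0.6, 0.4, 0, 0, 0)
  errs <- vapply(1:20, function(rep) {
    counts <- withr::with_seed(100 + rep, {
      ch <- simulate_dnm_channels(2000, setNames(w_true, colnames(M)), M)
      setNames(as.integer(table(factor(ch, levels = sbs96_channels()))),
               sbs96_channels())
    })
    frac <- tidy(fit_exposures(counts, M))$fraction
    mean(abs(frac - w_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  # single replicate also lands within +-0.05 per component
  counts <- withr::with_seed(7, {
    ch <- simulate_dnm_channels(2000, setNames(w_true, colnames(M)), M)
    setNames(as.integer(table(factor(ch, levels = sbs96_channels()))),
             sbs96_channels())
  })
  frac <- tidy(fit_exposures(counts, M))$fraction
  expect_true(all(abs(frac - w_true) < 0.05))
})

test_that("assignment maximises exposure-weighted channel probability", {
  M <- synthetic_signature_matrix(3, seed = 8)
  dnms <- tibble::tibble(channel = sample(sbs96_channels(), 50, replace = TRUE))
  one_hot <- structure(tibble::tibble(signature = colnames(M),
                                      exposure = c(0, 10, 0)),
                       class = c("exposure_fit", "tbl_df", "tbl", "data.frame"))
  got <- assign_mutations(dnms, one_hot, M)
  expect_true(all(got$signature == colnames(M)[2]))
  # equal exposures: the channel probability decides
  eq <- structure(tibble::tibble(signature = colnames(M),
                                 exposure = c(5, 5, 5)),
                  class = c("exposure_fit", "tbl_df", "tbl", "data.frame"))
  got_eq <- assign_mutations(dnms, eq, M)
  k <- match(got_eq$channel, sbs96_channels())
  want <- colnames(M)[apply(M[k, ], 1, which.max)]
  expect_equal(got_eq$signature, want)
})

test_that("assignment equals exhaustive per-mutation score enumeration", {
  M <- synthetic_signature_matrix(5, seed = 12)
  fit <- withr::with_seed(13, {
    counts <- setNames(as.numeric(rmultinom(1, 400, M %*% rep(0.2, 5))),
                       rownames(M))
    fit_exposures(counts, M)
  })
  dnms <- withr::with_seed(14, {
    tibble::tibble(channel = sample(sbs96_channels(), 200, replace = TRUE))
  })
  got <- assign_mutations(dnms, fit, M)
  e <- fit$exposure
  want <- vapply(dnms$channel, function(ch) {
    k <- match(ch, sbs96_channels())
    scores <- e * M[k, ]
    if (all(scores <= 0)) "unassigned" else colnames(M)[which.max(scores)]
  }, character(1), USE.NAMES = FALSE)
  expect_equal(got$signature, want)
  # conservation at every grouping level
  expect_equal(sum(table(got$signature)), nrow(dnms))
})

test_that("family-count eligibility applies per cohort", {
  mk <- function(sig, cohort, n_fams) {
    tibble::tibble(signature = sig, cohort = cohort,
                   family_id = sprintf("%s_%02d", cohort, seq_len(n_fams)))
  }
  a <- dplyr::bind_rows(mk("SBS_x", "control", 12), mk("SBS_x", "NTV", 15),
                        mk("SBS_y", "control", 9), mk("SBS_y", "NTV", 20))
  expect_equal(families_with_signature(a, 10), "SBS_x")
  expect_equal(families_with_signature(a[0, ], 10), character(0))
})

test_that("downscaling preserves the target total with deterministic rounding", {
  expect_equal(unname(downscale_catalogue(c(10, 30), 8)), c(2L, 6L))
  tie <- downscale_catalogue(c(1, 1, 1), 2)
  expect_equal(sum(tie), 2L)
  expect_equal(unname(tie), c(1L, 1L, 0L))  # remainder ties break by index
  x <- c(a = 5, b = 12, c = 3)
  expect_equal(downscale_catalogue(x, sum(x)), setNames(as.integer(x), names(x)))
})

test_that("cohort signature comparison reproduces the large-count chi-square and Holm caps", {
  # one signature dominating the difference between two near-equal cohorts
  ca <- c(SBS_a = 432, SBS_b = 1851 - 432)
  cb <- c(SBS_a = 569, SBS_b = 1868 - 569)
  res <- compare_cohort_signatures(ca, cb)
  expect_lt(res$p[res$signature == "SBS_a"], 0.01)
  expect_equal(res$method, rep("chi-square", 2))
  # identical counts: null case
  same <- compare_cohort_signatures(c(SBS_a = 50, SBS_b = 50),
                                    c(SBS_a = 50, SBS_b = 50))
  expect_equal(same$p, rep(1, 2))
  expect_equal(same$p_adj, rep(1, 2))
  # single tested signature: adjusted equals raw
  one <- compare_cohort_signatures(c(SBS_a = 30), c(SBS_a = 40))
  expect_equal(one$p_adj, one$p)
  # small expected cells fall back to Fisher and are flagged
  small <- compare_cohort_signatures(c(SBS_a = 2, SBS_b = 100),
                                     c(SBS_a = 6, SBS_b = 90))
  expect_equal(small$method[small$signature == "SBS_a"], "fisher")
})
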
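# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (enumeration, O(n^2) sweeps,
# textbook formulas) and share no code with the implementation paths they
# check.

# All 27 non-missing trio genotype combinations over {0/0, 0/1, 1/1}.
trio_gt_grid <- function() {
  gts <- c("0/0", "0/1", "1/1")
  expand.grid(father = gts, mother = gts, child = gts,
              stringsAsFactors = FALSE)
}

# Transmission-rule oracle: enumerate every (paternal allele, maternal
# allele) pair and ask whether any yields the child's multiset.
oracle_mendelian_violation <- function(father, mother, child) {
  alleles <- function(gt) as.integer(strsplit(gt, "/")[[1]])
  f <- alleles(father)
  m <- alleles(mother)
  c_ <- sort(alleles(child))
  for (a in f) {
    for (b in m) {
      if (identical(sort(c(a, b)), c_)) return(FALSE)
    }
  }
  TRUE
}

# Order-free single-pass conjunction of every cascade rule.
oracle_cascade_keep <- function(v, cfg) {
  ann <- switch(cfg$annotation_mode,
    off = TRUE,
    any = isTRUE(v$pop_af < cfg$max_pop_af) ||
      isTRUE(v$deleterious_votes >= cfg$min_deleterious_votes) ||
      isTRUE(v$region == "exon_splice"),
    all = isTRUE(v$pop_af < cfg$max_pop_af) &&
      isTRUE(v$deleterious_votes >= cfg$min_deleterious_votes) &&
      isTRUE(v$region == "exon_splice")
  )
  mv <- !anyNA(c(v$father_gt, v$mother_gt, v$child_gt)) &&
    !any(grepl("\\.", c(v$father_gt, v$mother_gt, v$child_gt))) &&
    oracle_mendelian_violation(v$father_gt, v$mother_gt, v$child_gt)
  ann && mv &&
    (!cfg$exclude_repeats || !isTRUE(v$in_repeat)) &&
    v$father_alt <= cfg$max_parent_alt_reads &&
    v$mother_alt <= cfg$max_parent_alt_reads &&
    v$father_dp >= cfg$min_parent_dp &&
    v$mother_dp >= cfg$min_parent_dp &&
    v$child_alt >= cfg$min_child_alt_reads &&
    v$child_gq >= cfg$child_min_gq &&
    v$father_gq >= cfg$parent_min_gq &&
    v$mother_gq >= cfg$parent_min_gq
}

# Random trio variants that straddle every threshold.
random_trio_variants <- function(n, seed) {
  withr::with_seed(seed, {
    gts <- c("0/0", "0/1", "1/1", "./.")
    tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(1e6, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = "T", vclass = sample(c("SNV", "indel"), n, replace = TRUE),
      father_gt = sample(gts, n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
      father_dp = sample(4:40, n, replace = TRUE),
      father_alt = sample(0:3, n, replace = TRUE),
      father_gq = sample(40:99, n, replace = TRUE),
      mother_gt = sample(gts, n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
      mother_dp = sample(4:40, n, replace = TRUE),
      mother_alt = sample(0:3, n, replace = TRUE),
      mother_gq = sample(40:99, n, replace = TRUE),
      child_gt = sample(c("0/1", "1/1", "0/0"), n, replace = TRUE),
      child_dp = sample(4:40, n, replace = TRUE),
      child_alt = sample(0:10, n, replace = TRUE),
      child_gq = sample(c(99L, 98L, 90L), n, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2)),
      pop_af = ifelse(runif(n) < 0.3, NA, runif(n, 0, 0.05)),
      deleterious_votes = sample(0:4, n, replace = TRUE),
      region = sample(c("exon_splice", "other"), n, replace = TRUE),
      in_repeat = runif(n) < 0.2,
      mv_cohort_flag = FALSE,
      origin = NA_character_
    )
  })
}

# Random SV call tables across callers/families.
random_sv_calls <- function(n, seed, n_fams = 2) {
  withr::with_seed(seed, {
    start <- sample.int(5e4, n, replace = TRUE)
    len <- sample(100:2000, n, replace = TRUE)
    tibble::tibble(
      family_id = sample(sprintf("FAM%02d", seq_len(n_fams)), n, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = start, end = start + len,
      svtype = sample(c("DEL", "DUP", "INS", "INV"), n, replace = TRUE),
      length = len,
      caller = sample(c("delly", "lumpy", "manta", "breakseq", "cnvnator",
                        "svaba"), n, replace = TRUE),
      plus_reads = sample(0:10, n, replace = TRUE),
      minus_reads = sample(0:10, n, replace = TRUE)
    )
  })
}

# Transitive-closure merge oracle: boolean adjacency, closed by iteration.
oracle_merge_components <- function(calls, d) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same_fam <- !("family_id" %in% names(calls)) ||
        calls$family_id[i] == calls$family_id[j]
      adj[i, j] <- same_fam &&
        calls$chrom[i] == calls$chrom[j] &&
        calls$svtype[i] == calls$svtype[j] &&
        abs(calls$start[i] - calls$start[j]) <= d &&
        abs(calls$end[i] - calls$end[j]) <= d
    }
  }
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[adj[i, ]] <- k
    }
  }
  comp
}

# O(n^2) pairwise clustering oracle for one family/chromosome set of
# positions: link every pair closer than `window`, close transitively.
oracle_cluster_sets <- function(pos, window) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) < window
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[adj[i, ]] <- k
    }
  }
  sets <- split(sort(pos), comp[order(pos)])
  Filter(function(s) length(s) >= 2, unname(sets))
}

# Textbook Pearson chi-square.
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Definition-based Holm step-down.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Tie-corrected Kruskal-Wallis H from the rank formula.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# ECDF-sweep KS statistic.
oracle_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
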
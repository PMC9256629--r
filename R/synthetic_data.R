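# Synthetic trio-study generator: mini-genome, reference signature matrix,
# planted de novo mutations (with paternal-age dependence, signature-mixture
# spectra, clusters, decoys and inherited background), noisy multi-caller SV
# call sets, pedigree and covariates — all with exported ground truth and
# byte-identical output per seed.

SV_CALLERS <- c("delly", "lumpy", "manta", "breakseq", "cnvnator", "svaba")

#' Configuration of a synthetic trio study
#'
#' Defaults emulate the study design this package targets: 30 families per
#' cohort, a mean of 62 de novo mutations per offspring with a log-linear
#' paternal-age effect, 10% indels, a small clustered fraction, 80%
#' paternal origin, and six SV callers observing a handful of true events
#' through jittered breakpoints plus caller-private false positives.
#'
#' @param n_families_per_cohort Families in each of the two cohorts.
#' @param dnm_rate_mean Mean DNMs per offspring at the reference paternal
#'   age (30 years).
#' @param paternal_age_slope Log-scale increase in the DNM rate per year of
#'   paternal age.
#' @param cohort_fold Rate ratio exposed/control (1 = null study).
#' @param dispersion NB2 dispersion of per-offspring counts (0 = Poisson).
#' @param signature_mixture Named weights over signature-matrix columns
#'   (normalised internally); `NULL` = uniform.
#' @param cluster_fraction Fraction of SNVs planted as members of <10 bp
#'   pairs.
#' @param indel_fraction Fraction of DNMs that are indels.
#' @param indel_del_prob Probability an indel is a deletion.
#' @param paternal_fraction Fraction of DNMs of paternal origin.
#' @param inherited_variants_per_trio Mendelian-consistent background
#'   variants per trio.
#' @param decoy_fraction Fraction (of the DNM count) of planted decoys each
#'   failing exactly one named filter rule.
#' @param parent_contamination_prob Probability a true DNM shows one
#'   stray parental alt read (still below the filter threshold).
#' @param n_true_svs True de novo SVs per family.
#' @param sv_caller_sensitivity Per-caller detection probability (single
#'   value or named vector over the six callers).
#' @param breakpoint_jitter_sd SD (bp) of Gaussian breakpoint noise per
#'   caller.
#' @param fp_sv_rate Expected caller-private false-positive SVs per caller
#'   per family.
#' @param depth_mean Mean sequencing depth for simulated genotype metrics.
#' @param n_contigs,contig_length Mini-genome shape.
#' @param n_signatures Columns of the synthetic signature matrix.
#' @param seed Mandatory RNG seed; the whole bundle is a deterministic
#'   function of the configuration.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_families_per_cohort = 30, dnm_rate_mean = 62,
                              paternal_age_slope = 0.02, cohort_fold = 1,
                              dispersion = 0, signature_mixture = NULL,
                              cluster_fraction = 0.02, indel_fraction = 0.1,
                              indel_del_prob = 0.65, paternal_fraction = 0.8,
                              inherited_variants_per_trio = 100,
                              decoy_fraction = 0,
                              parent_contamination_prob = 0.05,
                              n_true_svs = 5, sv_caller_sensitivity = 0.95,
                              breakpoint_jitter_sd = 10, fp_sv_rate = 5,
                              depth_mean = 35, n_contigs = 3,
                              contig_length = 200000, n_signatures = 5,
                              seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  probs <- c(cluster_fraction, indel_fraction, indel_del_prob,
             paternal_fraction, decoy_fraction, parent_contamination_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("fractions and probabilities must lie in [0, 1]")
  }
  if (!is.null(signature_mixture)) {
    if (any(signature_mixture < 0) || sum(signature_mixture) <= 0) {
      abort("signature_mixture weights must be non-negative with positive sum")
    }
  }
  sens <- sv_caller_sensitivity
  if (length(sens) == 1 && is.null(names(sens))) {
    sens <- setNames(rep(sens, 6), SV_CALLERS)
  }
  if (!setequal(names(sens), SV_CALLERS)) {
    abort("sv_caller_sensitivity must cover the six callers")
  }
  if (any(sens < 0 | sens > 1)) abort("sensitivities must lie in [0, 1]")
  structure(list(
    n_families_per_cohort = n_families_per_cohort,
    dnm_rate_mean = dnm_rate_mean, paternal_age_slope = paternal_age_slope,
    cohort_fold = cohort_fold, dispersion = dispersion,
    signature_mixture = signature_mixture,
    cluster_fraction = cluster_fraction, indel_fraction = indel_fraction,
    indel_del_prob = indel_del_prob, paternal_fraction = paternal_fraction,
    inherited_variants_per_trio = inherited_variants_per_trio,
    decoy_fraction = decoy_fraction,
    parent_contamination_prob = parent_contamination_prob,
    n_true_svs = n_true_svs, sv_caller_sensitivity = sens[SV_CALLERS],
    breakpoint_jitter_sd = breakpoint_jitter_sd, fp_sv_rate = fp_sv_rate,
    depth_mean = depth_mean, n_contigs = n_contigs,
    contig_length = contig_length, n_signatures = n_signatures,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Synthetic reference signature matrix
#'
#' Builds a 96 x S matrix of distinct, well-separated signatures: each
#' column concentrates 80% of its mass on its own block of channels with a
#' 20% uniform background, then normalises to sum 1. Deterministic given
#' the seed.
#'
#' @param n_signatures Number of columns.
#' @param labels Column labels (default `SBS_s1` ...).
#' @param seed RNG seed.
#' @return 96 x S matrix, channel rownames in canonical order.
#' @export
synthetic_signature_matrix <- function(n_signatures = 5, labels = NULL,
                                       seed = 1) {
  labels <- labels %||% paste0("SBS_s", seq_len(n_signatures))
  if (length(labels) != n_signatures) abort("one label per signature")
  with_seed(seed, {
    m <- matrix(0, 96, n_signatures,
                dimnames = list(sbs96_channels(), labels))
    blocks <- split(seq_len(96), cut(seq_len(96), n_signatures, labels = FALSE))
    for (s in seq_len(n_signatures)) {
      peak <- runif(length(blocks[[s]]))
      m[blocks[[s]], s] <- 0.8 * peak / sum(peak)
      bg <- runif(96)
      m[, s] <- m[, s] + 0.2 * bg / sum(bg)
    }
    sweep(m, 2, colSums(m), "/")
  })
}

#' Random mini-genome with fixed base composition
#'
#' @param n_contigs,contig_length Shape of the genome.
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet] with contigs `chr1`, `chr2`, ...
#' @export
synthetic_genome <- function(n_contigs = 3, contig_length = 200000, seed = 1) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
                   prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n_contigs))))
  })
}

#' Sample mutation channels from a signature mixture
#'
#' Draws i.i.d. channels from the mixture distribution
#' `sum_s w_s M[, s]` over the 96 channels.
#'
#' @param n Number of channels to draw.
#' @param signature_mixture Named non-negative weights over matrix columns.
#' @param signature_matrix 96 x S reference matrix.
#' @param seed Optional seed (`NULL` = use the ambient RNG state).
#' @return Character vector of channel labels, length `n`.
#' @export
simulate_dnm_channels <- function(n, signature_mixture, signature_matrix,
                                  seed = NULL) {
  if (n == 0) return(character(0))
  if (is.null(names(signature_mixture))) {
    if (length(signature_mixture) != ncol(signature_matrix)) {
      abort("unnamed mixture must have one weight per signature")
    }
    w <- signature_mixture
  } else {
    w <- setNames(rep(0, ncol(signature_matrix)), colnames(signature_matrix))
    w[names(signature_mixture)] <- signature_mixture
  }
  w <- w / sum(w)
  p <- as.numeric(signature_matrix %*% w)
  with_seed(seed, sample(sbs96_channels(), n, replace = TRUE, prob = p))
}

# Index genome positions by pyrimidine-centred trinucleotide context.
# Returns a tibble (chrom, pos, mid, context) for interior positions.
context_index <- function(genome) {
  purrr::map_dfr(names(genome), function(ctg) {
    s <- as.character(genome[[ctg]])
    L <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    p5 <- ch[1:(L - 2)]
    mid <- ch[2:(L - 1)]
    p3 <- ch[3:L]
    pyr <- mid %in% c("C", "T")
    ctx <- ifelse(pyr, paste0(p5, mid, p3),
                  paste0(dna_complement(p3), dna_complement(mid),
                         dna_complement(p5)))
    tibble::tibble(chrom = ctg, pos = 2:(L - 1), mid = mid, context = ctx)
  })
}

# Draw per-offspring DNM counts from the generator's count model:
# log mean = log(rate) + slope * (age - 30) + log(fold) * [exposed].
draw_dnm_counts <- function(ages, exposed, config) {
  mu <- config$dnm_rate_mean *
    exp(config$paternal_age_slope * (ages - 30)) *
    ifelse(exposed, config$cohort_fold, 1)
  if (config$dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    rpois(length(mu), mu)
  }
}

#' Simulate per-offspring DNM totals
#'
#' Exposes the generator's count model on its own (Poisson, or NB2 when
#' `dispersion > 0`, with a log-linear paternal-age term and a cohort rate
#' ratio) so that rate and fold properties can be checked at large n
#' without building file bundles.
#'
#' @param n Offspring per cohort.
#' @param config A [simulation_config()].
#' @return Tibble `cohort`, `paternal_age_conception`, `n_dnm`.
#' @export
simulate_offspring_counts <- function(n, config) {
  with_seed(config$seed, {
    ages <- pmin(pmax(rnorm(2 * n, 30, 5), 18), 50)
    exposed <- rep(c(FALSE, TRUE), each = n)
    tibble::tibble(
      cohort = ifelse(exposed, "NTV", "control"),
      paternal_age_conception = round(ages, 1),
      n_dnm = draw_dnm_counts(ages, exposed, config)
    )
  })
}

# Non-violating trio genotype configurations used for the inherited
# background (father, mother, child).
INHERITED_GT <- matrix(c(
  "0/1", "0/0", "0/1",
  "0/0", "0/1", "0/1",
  "0/1", "0/1", "0/1",
  "0/1", "0/1", "1/1",
  "0/1", "0/1", "0/0",
  "1/1", "0/0", "0/1",
  "0/0", "0/1", "0/0"
), ncol = 3, byrow = TRUE)

DECOY_RULES <- c("parental alt reads", "parental depth", "child alt reads",
                 "child GQ", "parental GQ", "repeat region")

#' Simulate a complete synthetic trio study
#'
#' Generates the full input bundle of a two-cohort trio study — pedigree,
#' covariates, per-family trio variants (planted DNMs with clusters,
#' channel-faithful contexts and known parental origin; decoys failing
#' exactly one named filter rule; Mendelian-consistent inherited
#' background), true SVs with noisy per-caller call sets, a mini-genome and
#' a synthetic signature matrix — together with the ground truth. With
#' `dir` set, the bundle is also written as plain files (PED, TSVs,
#' per-trio and per-caller VCFs, FASTA, truth JSON); output is
#' byte-identical for identical configurations.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory.
#' @return List with `bundle` (tibbles: `pedigree`, `covariates`,
#'   `variants`, `sv_calls`; `genome`; `signature_matrix`; `config`) and
#'   `truth` (`dnms`, `svs`, `coefficients`).
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sig_m <- synthetic_signature_matrix(config$n_signatures,
                                      seed = config$seed + 1000L)
  genome <- synthetic_genome(config$n_contigs, config$contig_length,
                             seed = config$seed + 2000L)
  ctx_idx <- context_index(genome)
  ctx_by_context <- split(seq_len(nrow(ctx_idx)), ctx_idx$context)

  mixture <- config$signature_mixture %||%
    setNames(rep(1, ncol(sig_m)), colnames(sig_m))

  out <- with_seed(config$seed, {
    n <- config$n_families_per_cohort
    fams <- sprintf("FAM%03d", seq_len(2 * n))
    cohort <- rep(c("control", "NTV"), each = n)
    ped <- tibble::tibble(
      family_id = fams,
      father_id = paste0(fams, "_fa"),
      mother_id = paste0(fams, "_mo"),
      child_id = paste0(fams, "_ch"),
      cohort = cohort
    )
    ages <- round(pmin(pmax(rnorm(2 * n, 30, 5), 18), 50), 1)
    covar <- tibble::tibble(
      family_id = fams, cohort = cohort,
      paternal_age_conception = ages,
      child_age_sampling = round(pmin(pmax(rnorm(2 * n, 52, 6), 27), 60), 1),
      exposure_rank = ifelse(cohort == "NTV",
                             sample(1:3, 2 * n, replace = TRUE,
                                    prob = c(0.3, 0.3, 0.4)), 1L),
      occupational_exposure = runif(2 * n) < 0.1,
      medical_diagnostics = runif(2 * n) < 0.3,
      smoker = runif(2 * n) < 0.3,
      alcohol = sample(0:2, 2 * n, replace = TRUE)
    )

    n_dnm <- draw_dnm_counts(ages, cohort == "NTV", config)

    fam_out <- purrr::map(seq_along(fams), function(i) {
      simulate_family(fams[i], cohort[i], n_dnm[i], config, genome,
                      ctx_idx, ctx_by_context, mixture, sig_m)
    })
    variants <- dplyr::bind_rows(purrr::map(fam_out, "variants"))
    truth_dnms <- dplyr::bind_rows(purrr::map(fam_out, "truth"))

    svs <- simulate_true_svs(fams, config, genome)
    sv_calls <- simulate_sv_callsets(svs, config)

    list(pedigree = ped, covariates = covar, variants = variants,
         truth_dnms = truth_dnms, true_svs = svs, sv_calls = sv_calls)
  })

  truth <- list(
    dnms = out$truth_dnms,
    svs = out$true_svs,
    coefficients = tibble::tibble(
      term = c("log_rate", "paternal_age_slope", "log_cohort_fold"),
      value = c(log(config$dnm_rate_mean), config$paternal_age_slope,
                log(config$cohort_fold))
    )
  )
  bundle <- list(pedigree = out$pedigree, covariates = out$covariates,
                 variants = out$variants, sv_calls = out$sv_calls,
                 genome = genome, signature_matrix = sig_m, config = config)
  if (!is.null(dir)) write_bundle(bundle, truth, dir)
  list(bundle = bundle, truth = truth)
}

# Build one family's variant table (planted DNMs + decoys + inherited
# background) and its ground-truth records. Runs inside the study's seeded
# RNG scope.
simulate_family <- function(family_id, cohort, n_dnm, config, genome,
                            ctx_idx, ctx_by_context, mixture, sig_m) {
  used <- new.env(parent = emptyenv())
  take_pos <- function(rows) {
    # sample an unused context row index
    for (k in seq_len(50)) {
      cand <- rows[[sample.int(length(rows), 1)]]
      key <- paste0(ctx_idx$chrom[cand], ":", ctx_idx$pos[cand])
      if (is.null(used[[key]])) {
        used[[key]] <- TRUE
        return(cand)
      }
    }
    NA_integer_
  }

  n_indel <- rbinom(1, n_dnm, config$indel_fraction)
  n_snv <- n_dnm - n_indel
  channels <- simulate_dnm_channels(n_snv, mixture, sig_m)
  n_cluster_pairs <- floor(config$cluster_fraction * n_snv / 2)

  dnm_rows <- list()
  add_snv <- function(chrom, pos, ref, alt, channel, clustered) {
    dnm_rows[[length(dnm_rows) + 1L]] <<- tibble::tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt, vclass = "SNV",
      channel = channel, clustered = clustered
    )
  }

  # channel-faithful SNV placement: pick a genome position whose
  # pyrimidine-centred context matches the sampled channel
  for (j in seq_len(n_snv)) {
    ch <- channels[j]
    ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
    alt_pyr <- substr(ch, 5, 5)
    rows <- ctx_by_context[[ctx]]
    idx <- take_pos(rows)
    if (is.na(idx)) next
    mid <- ctx_idx$mid[idx]
    if (mid %in% c("C", "T")) {
      ref <- mid
      alt <- alt_pyr
    } else {
      ref <- mid
      alt <- dna_complement(alt_pyr)
    }
    add_snv(ctx_idx$chrom[idx], ctx_idx$pos[idx], ref, alt, ch,
            clustered = FALSE)
  }
  dnms <- dplyr::bind_rows(dnm_rows)

  # convert some SNVs into <10 bp pairs: add a partner mutation next to an
  # existing one (the partner's channel follows from its own context)
  if (n_cluster_pairs > 0 && nrow(dnms) > 0) {
    anchors <- head(sample.int(nrow(dnms)), n_cluster_pairs)
    partners <- list()
    for (a in anchors) {
      p2 <- dnms$pos[a] + sample(1:9, 1)
      hit <- which(ctx_idx$chrom == dnms$chrom[a] & ctx_idx$pos == p2)
      if (length(hit) != 1) next
      key <- paste0(dnms$chrom[a], ":", p2)
      if (!is.null(used[[key]])) next
      used[[key]] <- TRUE
      mid <- ctx_idx$mid[hit]
      alt <- sample(setdiff(c("A", "C", "G", "T"), mid), 1)
      trip_pyr <- ctx_idx$context[hit]
      alt_pyr <- if (mid %in% c("C", "T")) alt else dna_complement(alt)
      ch <- paste0(substr(trip_pyr, 1, 1), "[", substr(trip_pyr, 2, 2), ">",
                   alt_pyr, "]", substr(trip_pyr, 3, 3))
      partners[[length(partners) + 1L]] <- tibble::tibble(
        chrom = dnms$chrom[a], pos = p2, ref = mid, alt = alt,
        vclass = "SNV", channel = ch, clustered = TRUE)
      dnms$clustered[a] <- TRUE
    }
    dnms <- dplyr::bind_rows(dnms, partners)
  }

  # indels: deletions ref = anchored genome run, insertions random bases
  if (n_indel > 0) {
    ctgs <- names(genome)
    ind <- purrr::map_dfr(seq_len(n_indel), function(j) {
      ctg <- sample(ctgs, 1)
      len <- sample(1:20, 1, prob = 0.8^(1:20))
      pos <- sample.int(length(genome[[ctg]]) - len - 2, 1) + 1L
      anchor <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos))
      if (runif(1) < config$indel_del_prob) {
        ref <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos + len))
        tibble::tibble(chrom = ctg, pos = pos, ref = ref, alt = anchor,
                       vclass = "indel", channel = NA_character_,
                       clustered = FALSE)
      } else {
        alt <- paste0(anchor, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
        tibble::tibble(chrom = ctg, pos = pos, ref = anchor, alt = alt,
                       vclass = "indel", channel = NA_character_,
                       clustered = FALSE)
      }
    })
    dnms <- dplyr::bind_rows(dnms, ind)
  }

  n_real <- nrow(dnms)
  dnms$origin <- ifelse(runif(n_real) < config$paternal_fraction,
                        "paternal", "maternal")
  dnms$family_id <- family_id
  dnms$cohort <- cohort

  dnm_vars <- dnm_metrics(dnms, config)
  truth <- dnms[, c("family_id", "cohort", "chrom", "pos", "ref", "alt",
                    "vclass", "channel", "clustered", "origin")]
  truth$kind <- "dnm"
  truth$decoy_rule <- NA_character_

  # decoys: DNM-like records each violating exactly one cascade rule
  n_decoy <- round(config$decoy_fraction * max(n_real, 1))
  if (n_decoy > 0) {
    rules <- rep_len(DECOY_RULES, n_decoy)
    dec <- purrr::map_dfr(seq_len(n_decoy), function(j) {
      ctg <- sample(names(genome), 1)
      pos <- sample.int(length(genome[[ctg]]) - 2, 1) + 1L
      ref <- as.character(Biostrings::subseq(genome[[ctg]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      tibble::tibble(chrom = ctg, pos = pos, ref = ref, alt = alt,
                     vclass = "SNV", channel = NA_character_,
                     clustered = FALSE, origin = "unknown",
                     family_id = family_id, cohort = cohort)
    })
    dec_vars <- dnm_metrics(dec, config, contamination = FALSE)
    for (j in seq_len(n_decoy)) {
      dec_vars[j, ] <- break_rule(dec_vars[j, ], rules[j])
    }
    dec_truth <- dec[, c("family_id", "cohort", "chrom", "pos", "ref", "alt",
                         "vclass", "channel", "clustered", "origin")]
    dec_truth$kind <- "decoy"
    dec_truth$decoy_rule <- rules
    truth <- dplyr::bind_rows(truth, dec_truth)
    dnm_vars <- dplyr::bind_rows(dnm_vars, dec_vars)
  }

  inh <- simulate_inherited(family_id, cohort, config, genome)
  variants <- dplyr::bind_rows(dnm_vars, inh)
  variants <- variants[sample.int(nrow(variants)), , drop = FALSE]
  list(variants = variants, truth = truth)
}

# Attach trio genotype metrics making a record a clean DNM: child het with
# >= 3 alt reads and GQ 99, parents hom-ref at depth >= 7 with GQ >= 50.
dnm_metrics <- function(dnms, config, contamination = TRUE) {
  n <- nrow(dnms)
  child_dp <- pmax(rpois(n, config$depth_mean), 10L)
  child_alt <- pmax(rbinom(n, child_dp, 0.5), 3L)
  parent_dp <- function() pmax(rpois(n, config$depth_mean), 7L)
  contam <- if (contamination) {
    as.integer(runif(n) < config$parent_contamination_prob)
  } else rep(0L, n)
  tibble::tibble(
    family_id = dnms$family_id, chrom = dnms$chrom, pos = dnms$pos,
    ref = dnms$ref, alt = dnms$alt, vclass = dnms$vclass,
    origin = dnms$origin,
    father_gt = "0/0", father_dp = parent_dp(), father_alt = contam,
    father_gq = sample(60:99, n, replace = TRUE),
    mother_gt = "0/0", mother_dp = parent_dp(), mother_alt = 0L,
    mother_gq = sample(60:99, n, replace = TRUE),
    child_gt = "0/1", child_dp = child_dp, child_alt = child_alt,
    child_gq = 99L,
    pop_af = NA_real_, deleterious_votes = NA_real_, region = "other",
    in_repeat = FALSE, mv_cohort_flag = FALSE
  )
}

# Flip exactly one filter rule on a DNM-like record.
break_rule <- function(row, rule) {
  switch(rule,
    "parental alt reads" = {
      row$mother_alt <- 2L
      row
    },
    "parental depth" = {
      row$father_dp <- 6L
      row
    },
    "child alt reads" = {
      row$child_alt <- 2L
      row
    },
    "child GQ" = {
      row$child_gq <- 98L
      row
    },
    "parental GQ" = {
      row$mother_gq <- 49L
      row
    },
    "repeat region" = {
      row$in_repeat <- TRUE
      row
    },
    abort(sprintf("unknown decoy rule '%s'", rule))
  )
}

# Mendelian-consistent background variants with filter-passing metrics, so
# that only the violation requirement removes them.
simulate_inherited <- function(family_id, cohort, config, genome) {
  n <- config$inherited_variants_per_trio
  if (n == 0) return(NULL)
  ctgs <- names(genome)
  cfg_rows <- INHERITED_GT[sample.int(nrow(INHERITED_GT), n, replace = TRUE), ,
                           drop = FALSE]
  ctg <- sample(ctgs, n, replace = TRUE)
  pos <- vapply(ctg, function(cg) {
    sample.int(length(genome[[cg]]) - 2L, 1) + 1L
  }, integer(1))
  ref <- vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(genome[[ctg[i]]], pos[i], pos[i]))
  }, character(1))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  dp <- function() pmax(rpois(n, config$depth_mean), 10L)
  child_dp <- dp()
  child_has_alt <- cfg_rows[, 3] != "0/0"
  tibble::tibble(
    family_id = family_id, chrom = ctg, pos = as.integer(pos),
    ref = ref, alt = alt, vclass = "SNV", origin = NA_character_,
    father_gt = cfg_rows[, 1], father_dp = dp(),
    father_alt = ifelse(cfg_rows[, 1] == "0/0", 0L, 12L),
    father_gq = sample(60:99, n, replace = TRUE),
    mother_gt = cfg_rows[, 2], mother_dp = dp(),
    mother_alt = ifelse(cfg_rows[, 2] == "0/0", 0L, 12L),
    mother_gq = sample(60:99, n, replace = TRUE),
    child_gt = cfg_rows[, 3], child_dp = child_dp,
    child_alt = ifelse(child_has_alt, pmax(rbinom(n, child_dp, 0.5), 3L), 0L),
    child_gq = 99L,
    pop_af = round(runif(n, 0.02, 0.5), 3), deleterious_votes = 0,
    region = "other", in_repeat = FALSE, mv_cohort_flag = FALSE
  )
}

# True de novo SVs per family: deletions sized to the <=300 bp support rule,
# duplications to the <=1500 bp rule, on random non-colliding loci.
simulate_true_svs <- function(fams, config, genome) {
  if (config$n_true_svs == 0) return(empty_sv_calls()[, 1:6])
  purrr::map_dfr(fams, function(fam) {
    ctg <- sample(names(genome), config$n_true_svs, replace = TRUE)
    svtype <- sample(c("DEL", "DUP"), config$n_true_svs, replace = TRUE,
                     prob = c(0.7, 0.3))
    len <- ifelse(svtype == "DEL",
                  sample(100:300, config$n_true_svs, replace = TRUE),
                  sample(200:1500, config$n_true_svs, replace = TRUE))
    start <- vapply(seq_len(config$n_true_svs), function(i) {
      sample.int(length(genome[[ctg[i]]]) - len[i] - 10L, 1)
    }, integer(1))
    tibble::tibble(family_id = fam, chrom = ctg, start = start,
                   end = start + len, svtype = svtype, length = len)
  })
}

#' Simulate noisy per-caller SV call sets
#'
#' Each of the six callers detects each true SV independently with its
#' sensitivity, reporting breakpoints jittered by Gaussian noise, and adds
#' caller-private false positives at a Poisson rate per family. Strand
#' support reads are populated on both strands.
#'
#' @param true_svs Tibble of true events (`family_id`, `chrom`, `start`,
#'   `end`, `svtype`, `length`).
#' @param config A [simulation_config()].
#' @param seed Optional seed (`NULL` = ambient RNG, as when called inside
#'   [simulate_study()]).
#' @return Tidy SV call tibble across callers.
#' @export
simulate_sv_callsets <- function(true_svs, config, seed = NULL) {
  with_seed(seed, {
    fams <- unique(true_svs$family_id)
    calls <- purrr::map_dfr(SV_CALLERS, function(cl) {
      sens <- config$sv_caller_sensitivity[[cl]]
      det <- true_svs[runif(nrow(true_svs)) < sens, , drop = FALSE]
      if (nrow(det) > 0) {
        # truncated-normal breakpoint error: callers localise breakpoints
        # from local read evidence, so errors are bounded (clamped at 2 sd)
        sd_ <- config$breakpoint_jitter_sd
        jit <- function(n) {
          as.integer(round(pmin(pmax(rnorm(n, 0, sd_), -2 * sd_), 2 * sd_)))
        }
        det$start <- pmax(det$start + jit(nrow(det)), 1L)
        det$end <- pmax(det$end + jit(nrow(det)), det$start + 50L)
        det$length <- det$end - det$start
      }
      fp_n <- rpois(length(fams), config$fp_sv_rate)
      fps <- purrr::map_dfr(seq_along(fams), function(i) {
        if (fp_n[i] == 0) return(NULL)
        len <- sample(100:5000, fp_n[i], replace = TRUE)
        start <- sample.int(config$contig_length - 6000L, fp_n[i])
        tibble::tibble(
          family_id = fams[i],
          chrom = paste0("chr", sample.int(config$n_contigs, fp_n[i],
                                           replace = TRUE)),
          start = start,
          end = start + len,
          svtype = sample(c("DEL", "DUP", "INS", "INV"), fp_n[i],
                          replace = TRUE),
          length = len
        )
      })
      out <- dplyr::bind_rows(det, fps)
      if (nrow(out) == 0) return(NULL)
      out$caller <- cl
      out$plus_reads <- rpois(nrow(out), 5) + 1L
      out$minus_reads <- rpois(nrow(out), 5) + 1L
      out
    })
    if (nrow(calls) == 0) return(empty_sv_calls())
    calls[, c("family_id", "chrom", "start", "end", "svtype", "length",
              "caller", "plus_reads", "minus_reads")]
  })
}

# ---- file bundle writing -------------------------------------------------

write_bundle <- function(bundle, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- bundle$pedigree
  ped_lines <- c(
    paste(ped$family_id, ped$father_id, "0", "0", "1", "1", sep = "\t"),
    paste(ped$family_id, ped$mother_id, "0", "0", "2", "1", sep = "\t"),
    paste(ped$family_id, ped$child_id, ped$father_id, ped$mother_id, "0",
          ifelse(ped$cohort == "NTV", "2", "1"), sep = "\t")
  )
  writeLines(ped_lines, file.path(dir, "families.ped"))
  readr::write_tsv(bundle$covariates, file.path(dir, "covariates.tsv"))
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  sig <- tibble::as_tibble(bundle$signature_matrix)
  sig <- dplyr::bind_cols(tibble::tibble(Type = rownames(bundle$signature_matrix)), sig)
  readr::write_tsv(sig, file.path(dir, "signatures.tsv"))

  trio_dir <- file.path(dir, "trios")
  dir.create(trio_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(ped))) {
    fam <- ped$family_id[i]
    v <- bundle$variants[bundle$variants$family_id == fam, , drop = FALSE]
    write_trio_vcf(v, ped[i, ], bundle$genome, file.path(trio_dir, paste0(fam, ".vcf")))
  }

  sv_dir <- file.path(dir, "sv")
  dir.create(sv_dir, showWarnings = FALSE)
  for (cl in unique(bundle$sv_calls$caller)) {
    cdir <- file.path(sv_dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (fam in ped$family_id) {
      calls <- bundle$sv_calls[bundle$sv_calls$caller == cl &
                                 bundle$sv_calls$family_id == fam, ,
                               drop = FALSE]
      write_sv_vcf(calls, bundle$genome, file.path(cdir, paste0(fam, ".vcf")))
    }
  }
  jsonlite::write_json(
    list(dnms = truth$dnms, svs = truth$svs,
         coefficients = truth$coefficients),
    file.path(dir, "truth.json"), dataframe = "columns", na = "null")
  invisible(dir)
}

vcf_header <- function(genome, samples, sv = FALSE) {
  contigs <- sprintf("##contig=<ID=%s,length=%d>", names(genome),
                     Biostrings::width(genome))
  info <- if (sv) {
    c('##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
      '##INFO=<ID=END,Number=1,Type=Integer,Description="SV end">',
      '##INFO=<ID=PLUS,Number=1,Type=Integer,Description="Plus-strand support reads">',
      '##INFO=<ID=MINUS,Number=1,Type=Integer,Description="Minus-strand support reads">')
  } else {
    c('##INFO=<ID=AF_POP,Number=1,Type=Float,Description="Population allele frequency">',
      '##INFO=<ID=DELVOTES,Number=1,Type=Integer,Description="Deleteriousness votes">',
      '##INFO=<ID=REGION,Number=1,Type=String,Description="Region class">',
      '##INFO=<ID=REPEAT,Number=0,Type=Flag,Description="Repeat region">',
      '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Simulated parental origin">',
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  }
  c("##fileformat=VCFv4.2", contigs, info,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!sv) "FORMAT", samples), collapse = "\t"))
}

write_trio_vcf <- function(variants, ped_row, genome, path) {
  samples <- c(ped_row$father_id, ped_row$mother_id, ped_row$child_id)
  v <- dplyr::arrange(variants, .data$chrom, .data$pos)
  fmt <- function(gt, dp, alt, gq) {
    ref_reads <- pmax(dp - alt, 0)
    paste0(gt, ":", dp, ":", ref_reads, ",", alt, ":", gq)
  }
  info <- ifelse(is.na(v$pop_af), ".", sprintf("AF_POP=%g", v$pop_af))
  add_key <- function(info, cond, key) {
    ifelse(cond, ifelse(info == ".", key, paste0(info, ";", key)), info)
  }
  info <- add_key(info, v$in_repeat, "REPEAT")
  has_origin <- !is.na(v$origin) & v$origin %in% c("paternal", "maternal")
  info <- add_key(info, has_origin, paste0("ORIGIN=", v$origin))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT:DP:AD:GQ",
                fmt(v$father_gt, v$father_dp, v$father_alt, v$father_gq),
                fmt(v$mother_gt, v$mother_dp, v$mother_alt, v$mother_gq),
                fmt(v$child_gt, v$child_dp, v$child_alt, v$child_gq),
                sep = "\t")
  writeLines(c(vcf_header(genome, samples), body), path)
  invisible(path)
}

write_sv_vcf <- function(calls, genome, path) {
  v <- dplyr::arrange(calls, .data$chrom, .data$start)
  body <- if (nrow(v) == 0) character(0) else {
    paste(v$chrom, v$start, ".", "N", paste0("<", v$svtype, ">"), ".", "PASS",
          sprintf("SVTYPE=%s;END=%d;PLUS=%d;MINUS=%d", v$svtype, v$end,
                  v$plus_reads, v$minus_reads),
          sep = "\t")
  }
  writeLines(c(vcf_header(genome, character(0), sv = TRUE), body), path)
  invisible(path)
}
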
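# Study orchestration: run every stage on an input bundle (in-memory or a
# directory of standard files) and emit the cohort-comparison tables.

#' Run the full trio DNM study
#'
#' Executes, in order: the candidate DNM filter cascade per family, the
#' multi-caller SV consensus, clustered-mutation detection at 10 and 100 bp,
#' per-family endpoint counting, mutation-spectrum chi-square tests
#' (transitions/transversions, deletions/insertions, SV types), KS
#' comparison of indel and SV size spectra, 96-channel catalogue
#' construction with signature fitting, per-mutation assignment and
#' Holm-adjusted cohort comparison, per-family Williams binomial tests for
#' eligible signatures, Kruskal-Wallis endpoint comparisons with Holm
#' adjustment, bootstrap per-offspring rates and the negative-binomial
#' exposure regression.
#'
#' @param bundle Either the `bundle` element of [simulate_study()] or a
#'   directory created with `simulate_study(config, dir = ...)`.
#' @param filter_cfg A [filter_config()].
#' @param merge_cfg A [merge_config()].
#' @param min_families Eligibility threshold for per-family signature
#'   testing.
#' @param seed Seed for the bootstrap confidence intervals.
#' @return A list of class `study_tables`; see the elements documented in
#'   the package vignette.
#' @export
run_study <- function(bundle, filter_cfg = filter_config(),
                      merge_cfg = merge_config(), min_families = 10,
                      seed = 1) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  ped <- bundle$pedigree
  variants <- bundle$variants
  cohorts <- sort(unique(ped$cohort))
  if (length(cohorts) != 2) abort("a two-cohort pedigree is required")

  # --- DNM cascade per family
  per_fam <- purrr::map(seq_len(nrow(ped)), function(i) {
    fam_vars <- variants[variants$family_id == ped$family_id[i], , drop = FALSE]
    run_dnm_cascade(fam_vars, ped[i, ], filter_cfg)
  })
  dnm_calls <- dplyr::bind_rows(purrr::map(per_fam, "calls"))
  filter_summary <- dplyr::bind_rows(
    purrr::map2(purrr::map(per_fam, "summary"), ped$family_id,
                ~ dplyr::mutate(.x, family_id = .y))) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(snv = sum(.data$snv), indel = sum(.data$indel),
                     .groups = "drop")

  # --- SV consensus
  sv <- run_sv_consensus(bundle$sv_calls, ped, merge_cfg)

  # --- clusters
  clusters10 <- detect_clusters(dnm_calls, 10)
  clusters100 <- detect_clusters(dnm_calls, 100)

  # --- per-family endpoint counts
  per_family <- ped[, c("family_id", "cohort")] |>
    dplyr::left_join(
      dnm_calls |>
        dplyr::group_by(.data$family_id) |>
        dplyr::summarise(n_snv = sum(.data$vclass == "SNV"),
                         n_indel = sum(.data$vclass == "indel"),
                         n_paternal = sum(.data$origin == "paternal"),
                         .groups = "drop"),
      by = "family_id") |>
    dplyr::left_join(dplyr::count(sv$consensus, .data$family_id, name = "n_sv"),
                     by = "family_id") |>
    dplyr::left_join(dplyr::count(clusters10, .data$family_id,
                                  name = "n_clusters_lt10"),
                     by = "family_id") |>
    dplyr::left_join(dplyr::count(clusters100, .data$family_id,
                                  name = "n_clusters_lt100"),
                     by = "family_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ dplyr::coalesce(.x, 0L)))

  # --- mutation spectra
  snvs <- dnm_calls[dnm_calls$vclass == "SNV", , drop = FALSE]
  indels <- dnm_calls[dnm_calls$vclass == "indel", , drop = FALSE]
  indels$indel_len <- abs(nchar(indels$ref) - nchar(indels$alt))
  indels$indel_type <- ifelse(nchar(indels$ref) > nchar(indels$alt),
                              "deletion", "insertion")
  titv <- spectrum_table(
    snvs$cohort, ifelse(is_transition(snvs$ref, snvs$alt),
                        "transition", "transversion"), cohorts)
  delins <- spectrum_table(indels$cohort, indels$indel_type, cohorts)
  svtab <- spectrum_table(sv$consensus$cohort,
                          sv$consensus$svtype, cohorts,
                          levels = c("DEL", "DUP"))
  spectra_tests <- dplyr::bind_rows(
    safe_chi("transition_transversion", titv),
    safe_chi("deletion_insertion", delins),
    safe_chi("sv_del_dup", svtab)
  )

  ks_tests <- dplyr::bind_rows(
    safe_ks("indel_size", indels$indel_len[indels$cohort == cohorts[1]],
            indels$indel_len[indels$cohort == cohorts[2]]),
    safe_ks("sv_size", sv$consensus$length[sv$consensus$cohort == cohorts[1]],
            sv$consensus$length[sv$consensus$cohort == cohorts[2]])
  )

  # --- signature analysis (per-cohort fit, per-mutation assignment)
  sig <- signature_analysis(snvs, bundle$genome, bundle$signature_matrix,
                            cohorts, min_families)

  # --- endpoint comparisons
  endpoints <- c("n_snv", "n_indel", "n_paternal", "n_sv",
                 "n_clusters_lt10", "n_clusters_lt100")
  endpoint_tests <- purrr::map_dfr(endpoints, function(ep) {
    groups <- split(per_family[[ep]], per_family$cohort)
    dplyr::mutate(kruskal_wallis(groups), endpoint = ep, .before = 1)
  })
  endpoint_tests$p_adj <- holm_adjust(endpoint_tests$p)

  rates <- tidyr::expand_grid(endpoint = endpoints, cohort = cohorts) |>
    purrr::pmap_dfr(function(endpoint, cohort) {
      counts <- per_family[[endpoint]][per_family$cohort == cohort]
      dplyr::mutate(rate_with_ci(counts, seed = seed),
                    endpoint = endpoint, cohort = cohort, .before = 1)
    })

  # --- NB exposure regression on the SNV endpoint
  reg_data <- dplyr::left_join(per_family, bundle$covariates,
                               by = c("family_id", "cohort"))
  reg_data$exposed <- as.integer(reg_data$cohort == cohorts[2])
  confs <- intersect(c("paternal_age_conception", "child_age_sampling",
                       "smoker", "alcohol"), names(reg_data))
  nb <- tryCatch(
    nb_regression(reg_data, "n_snv", "exposed", confounders = confs,
                  priority = confs),
    error = function(e) NULL
  )

  structure(list(
    pedigree = ped,
    dnm_calls = dnm_calls,
    filter_summary = filter_summary,
    sv_consensus = sv$consensus,
    sv_counts = sv$counts,
    clusters_lt10 = clusters10,
    clusters_lt100 = clusters100,
    per_family = per_family,
    spectra_tables = list(transition_transversion = titv,
                          deletion_insertion = delins, sv_del_dup = svtab),
    spectra_tests = spectra_tests,
    ks_tests = ks_tests,
    signatures = sig,
    endpoint_tests = endpoint_tests,
    rates = rates,
    nb_regression = nb,
    chromosome_counts = per_chromosome_counts(dnm_calls, sv$consensus)
  ), class = "study_tables")
}

spectrum_table <- function(cohort, type, cohorts, levels = NULL) {
  levels <- levels %||% sort(unique(type))
  m <- table(factor(cohort, levels = cohorts),
             factor(type, levels = levels))
  matrix(as.integer(m), nrow = 2, dimnames = dimnames(m))
}

safe_chi <- function(endpoint, tab) {
  res <- tryCatch(chi_square_2x2(tab), error = function(e) {
    test_result("chi-square", NA_real_, 1, NA_real_)
  })
  dplyr::mutate(res, endpoint = endpoint, .before = 1)
}

safe_ks <- function(endpoint, a, b) {
  res <- tryCatch(ks_two_sample(a, b), error = function(e) {
    test_result("kolmogorov-smirnov", NA_real_, NA_real_, NA_real_)
  })
  dplyr::mutate(res, endpoint = endpoint, .before = 1)
}

# Catalogues, per-cohort NNLS fits, per-mutation assignment, cohort
# comparison and per-family Williams tests for eligible signatures.
signature_analysis <- function(snvs, genome, signature_matrix, cohorts,
                               min_families) {
  if (nrow(snvs) == 0) {
    return(list(catalogues = list(), exposures = list(),
                assignments = snvs, comparison = tibble::tibble(),
                eligible = character(0), williams = tibble::tibble()))
  }
  catalogues <- lapply(setNames(cohorts, cohorts), function(co) {
    build_catalogue(snvs[snvs$cohort == co, , drop = FALSE], genome,
                    owner = co)
  })
  exposures <- lapply(catalogues, fit_exposures,
                      signature_matrix = signature_matrix)
  assignments <- dplyr::bind_rows(lapply(cohorts, function(co) {
    sub <- snvs[snvs$cohort == co, , drop = FALSE]
    if (nrow(sub) == 0) return(sub)
    assign_mutations(sub, exposures[[co]], signature_matrix, genome = genome)
  }))
  counts_by <- function(co) {
    tab <- assignments[assignments$cohort == co & assignments$signature != "unassigned", ]
    tapply(rep(1L, nrow(tab)), tab$signature, sum)
  }
  ca <- counts_by(cohorts[1])
  cb <- counts_by(cohorts[2])
  comparison <- compare_cohort_signatures(
    setNames(as.integer(ca), names(ca)),
    setNames(as.integer(cb), names(cb)), labels = cohorts)
  eligible <- families_with_signature(assignments, min_families)

  totals <- assignments |>
    dplyr::count(.data$family_id, .data$cohort, name = "total")
  williams <- purrr::map_dfr(eligible, function(s) {
    succ <- assignments |>
      dplyr::filter(.data$signature == s) |>
      dplyr::count(.data$family_id, name = "successes")
    dat <- dplyr::left_join(totals, succ, by = "family_id") |>
      dplyr::mutate(successes = dplyr::coalesce(.data$successes, 0L))
    fit <- williams_binomial(dat$successes, dat$total, dat$cohort)
    dplyr::mutate(tidy(fit), signature = s, phi = fit$phi, .before = 1)
  })
  list(catalogues = catalogues, exposures = exposures,
       assignments = assignments, comparison = comparison,
       eligible = eligible, williams = williams)
}

# Read a study bundle written by simulate_study(config, dir = ...).
read_bundle <- function(dir) {
  ped <- read_pedigree(file.path(dir, "families.ped"))
  covariates <- read_covariates(file.path(dir, "covariates.tsv"))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  signature_matrix <- read_signature_matrix(file.path(dir, "signatures.tsv"))
  variants <- purrr::map_dfr(seq_len(nrow(ped)), function(i) {
    path <- file.path(dir, "trios", paste0(ped$family_id[i], ".vcf"))
    v <- read_trio_vcf(path, ped[i, ])
    v$family_id <- ped$family_id[i]
    v
  })
  sv_dir <- file.path(dir, "sv")
  callers <- list.dirs(sv_dir, recursive = FALSE, full.names = FALSE)
  sv_calls <- purrr::map_dfr(callers, function(cl) {
    purrr::map_dfr(ped$family_id, function(fam) {
      path <- file.path(sv_dir, cl, paste0(fam, ".vcf"))
      if (!file.exists(path)) return(NULL)
      read_sv_vcf(path, caller = cl, family_id = fam)
    })
  })
  list(pedigree = ped, covariates = covariates, variants = variants,
       sv_calls = sv_calls, genome = genome,
       signature_matrix = signature_matrix)
}

#' @export
print.study_tables <- function(x, ...) {
  cat("Trio DNM study\n")
  cat(sprintf("  families: %d (%s)\n", nrow(x$pedigree),
              paste(sprintf("%s: %d", names(table(x$pedigree$cohort)),
                            table(x$pedigree$cohort)), collapse = ", ")))
  cat(sprintf("  accepted DNMs: %d SNVs, %d indels\n",
              sum(x$dnm_calls$vclass == "SNV"),
              sum(x$dnm_calls$vclass == "indel")))
  cat(sprintf("  consensus SVs: %d\n", nrow(x$sv_consensus)))
  cat("  endpoint tests (Kruskal-Wallis, Holm-adjusted):\n")
  print(x$endpoint_tests[, c("endpoint", "statistic", "p", "p_adj")])
  invisible(x)
}

#' @exportS3Method generics::glance
glance.study_tables <- function(x, ...) {
  tibble::tibble(
    n_families = nrow(x$pedigree),
    n_snv = sum(x$dnm_calls$vclass == "SNV"),
    n_indel = sum(x$dnm_calls$vclass == "indel"),
    n_sv = nrow(x$sv_consensus),
    n_clusters_lt10 = nrow(x$clusters_lt10),
    n_clusters_lt100 = nrow(x$clusters_lt100),
    min_endpoint_p_adj = suppressWarnings(min(x$endpoint_tests$p_adj,
                                              na.rm = TRUE))
  )
}
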
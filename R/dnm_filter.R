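# Candidate de novo SNV/indel filter cascade: annotation retention,
# Mendelian-violation requirement, parental-evidence rules and genotype
# quality, with stagewise bookkeeping.

#' Filter thresholds for the candidate DNM cascade
#'
#' Defaults mirror the study design: parents may show at most 1 read
#' supporting the alternate allele, parental depth must reach 7, the child
#' needs 3 alternate reads, genotype quality must be 99 for the child
#' (the caller cap) and at least 50 for both parents; variants in
#' segmental-duplication/repeat regions are excluded. The annotation stage
#' (population frequency / deleteriousness / exonic region) is off for the
#' genome-wide endpoint and can be switched to disjunctive ("any") or
#' conjunctive ("all") retention for functional sub-analyses.
#'
#' @param max_pop_af Maximum population allele frequency for retention.
#' @param min_deleterious_votes Minimum count of deleteriousness predictions.
#' @param annotation_mode One of "off", "any", "all".
#' @param max_parent_alt_reads Maximum alt-supporting reads in each parent.
#' @param min_parent_dp Minimum depth in each parent.
#' @param min_child_alt_reads Minimum alt-supporting reads in the child.
#' @param child_min_gq,parent_min_gq Genotype-quality thresholds.
#' @param exclude_repeats Drop variants flagged as repeat-region.
#' @param rescue_cohort_mv Retain variants carrying an upstream cohort-mode
#'   Mendelian-violation flag even when the per-trio genotypes alone do not
#'   show a violation (coverage rules still apply).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_pop_af = 0.01, min_deleterious_votes = 2,
                          annotation_mode = c("off", "any", "all"),
                          max_parent_alt_reads = 1, min_parent_dp = 7,
                          min_child_alt_reads = 3, child_min_gq = 99,
                          parent_min_gq = 50, exclude_repeats = TRUE,
                          rescue_cohort_mv = FALSE) {
  annotation_mode <- match.arg(annotation_mode)
  cfg <- list(max_pop_af = max_pop_af,
              min_deleterious_votes = min_deleterious_votes,
              annotation_mode = annotation_mode,
              max_parent_alt_reads = max_parent_alt_reads,
              min_parent_dp = min_parent_dp,
              min_child_alt_reads = min_child_alt_reads,
              child_min_gq = child_min_gq, parent_min_gq = parent_min_gq,
              exclude_repeats = exclude_repeats,
              rescue_cohort_mv = rescue_cohort_mv)
  nums <- unlist(cfg[c("max_pop_af", "min_deleterious_votes",
                       "max_parent_alt_reads", "min_parent_dp",
                       "min_child_alt_reads", "child_min_gq",
                       "parent_min_gq")])
  if (any(nums < 0)) abort("filter thresholds must be non-negative")
  structure(cfg, class = "filter_config")
}

#' Is a trio genotype configuration a Mendelian violation?
#'
#' A violation means the child's diploid genotype cannot be formed by taking
#' one allele from the father and one from the mother. The canonical de novo
#' configuration is child heterozygous with both parents homozygous
#' reference. Any missing genotype gives `FALSE` (fail-closed: de novo
#' status cannot be verified).
#'
#' @param father_gt,mother_gt,child_gt Diploid genotype strings
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`; `|` separators accepted).
#' @return Logical vector.
#' @export
is_mendelian_violation <- function(father_gt, mother_gt, child_gt) {
  f <- gt_allele_matrix(father_gt)
  m <- gt_allele_matrix(mother_gt)
  c_ <- gt_allele_matrix(child_gt)
  n <- max(nrow(f), nrow(m), nrow(c_))
  out <- logical(n)
  for (i in seq_len(n)) {
    fi <- f[min(i, nrow(f)), ]
    mi <- m[min(i, nrow(m)), ]
    ci <- c_[min(i, nrow(c_)), ]
    if (anyNA(c(fi, mi, ci))) {
      out[i] <- FALSE
      next
    }
    compatible <- (ci[1] %in% fi && ci[2] %in% mi) ||
      (ci[2] %in% fi && ci[1] %in% mi)
    out[i] <- !compatible
  }
  out
}

#' Annotation-based retention decision
#'
#' Under mode `"any"` a variant is retained if it is rare
#' (`pop_af < max_pop_af`), predicted deleterious by at least
#' `min_deleterious_votes` tools, or falls in an exon/splice region; under
#' `"all"` all three must hold (missing fields fail); under `"off"` every
#' variant is retained. Missing fields under `"any"` simply cannot rescue.
#'
#' @param variants Tibble with `pop_af`, `deleterious_votes`, `region`.
#' @param config A [filter_config()].
#' @return Tibble with columns `retained` (logical) and `reason`.
#' @export
annotation_retention <- function(variants, config = filter_config()) {
  n <- nrow(variants)
  if (config$annotation_mode == "off") {
    return(tibble::tibble(retained = rep(TRUE, n),
                          reason = rep(NA_character_, n)))
  }
  af_ok <- !is.na(variants$pop_af) & variants$pop_af < config$max_pop_af
  votes_ok <- !is.na(variants$deleterious_votes) &
    variants$deleterious_votes >= config$min_deleterious_votes
  region_ok <- !is.na(variants$region) & variants$region == "exon_splice"
  retained <- if (config$annotation_mode == "any") {
    af_ok | votes_ok | region_ok
  } else {
    af_ok & votes_ok & region_ok
  }
  tibble::tibble(retained = retained,
                 reason = ifelse(retained, NA_character_, "annotation"))
}

#' Parental-evidence candidate filter
#'
#' Retains a variant iff (when repeat exclusion is on) it is not in a
#' repeat region, neither parent has more than `max_parent_alt_reads`
#' alt-supporting reads, both parents reach `min_parent_dp` depth, and the
#' child shows at least `min_child_alt_reads` alt reads. The reason names
#' the first failed rule in that order.
#'
#' @param variants Trio-variant tibble.
#' @param config A [filter_config()].
#' @return Tibble with `retained` and `reason` columns.
#' @export
dnm_candidate_filter <- function(variants, config = filter_config()) {
  reason <- rep(NA_character_, nrow(variants))
  fail <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  if (isTRUE(config$exclude_repeats)) {
    fail(dplyr::coalesce(variants$in_repeat, FALSE), "repeat region")
  }
  parent_alt_bad <- dplyr::coalesce(variants$father_alt, Inf) > config$max_parent_alt_reads |
    dplyr::coalesce(variants$mother_alt, Inf) > config$max_parent_alt_reads
  fail(parent_alt_bad, "parental alt reads")
  parent_dp_bad <- dplyr::coalesce(variants$father_dp, -Inf) < config$min_parent_dp |
    dplyr::coalesce(variants$mother_dp, -Inf) < config$min_parent_dp
  fail(parent_dp_bad, "parental depth")
  fail(dplyr::coalesce(variants$child_alt, -Inf) < config$min_child_alt_reads,
       "child alt reads")
  tibble::tibble(retained = is.na(reason), reason = reason)
}

#' Genotype-quality filter
#'
#' Retains a variant iff the child genotype quality reaches
#' `child_min_gq` (99, the caller cap) and both parents reach
#' `parent_min_gq` (50). Missing quality values fail.
#'
#' @inheritParams dnm_candidate_filter
#' @return Tibble with `retained` and `reason` columns.
#' @export
genotype_quality_filter <- function(variants, config = filter_config()) {
  child_ok <- dplyr::coalesce(variants$child_gq, -Inf) >= config$child_min_gq
  parent_ok <- dplyr::coalesce(variants$father_gq, -Inf) >= config$parent_min_gq &
    dplyr::coalesce(variants$mother_gq, -Inf) >= config$parent_min_gq
  retained <- child_ok & parent_ok
  tibble::tibble(retained = retained,
                 reason = dplyr::case_when(retained ~ NA_character_,
                                           !child_ok ~ "child GQ",
                                           TRUE ~ "parental GQ"))
}

#' Run the full candidate DNM cascade for one trio
#'
#' Applies, in order: annotation retention (when enabled), the
#' Mendelian-violation requirement (with optional cohort-mode rescue),
#' the parental-evidence candidate filter and the genotype-quality filter.
#' The stage summary reports retained counts after every stage for SNVs and
#' indels separately; counts are non-increasing along the cascade.
#'
#' @param variants Trio-variant tibble for one family.
#' @param pedigree One-row pedigree tibble giving `family_id` and `cohort`.
#' @param config A [filter_config()].
#' @return A list with `calls` (accepted DNM tibble: family, cohort, locus,
#'   alleles, class, origin, per-sample metrics) and `summary` (tibble of
#'   stage x variant-class retained counts).
#' @export
run_dnm_cascade <- function(variants, pedigree, config = filter_config()) {
  stages <- c("input", "annotation", "mendelian", "candidate", "genotype_quality")
  keep <- rep(TRUE, nrow(variants))
  counts <- list()
  tally <- function(stage, keep) {
    tibble::tibble(
      stage = stage,
      snv = sum(keep & variants$vclass == "SNV"),
      indel = sum(keep & variants$vclass == "indel")
    )
  }
  counts[[1]] <- tally("input", keep)

  keep <- keep & annotation_retention(variants, config)$retained
  counts[[2]] <- tally("annotation", keep)

  mv <- is_mendelian_violation(variants$father_gt, variants$mother_gt,
                               variants$child_gt)
  if (isTRUE(config$rescue_cohort_mv) && "mv_cohort_flag" %in% names(variants)) {
    mv <- mv | dplyr::coalesce(variants$mv_cohort_flag, FALSE)
  }
  keep <- keep & mv
  counts[[3]] <- tally("mendelian", keep)

  keep <- keep & dnm_candidate_filter(variants, config)$retained
  counts[[4]] <- tally("candidate", keep)

  keep <- keep & genotype_quality_filter(variants, config)$retained
  counts[[5]] <- tally("genotype_quality", keep)

  calls <- variants[keep, , drop = FALSE]
  calls$family_id <- pedigree$family_id[[1]]
  calls$cohort <- pedigree$cohort[[1]]
  if (!"origin" %in% names(calls)) calls$origin <- "unknown"
  calls$origin <- dplyr::coalesce(calls$origin, "unknown")
  front <- c("family_id", "cohort", "chrom", "pos", "ref", "alt", "vclass",
             "origin")
  calls <- calls[, c(front, setdiff(names(calls), front))]
  summary <- dplyr::bind_rows(counts)
  summary$stage <- factor(summary$stage, levels = stages)
  list(calls = tibble::as_tibble(calls), summary = summary)
}
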
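# Multi-caller de novo structural-variant consensus: breakpoint-distance
# merging at a ladder of ranges (SURVIVOR-style single linkage), strand and
# size-dependent caller-support rules, multi-range consistency and a
# cross-pedigree artifact filter.

#' Configuration for the SV consensus procedure
#'
#' @param merge_ranges Breakpoint-distance ladder (bp), descending.
#' @param canonical_range Range whose consensus coordinates are reported and
#'   at which the cross-pedigree filter operates.
#' @param min_consistent_ranges Minimum number of merge ranges (canonical
#'   included) at which an event must be recovered.
#' @param cross_pedigree_range Breakpoint distance for the multi-family
#'   artifact test.
#' @param length_ratio Maximum relative length difference
#'   (`|len1-len2| / max(len1, len2)`) for two families' events to count as
#'   the same artifact.
#' @param strict_support Use the alternative final filter: at least 5
#'   supporting callers regardless of type and size.
#' @param min_sv_length Minimum event length for consensus candidacy.
#' @return A list of class `merge_config`.
#' @export
merge_config <- function(merge_ranges = c(1000, 500, 250, 150, 50, 25, 10),
                         canonical_range = 50, min_consistent_ranges = 2,
                         cross_pedigree_range = 50, length_ratio = 0.10,
                         strict_support = FALSE, min_sv_length = 100) {
  if (any(merge_ranges <= 0) || is.unsorted(rev(merge_ranges), strictly = TRUE)) {
    abort("merge_ranges must be positive and strictly descending")
  }
  if (!canonical_range %in% merge_ranges) {
    abort("canonical_range must be one of merge_ranges")
  }
  structure(list(merge_ranges = merge_ranges,
                 canonical_range = canonical_range,
                 min_consistent_ranges = min_consistent_ranges,
                 cross_pedigree_range = cross_pedigree_range,
                 length_ratio = length_ratio,
                 strict_support = strict_support,
                 min_sv_length = min_sv_length),
            class = "merge_config")
}

#' Merge SV calls at one breakpoint distance
#'
#' Two calls belong to the same cluster iff they share chromosome and SV
#' type and both breakpoints lie within `d` bp (`|start1-start2| <= d` and
#' `|end1-end2| <= d`), extended by single-linkage transitive closure.
#' The representative interval is the per-coordinate median of the members;
#' support counts distinct callers, never calls.
#'
#' @param calls Tidy SV call tibble (one family): `chrom`, `start`, `end`,
#'   `svtype`, `caller`, `plus_reads`, `minus_reads`.
#' @param d Merge distance in bp.
#' @return Consensus tibble with `start`, `end`, `length`, `support`,
#'   `callers` (list column), summed strand reads and `n_calls`.
#' @export
merge_at_range <- function(calls, d) {
  if (d <= 0) abort("merge distance must be positive")
  if (nrow(calls) == 0) return(empty_consensus())
  fam <- if ("family_id" %in% names(calls)) calls$family_id else ""
  groups <- split(seq_len(nrow(calls)),
                  paste(fam, calls$chrom, calls$svtype, sep = "\r"))
  out <- lapply(groups, function(idx) {
    sub <- calls[idx, , drop = FALSE]
    ord <- order(sub$start, sub$end, sub$caller)
    sub <- sub[ord, , drop = FALSE]
    n <- nrow(sub)
    parent <- uf_new(n)
    for (i in seq_len(n)) {
      j <- i + 1L
      # calls are start-sorted, so the scan can stop once starts diverge
      while (j <= n && sub$start[j] - sub$start[i] <= d) {
        if (abs(sub$end[i] - sub$end[j]) <= d) parent <- uf_union(parent, i, j)
        j <- j + 1L
      }
    }
    comp <- uf_components(parent)
    sub$cluster <- comp
    sub |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        family_id = dplyr::first(if ("family_id" %in% names(sub)) .data$family_id else NA_character_),
        chrom = dplyr::first(.data$chrom),
        svtype = dplyr::first(.data$svtype),
        start = as.integer(round(median(.data$start))),
        end = as.integer(round(median(.data$end))),
        support = dplyr::n_distinct(.data$caller),
        callers = list(sort(unique(.data$caller))),
        plus_reads = sum(.data$plus_reads),
        minus_reads = sum(.data$minus_reads),
        n_calls = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::select(-"cluster")
  })
  res <- dplyr::bind_rows(out)
  res$length <- res$end - res$start
  res <- dplyr::arrange(res, .data$family_id, .data$chrom, .data$svtype,
                        .data$start, .data$end)
  res[, c("family_id", "chrom", "svtype", "start", "end", "length",
          "support", "callers", "plus_reads", "minus_reads", "n_calls")]
}

empty_consensus <- function() {
  tibble::tibble(family_id = character(), chrom = character(),
                 svtype = character(), start = integer(), end = integer(),
                 length = integer(), support = integer(), callers = list(),
                 plus_reads = integer(), minus_reads = integer(),
                 n_calls = integer())
}

#' Strand and caller-support filter for consensus SVs
#'
#' An event needs read support on both strands, plus the size-dependent
#' caller-support rule: deletions need 6 callers, or 4 if at most 300 bp;
#' duplications need 5, or 4 if at most 1500 bp. Insertions and inversions
#' are held to the duplication rule. Under `strict_support`, the rule is a
#' flat minimum of 5 callers for every type.
#'
#' @param consensus Consensus tibble from [merge_at_range()].
#' @param config A [merge_config()].
#' @return Tibble with `retained` and `reason` columns.
#' @export
support_filter <- function(consensus, config = merge_config()) {
  known <- c("DEL", "DUP", "INS", "INV")
  if (nrow(consensus) > 0 && !all(consensus$svtype %in% known)) {
    abort(sprintf("unknown svtype: %s",
                  paste(setdiff(unique(consensus$svtype), known), collapse = ", ")))
  }
  strand_ok <- consensus$plus_reads >= 1 & consensus$minus_reads >= 1
  support_ok <- if (isTRUE(config$strict_support)) {
    consensus$support >= 5
  } else {
    ifelse(consensus$svtype == "DEL",
           consensus$support >= 6 |
             (consensus$support >= 4 & consensus$length <= 300),
           consensus$support >= 5 |
             (consensus$support >= 4 & consensus$length <= 1500))
  }
  retained <- strand_ok & support_ok
  tibble::tibble(retained = retained,
                 reason = dplyr::case_when(retained ~ NA_character_,
                                           !strand_ok ~ "strand support",
                                           TRUE ~ "caller support"))
}

#' Require recovery of an event at multiple merge ranges
#'
#' A canonical-range consensus event is retained iff a same-type consensus
#' with reciprocal overlap of at least 50% exists at
#' `min_consistent_ranges` or more of the merge ranges (the canonical range
#' counts as one of them). The ranges where the event was recovered are
#' recorded in a `ranges_detected` list column.
#'
#' @param per_range Named list of consensus tibbles, names = merge ranges
#'   (as produced at each distance for one family or several).
#' @param config A [merge_config()].
#' @return The canonical consensus tibble filtered to consistent events.
#' @export
multi_range_consistency <- function(per_range, config = merge_config()) {
  canon_name <- as.character(config$canonical_range)
  if (!canon_name %in% names(per_range)) {
    abort("per_range must contain the canonical range")
  }
  canon <- per_range[[canon_name]]
  if (nrow(canon) == 0) {
    canon$ranges_detected <- list()
    return(canon)
  }
  detected <- lapply(seq_len(nrow(canon)), function(i) {
    hit <- vapply(names(per_range), function(rg) {
      other <- per_range[[rg]]
      any(same_event(canon[i, ], other))
    }, logical(1))
    sort(as.numeric(names(per_range)[hit]), decreasing = TRUE)
  })
  canon$ranges_detected <- detected
  keep <- vapply(detected, length, integer(1)) >= config$min_consistent_ranges
  canon[keep, , drop = FALSE]
}

# Reciprocal-overlap >= 50% match of one event against a consensus table,
# respecting family, chromosome and type.
same_event <- function(ev, other) {
  if (nrow(other) == 0) return(logical(0))
  cand <- other$family_id == ev$family_id & other$chrom == ev$chrom &
    other$svtype == ev$svtype
  ov <- pmin(ev$end, other$end) - pmax(ev$start, other$start)
  ro <- ov / pmax(ev$length, other$length)
  cand & ov > 0 & ro >= 0.5
}

#' Discard events recurring across pedigrees
#'
#' A de novo SV seen in more than one family at the same locus is treated
#' as a shared artifact (or inherited variant leaking through) rather than
#' a true de novo event: if another family carries a same-type event whose
#' start and end are each within `cross_pedigree_range` bp and whose length
#' differs by at most `length_ratio` (relative to the longer event), all
#' matching families' events are discarded.
#'
#' @param consensus Combined canonical consensus tibble across families.
#' @param config A [merge_config()].
#' @return The consensus tibble with recurrent events removed.
#' @export
cross_pedigree_filter <- function(consensus, config = merge_config()) {
  n <- nrow(consensus)
  if (n <= 1) return(consensus)
  drop <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (consensus$family_id[i] == consensus$family_id[j]) next
      if (consensus$chrom[i] != consensus$chrom[j]) next
      if (consensus$svtype[i] != consensus$svtype[j]) next
      if (abs(consensus$start[i] - consensus$start[j]) > config$cross_pedigree_range) next
      if (abs(consensus$end[i] - consensus$end[j]) > config$cross_pedigree_range) next
      lr <- abs(consensus$length[i] - consensus$length[j]) /
        max(consensus$length[i], consensus$length[j])
      if (lr <= config$length_ratio) {
        drop[i] <- TRUE
        drop[j] <- TRUE
      }
    }
  }
  consensus[!drop, , drop = FALSE]
}

#' Run the full multi-caller SV consensus
#'
#' Composition of the four stages for every family: merge at each range of
#' the ladder, strand/caller-support filtering at the canonical range,
#' multi-range consistency, and the cross-pedigree filter. The result is
#' deterministic under permutation of the input calls.
#'
#' @param calls Tidy SV call tibble across all callers and families
#'   (e.g. row-bound [read_sv_vcf()] outputs).
#' @param pedigree Pedigree tibble supplying cohort labels.
#' @param config A [merge_config()].
#' @return List with `consensus` (retained events, with `cohort` joined) and
#'   `counts` (cohort x svtype tally of retained events).
#' @export
run_sv_consensus <- function(calls, pedigree, config = merge_config()) {
  calls <- calls[calls$end - calls$start >= config$min_sv_length, , drop = FALSE]
  per_range <- lapply(config$merge_ranges, function(d) merge_at_range(calls, d))
  names(per_range) <- as.character(config$merge_ranges)

  canon <- per_range[[as.character(config$canonical_range)]]
  dec <- support_filter(canon, config)
  per_range[[as.character(config$canonical_range)]] <-
    canon[dec$retained, , drop = FALSE]

  consistent <- multi_range_consistency(per_range, config)
  final <- cross_pedigree_filter(consistent, config)
  final <- dplyr::left_join(final,
                            pedigree[, c("family_id", "cohort")],
                            by = "family_id")
  counts <- final |>
    dplyr::count(.data$cohort, .data$svtype, name = "n") |>
    tidyr::complete(cohort = unique(pedigree$cohort),
                    svtype = c("DEL", "DUP", "INS", "INV"),
                    fill = list(n = 0L))
  list(consensus = tibble::as_tibble(final), counts = counts)
}
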
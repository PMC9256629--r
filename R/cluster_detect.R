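# Clustered de novo mutation detection at short genomic windows and
# per-chromosome distribution summaries.

#' Detect clustered de novo mutations
#'
#' Within one offspring, a cluster is a maximal run of same-chromosome
#' calls in which every consecutive pair is strictly less than `window` bp
#' apart (single-linkage on position differences). SNVs and indels are both
#' eligible; a cluster needs at least two members. Each call belongs to at
#' most one cluster per window.
#'
#' @param dnms DNM call tibble with `family_id`, `chrom`, `pos` (one or
#'   several families; clustering is per family).
#' @param window Window size in bp, conventionally 10 or 100.
#' @return Cluster-level tibble: `family_id`, `chrom`, `cluster_id`,
#'   `n_members`, `span`, `start`, `end`, `window_class` and a `members`
#'   list column of positions.
#' @export
detect_clusters <- function(dnms, window = 10) {
  if (window <= 0) abort("window must be positive")
  wclass <- paste0("lt", window)
  if (nrow(dnms) == 0) return(empty_clusters(wclass))
  res <- dnms |>
    dplyr::arrange(.data$family_id, .data$chrom, .data$pos) |>
    dplyr::group_by(.data$family_id, .data$chrom) |>
    dplyr::mutate(run = cumsum(c(1L, as.integer(diff(.data$pos) >= window)))) |>
    dplyr::group_by(.data$family_id, .data$chrom, .data$run) |>
    dplyr::summarise(n_members = dplyr::n(),
                     start = min(.data$pos), end = max(.data$pos),
                     members = list(.data$pos), .groups = "drop") |>
    dplyr::filter(.data$n_members >= 2) |>
    dplyr::mutate(span = .data$end - .data$start, window_class = wclass) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(cluster_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("family_id", "chrom", "cluster_id", "n_members", "span",
                  "start", "end", "window_class", "members")
  res
}

empty_clusters <- function(wclass) {
  tibble::tibble(family_id = character(), chrom = character(),
                 cluster_id = integer(), n_members = integer(),
                 span = integer(), start = integer(), end = integer(),
                 window_class = character(), members = list())
}

#' Count clusters per offspring
#'
#' Convenience tally for the per-offspring clustered-mutation endpoint:
#' number of cluster events (not pairs) per family at one window.
#'
#' @inheritParams detect_clusters
#' @param families Optional character vector of family ids so that
#'   zero-cluster offspring appear with count 0.
#' @return Tibble `family_id`, `n_clusters`.
#' @export
cluster_counts <- function(dnms, window = 10, families = NULL) {
  cl <- detect_clusters(dnms, window)
  counts <- dplyr::count(cl, .data$family_id, name = "n_clusters")
  families <- families %||% unique(dnms$family_id)
  tibble::tibble(family_id = families) |>
    dplyr::left_join(counts, by = "family_id") |>
    dplyr::mutate(n_clusters = dplyr::coalesce(.data$n_clusters, 0L))
}

#' Per-chromosome mutation counts by cohort
#'
#' @param dnms DNM call tibble with `cohort`, `chrom`, `vclass`.
#' @param svs Optional consensus SV tibble with `cohort`, `chrom`; counted
#'   under class "SV".
#' @return Long tibble `cohort`, `chrom`, `vclass`, `n`; total equals the
#'   number of input records.
#' @export
per_chromosome_counts <- function(dnms, svs = NULL) {
  base <- dnms[, c("cohort", "chrom", "vclass")]
  if (!is.null(svs) && nrow(svs) > 0) {
    base <- dplyr::bind_rows(base,
                             tibble::tibble(cohort = svs$cohort,
                                            chrom = svs$chrom,
                                            vclass = "SV"))
  }
  if (nrow(base) == 0) {
    return(tibble::tibble(cohort = character(), chrom = character(),
                          vclass = character(), n = integer()))
  }
  dplyr::count(base, .data$cohort, .data$chrom, .data$vclass, name = "n") |>
    dplyr::arrange(.data$cohort, .data$chrom, .data$vclass)
}
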
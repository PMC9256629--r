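# 96-channel trinucleotide catalogues, non-negative least-squares signature
# fitting against a reference matrix, one-signature-per-mutation assignment
# and the cohort-level signature comparisons.

#' Canonical SBS 96-channel labels
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' base, then 3' base, on the pyrimidine-centred strand —
#' the ordering used by the COSMIC reference catalogues.
#'
#' @return Character vector of 96 labels like `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

#' Classify a substitution into its 96-channel context
#'
#' Takes the reference trinucleotide centred on the mutated base and the
#' alternate base; purine-centred mutations are reverse-complemented to the
#' pyrimidine strand before lookup, so the two strand representations of a
#' mutation map to the same channel.
#'
#' @param ref_triplet Character vector of 3-base reference contexts (ACGT).
#' @param alt_base Alternate base, same length.
#' @return Integer channel indices into [sbs96_channels()], with the labels
#'   as names.
#' @export
classify_context <- function(ref_triplet, alt_base) {
  ref_triplet <- toupper(ref_triplet)
  alt_base <- toupper(alt_base)
  if (any(nchar(ref_triplet) != 3)) abort("ref_triplet must have 3 bases")
  if (any(!grepl("^[ACGT]{3}$", ref_triplet)) ||
      any(!grepl("^[ACGT]$", alt_base))) {
    abort("ref_triplet and alt_base must be ACGT only")
  }
  mid <- substr(ref_triplet, 2, 2)
  if (any(mid == alt_base)) abort("alt base equals the reference base")
  flip <- mid %in% c("A", "G")
  trip <- ifelse(flip, revcomp(ref_triplet), ref_triplet)
  alt <- ifelse(flip, dna_complement(alt_base), alt_base)
  label <- paste0(substr(trip, 1, 1), "[", substr(trip, 2, 2), ">", alt, "]",
                  substr(trip, 3, 3))
  idx <- match(label, sbs96_channels())
  setNames(idx, label)
}

#' Build a 96-channel catalogue from SNV calls
#'
#' Looks up each SNV's flanking bases in the reference genome, classifies
#' the substitution to its pyrimidine-centred channel and tallies. Indels
#' are ignored; SNVs at contig edges (no flanking base) are skipped with a
#' logged count. A mismatch between a call's `ref` allele and the genome is
#' an error.
#'
#' @param dnms DNM call tibble with `chrom`, `pos`, `ref`, `alt`, `vclass`.
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA) whose
#'   names match `chrom`.
#' @param owner Label recorded on the catalogue (sample/family/cohort).
#' @return A tibble of class `catalogue96` with columns `channel` (all 96,
#'   canonical order) and `count`; the sum equals the number of classified
#'   SNVs.
#' @export
build_catalogue <- function(dnms, genome, owner = "sample") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  snv <- dnms[dnms$vclass == "SNV", , drop = FALSE]
  counts <- setNames(rep(0L, 96), sbs96_channels())
  skipped <- 0L
  if (nrow(snv) > 0) {
    lens <- Biostrings::width(genome)[match(snv$chrom, names(genome))]
    edge <- snv$pos <= 1 | snv$pos >= lens
    skipped <- sum(edge)
    if (skipped > 0) {
      message(sprintf("build_catalogue: skipped %d call(s) at contig edges", skipped))
    }
    snv <- snv[!edge, , drop = FALSE]
    if (nrow(snv) > 0) {
      trip <- as.character(Biostrings::subseq(
        genome[snv$chrom], start = snv$pos - 1L, end = snv$pos + 1L))
      if (any(substr(trip, 2, 2) != snv$ref)) {
        abort("reference allele does not match the genome sequence")
      }
      idx <- classify_context(trip, snv$alt)
      tab <- table(factor(names(idx), levels = sbs96_channels()))
      counts <- counts + as.integer(tab)
      counts <- setNames(as.integer(counts), sbs96_channels())
    }
  }
  structure(tibble::tibble(channel = sbs96_channels(), count = unname(counts)),
            class = c("catalogue96", "tbl_df", "tbl", "data.frame"),
            owner = owner, skipped = skipped)
}

catalogue_vector <- function(catalogue) {
  if (inherits(catalogue, "data.frame")) {
    setNames(catalogue$count, catalogue$channel)[sbs96_channels()]
  } else {
    catalogue[sbs96_channels()]
  }
}

#' Fit non-negative signature exposures to a catalogue
#'
#' Solves `min || M e - c ||_2` subject to `e >= 0` (Lawson-Hanson
#' active-set non-negative least squares), where `M` is the reference
#' signature matrix and `c` the observed 96-channel catalogue. The fit is
#' deterministic and unregularised.
#'
#' @param catalogue A `catalogue96` tibble or named 96-vector of counts.
#' @param signature_matrix 96 x S matrix with columns summing to 1
#'   (see [read_signature_matrix()]).
#' @return A tibble of class `exposure_fit`: `signature`, `exposure`, with
#'   the residual L2 norm and total count as attributes (see
#'   [glance.exposure_fit()]).
#' @export
fit_exposures <- function(catalogue, signature_matrix) {
  cvec <- catalogue_vector(catalogue)
  if (anyNA(cvec)) abort("catalogue does not cover the 96 channels")
  M <- signature_matrix[sbs96_channels(), , drop = FALSE]
  if (sum(cvec) == 0) {
    warn("zero catalogue: exposures are all zero")
    e <- rep(0, ncol(M))
    resid <- 0
  } else {
    fit <- pracma::lsqnonneg(M, as.numeric(cvec))
    e <- fit$x
    resid <- sqrt(max(fit$resid.norm, 0))
  }
  structure(tibble::tibble(signature = colnames(M), exposure = e),
            class = c("exposure_fit", "tbl_df", "tbl", "data.frame"),
            residual = resid, total = sum(cvec))
}

#' Assign each mutation to exactly one signature
#'
#' A mutation in channel `k` is assigned to the signature maximising
#' `exposure[s] * M[k, s]` — the posterior-proportional score under the
#' fitted mixture. Ties break to the lowest signature index (column
#' order); channels where every score is zero go to an `"unassigned"`
#' bucket with a logged count.
#'
#' @param dnms SNV call tibble with a `channel` column, or with
#'   `chrom`/`pos`/`ref`/`alt` plus a `genome` to classify on the fly.
#' @param exposures An `exposure_fit` from [fit_exposures()].
#' @param signature_matrix The reference matrix used for the fit.
#' @param genome Optional genome for context lookup when `channel` is
#'   absent.
#' @return The input tibble with a `signature` column appended.
#' @export
assign_mutations <- function(dnms, exposures, signature_matrix, genome = NULL) {
  if (!"channel" %in% names(dnms)) {
    if (is.null(genome)) abort("dnms needs a channel column or a genome")
    if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    trip <- as.character(Biostrings::subseq(genome[dnms$chrom],
                                            start = dnms$pos - 1L,
                                            end = dnms$pos + 1L))
    dnms$channel <- names(classify_context(trip, dnms$alt))
  }
  M <- signature_matrix[sbs96_channels(), , drop = FALSE]
  e <- setNames(exposures$exposure, exposures$signature)[colnames(M)]
  scores <- M * rep(e, each = nrow(M))  # 96 x S: exposure-weighted likelihood
  k <- match(dnms$channel, sbs96_channels())
  best <- apply(scores[k, , drop = FALSE], 1, function(row) {
    if (all(row <= 0)) return(NA_integer_)
    which.max(row)  # ties: first (lowest) index
  })
  sig <- unname(ifelse(is.na(best), "unassigned", colnames(M)[best]))
  n_un <- sum(sig == "unassigned")
  if (n_un > 0) {
    message(sprintf("assign_mutations: %d mutation(s) unassigned (all-zero scores)", n_un))
  }
  dnms$signature <- sig
  dnms
}

#' Signatures eligible for per-family testing
#'
#' Restricts per-family statistical comparison to signatures for which at
#' least `min_families` offspring in each cohort carry at least one
#' assigned mutation.
#'
#' @param assignments Tibble with `family_id`, `cohort`, `signature`.
#' @param min_families Minimum offspring per cohort.
#' @return Character vector of eligible signature labels.
#' @export
families_with_signature <- function(assignments, min_families = 10) {
  if (nrow(assignments) == 0) return(character(0))
  tab <- assignments |>
    dplyr::filter(.data$signature != "unassigned") |>
    dplyr::distinct(.data$signature, .data$cohort, .data$family_id) |>
    dplyr::count(.data$signature, .data$cohort, name = "n_families")
  cohorts <- unique(assignments$cohort)
  tab |>
    dplyr::filter(.data$n_families >= min_families) |>
    dplyr::count(.data$signature, name = "n_cohorts") |>
    dplyr::filter(.data$n_cohorts == length(cohorts)) |>
    dplyr::pull(.data$signature) |>
    sort()
}

#' Downscale counts to a target total
#'
#' Proportional scaling with largest-remainder rounding, so the output is a
#' non-negative integer vector summing exactly to `n_target`. Remainder
#' ties break by index order.
#'
#' @param counts Non-negative numeric vector (optionally named).
#' @param n_target Target total, positive.
#' @return Integer vector, same names, summing to `n_target`.
#' @export
downscale_catalogue <- function(counts, n_target) {
  if (n_target <= 0) abort("n_target must be positive")
  if (sum(counts) <= 0) abort("counts must have a positive sum")
  scaled <- counts * n_target / sum(counts)
  base <- floor(scaled)
  short <- n_target - sum(base)
  if (short > 0) {
    rem <- scaled - base
    ord <- order(-rem, seq_along(rem))  # largest remainder, then index
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  setNames(as.integer(base), names(counts))
}

#' Per-signature cohort comparison with Holm adjustment
#'
#' For each signature, tests the 2x2 table (this signature vs all other
#' mutations) x (cohort A vs cohort B) by Pearson chi-square without
#' continuity correction; when any expected cell falls below 5 the test
#' falls back to Fisher's exact test and is flagged. P values are
#' Holm-adjusted across the tested signatures.
#'
#' @param counts_a,counts_b Named per-signature mutation counts for the two
#'   cohorts (signatures absent from one cohort count 0).
#' @param labels Cohort labels used in the output.
#' @return Tibble: `signature`, both counts, `statistic`, `p`, `p_adj`,
#'   `method`.
#' @export
compare_cohort_signatures <- function(counts_a, counts_b,
                                      labels = c("control", "NTV")) {
  sigs <- sort(union(names(counts_a), names(counts_b)))
  a <- setNames(rep(0, length(sigs)), sigs)
  b <- a
  a[names(counts_a)] <- counts_a
  b[names(counts_b)] <- counts_b
  tot_a <- sum(a)
  tot_b <- sum(b)
  res <- purrr::map_dfr(sigs, function(s) {
    tab <- matrix(c(a[s], tot_a - a[s], b[s], tot_b - b[s]), nrow = 2,
                  byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- fisher.test(tab)$p.value
      tibble::tibble(signature = s, statistic = NA_real_, p = p,
                     method = "fisher")
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(signature = s, statistic = unname(ct$statistic),
                     p = ct$p.value, method = "chi-square")
    }
  })
  res <- tibble::tibble(signature = sigs,
                        count_a = unname(a), count_b = unname(b)) |>
    dplyr::left_join(res, by = "signature")
  res$p_adj <- holm_adjust(res$p)
  attr(res, "labels") <- labels
  res
}

#' @exportS3Method generics::glance
glance.exposure_fit <- function(x, ...) {
  tibble::tibble(residual = attr(x, "residual"),
                 total = attr(x, "total"),
                 n_signatures = nrow(x),
                 n_active = sum(x$exposure > 0))
}

#' @exportS3Method generics::tidy
tidy.exposure_fit <- function(x, ...) {
  tot <- sum(x$exposure)
  tibble::tibble(signature = x$signature, exposure = x$exposure,
                 fraction = if (tot > 0) x$exposure / tot else rep(0, nrow(x)))
}
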
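# Readers/writers for the standard formats the pipeline touches:
# 6-column PED pedigrees, multi-sample trio VCFs, per-caller SV VCFs,
# covariate TSVs, reference signature matrices and the DNM call table.

#' Read a pedigree of father-mother-child trios
#'
#' Parses a 6-column PED file (family, individual, father, mother, sex,
#' phenotype) into one row per family trio. Child rows are those with both
#' parent ids set; each family must contain exactly one such trio.
#'
#' @param path Path to a PED file (whitespace-delimited, no header).
#' @param cohorts Optional cohort labels: either a path to a two-column TSV
#'   (`family_id`, `cohort`) or a named character vector keyed by family id.
#'   When `NULL`, the PED phenotype column is used (1 = "control",
#'   2 = "NTV").
#' @return A tibble with columns `family_id`, `father_id`, `mother_id`,
#'   `child_id`, `cohort`.
#' @export
read_pedigree <- function(path, cohorts = NULL) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    warn(sprintf("pedigree file '%s' is empty", path))
    return(tibble::tibble(family_id = character(), father_id = character(),
                          mother_id = character(), child_id = character(),
                          cohort = character()))
  }
  if (ncol(raw) < 6) abort("PED file must have 6 columns")
  names(raw) <- c("fid", "iid", "pat", "mat", "sex", "pheno")

  children <- raw[raw$pat != "0" & raw$mat != "0", , drop = FALSE]
  if (any(duplicated(children$fid))) {
    abort(sprintf("duplicate family id in pedigree: %s",
                  paste(unique(children$fid[duplicated(children$fid)]),
                        collapse = ", ")))
  }
  for (i in seq_len(nrow(children))) {
    fam <- children$fid[i]
    fam_ids <- raw$iid[raw$fid == fam]
    for (p in c(children$pat[i], children$mat[i])) {
      if (!p %in% fam_ids) {
        abort(sprintf("unknown parent '%s' referenced by family '%s'", p, fam))
      }
    }
  }

  ped <- tibble::tibble(
    family_id = children$fid,
    father_id = children$pat,
    mother_id = children$mat,
    child_id  = children$iid,
    cohort    = dplyr::case_when(children$pheno == "2" ~ "NTV",
                                 TRUE ~ "control")
  )
  if (!is.null(cohorts)) {
    map <- if (is.character(cohorts) && length(cohorts) == 1 &&
               file.exists(cohorts)) {
      tab <- readr::read_tsv(cohorts, show_col_types = FALSE)
      setNames(as.character(tab$cohort), tab$family_id)
    } else {
      cohorts
    }
    ped$cohort <- unname(map[ped$family_id])
  }
  bad <- ped$father_id == ped$mother_id | ped$father_id == ped$child_id |
    ped$mother_id == ped$child_id
  if (any(bad)) {
    abort(sprintf("family '%s' does not have three distinct sample ids",
                  ped$family_id[which(bad)[1]]))
  }
  ped
}

#' Default INFO/FORMAT key mapping for trio VCF annotation fields
#'
#' @param pop_af,deleterious_votes,region,in_repeat,mv_cohort,origin INFO key
#'   names used to populate the corresponding annotation columns (`origin`
#'   carries the simulated parental-origin label; phasing from reads is out
#'   of scope).
#' @param strip_chr Normalise chromosome names by removing a "chr" prefix.
#' @return A named list understood by [read_trio_vcf()].
#' @export
vcf_keys <- function(pop_af = "AF_POP", deleterious_votes = "DELVOTES",
                     region = "REGION", in_repeat = "REPEAT",
                     mv_cohort = "MVCOHORT", origin = "ORIGIN",
                     strip_chr = FALSE) {
  list(pop_af = pop_af, deleterious_votes = deleterious_votes,
       region = region, in_repeat = in_repeat, mv_cohort = mv_cohort,
       origin = origin, strip_chr = strip_chr)
}

#' Read a multi-sample trio VCF into the tidy variant model
#'
#' One row per biallelic record per trio; multiallelic records are decomposed
#' into one row per alternate allele (genotype alleles other than the current
#' alternate are mapped to reference). Substitutions of equal length > 1 and
#' indels of 50 bp or more are outside the small-variant model and are
#' skipped with a logged count, as are records with malformed genotypes.
#'
#' @param path VCF 4.x file (plain or bgzip/gzip compressed) with FORMAT
#'   fields GT, DP, AD and GQ.
#' @param pedigree A one-row pedigree tibble ([read_pedigree()]) naming the
#'   three samples, or a list with `father_id`, `mother_id`, `child_id`.
#' @param keys INFO key mapping from [vcf_keys()].
#' @return A tibble of trio variants with per-sample `*_gt`, `*_dp`,
#'   `*_alt`, `*_gq` columns for father/mother/child plus annotation columns
#'   `pop_af`, `deleterious_votes`, `region`, `in_repeat`, `mv_cohort_flag`.
#'   The number of skipped records is attached as attribute `skipped`.
#' @export
read_trio_vcf <- function(path, pedigree, keys = vcf_keys()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  roles <- c(father = pedigree$father_id[[1]],
             mother = pedigree$mother_id[[1]],
             child  = pedigree$child_id[[1]])
  absent <- setdiff(unname(roles), samples)
  if (length(absent) > 0) {
    abort(sprintf("sample(s) %s absent from VCF header",
                  paste(absent, collapse = ", ")))
  }
  if (nrow(fix) == 0) {
    out <- empty_trio_variants()
    attr(out, "skipped") <- 0L
    return(out)
  }

  gt_m <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  dp_m <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq_m <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  ad_m <- vcfR::extract.gt(v, element = "AD", convertNA = FALSE)

  info <- fix$INFO
  pop_af <- info_numeric(info, keys$pop_af)
  votes <- info_numeric(info, keys$deleterious_votes)
  region <- info_string(info, keys$region)
  region[is.na(region)] <- "other"
  in_rep <- info_flag(info, keys$in_repeat)
  mv_flag <- info_flag(info, keys$mv_cohort)
  origin <- info_string(info, keys$origin)

  chrom <- fix$CHROM
  if (isTRUE(keys$strip_chr)) chrom <- sub("^chr", "", chrom)

  rows <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- fix$REF[i]
    for (k in seq_along(alts)) {
      alt <- alts[k]
      len <- abs(nchar(ref) - nchar(alt))
      vclass <- if (nchar(ref) == 1 && nchar(alt) == 1) "SNV" else "indel"
      if (vclass == "indel" && (len < 1 || len >= 50)) {
        skipped <- skipped + 1L
        next
      }
      samp <- lapply(roles, function(sid) {
        decompose_sample(gt_m[i, sid], dp_m[i, sid], ad_m[i, sid],
                         gq_m[i, sid], alt_index = k)
      })
      if (any(vapply(samp, is.null, logical(1)))) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = chrom[i], pos = as.integer(fix$POS[i]), ref = ref, alt = alt,
        vclass = vclass,
        father_gt = samp$father$gt, father_dp = samp$father$dp,
        father_alt = samp$father$alt, father_gq = samp$father$gq,
        mother_gt = samp$mother$gt, mother_dp = samp$mother$dp,
        mother_alt = samp$mother$alt, mother_gq = samp$mother$gq,
        child_gt = samp$child$gt, child_dp = samp$child$dp,
        child_alt = samp$child$alt, child_gq = samp$child$gq,
        pop_af = pop_af[i], deleterious_votes = votes[i],
        region = region[i], in_repeat = in_rep[i], mv_cohort_flag = mv_flag[i],
        origin = origin[i]
      )
    }
  }
  rows <- purrr::compact(rows)
  out <- if (length(rows) == 0) empty_trio_variants() else dplyr::bind_rows(rows)
  if (skipped > 0) {
    message(sprintf("read_trio_vcf: skipped %d record(s) outside the small-variant model", skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

empty_trio_variants <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    vclass = character(),
    father_gt = character(), father_dp = integer(), father_alt = integer(),
    father_gq = integer(),
    mother_gt = character(), mother_dp = integer(), mother_alt = integer(),
    mother_gq = integer(),
    child_gt = character(), child_dp = integer(), child_alt = integer(),
    child_gq = integer(),
    pop_af = double(), deleterious_votes = double(), region = character(),
    in_repeat = logical(), mv_cohort_flag = logical(), origin = character()
  )
}

# Map one sample's FORMAT values onto a single alternate allele. Returns
# NULL for malformed genotype strings (the record is then skipped).
decompose_sample <- function(gt, dp, ad, gq, alt_index) {
  if (is.na(gt) || gt == "") return(NULL)
  norm <- gsub("|", "/", gt, fixed = TRUE)
  if (!grepl("^(\\.|\\d+)/(\\.|\\d+)$", norm)) return(NULL)
  alleles <- strsplit(norm, "/", fixed = TRUE)[[1]]
  if (any(alleles == ".")) {
    gt_out <- "./."
  } else {
    a <- as.integer(alleles)
    mapped <- ifelse(a == alt_index, 1L, 0L)
    gt_out <- paste(sort(mapped), collapse = "/")
  }
  alt_reads <- NA_integer_
  if (!is.na(ad) && ad != ".") {
    fields <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
    if (length(fields) > alt_index) alt_reads <- fields[alt_index + 1L]
  }
  list(gt = gt_out,
       dp = if (is.na(dp)) NA_integer_ else as.integer(dp),
       alt = alt_reads,
       gq = if (is.na(gq)) NA_integer_ else as.integer(gq))
}

info_field <- function(info, key) {
  info <- ifelse(is.na(info), "", info)
  pat <- paste0("(^|;)", key, "=[^;]*")
  hit <- regexpr(pat, info)
  out <- rep(NA_character_, length(info))
  has <- !is.na(hit) & hit > 0
  out[has] <- sub(paste0("^;?", key, "="), "", unlist(regmatches(info, hit)))
  out
}

info_numeric <- function(info, key) suppressWarnings(as.numeric(info_field(info, key)))
info_string <- function(info, key) info_field(info, key)
info_flag <- function(info, key) {
  info <- ifelse(is.na(info), "", info)
  grepl(paste0("(^|;)", key, "(;|$|=)"), info)
}

#' Read a single-sample SV caller VCF into a tidy call table
#'
#' Expects INFO keys `SVTYPE` and `END` plus strand-support read counts
#' (`PLUS`, `MINUS`). Records missing SVTYPE or END are skipped with a
#' logged count.
#'
#' @param path VCF file from one SV caller for one family.
#' @param caller Caller label recorded in the `caller` column.
#' @param family_id Family the calls belong to.
#' @return Tibble with `family_id`, `chrom`, `start`, `end`, `svtype`,
#'   `length`, `caller`, `plus_reads`, `minus_reads`.
#' @export
read_sv_vcf <- function(path, caller, family_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_sv_calls())
  svtype <- info_string(fix$INFO, "SVTYPE")
  endpos <- info_numeric(fix$INFO, "END")
  plus <- info_numeric(fix$INFO, "PLUS")
  minus <- info_numeric(fix$INFO, "MINUS")
  keep <- !is.na(svtype) & !is.na(endpos)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("read_sv_vcf: skipped %d record(s) without SVTYPE/END", n_skip))
  }
  tibble::tibble(
    family_id = family_id,
    chrom = fix$CHROM[keep],
    start = as.integer(fix$POS[keep]),
    end = as.integer(endpos[keep]),
    svtype = svtype[keep],
    length = as.integer(endpos[keep]) - as.integer(fix$POS[keep]),
    caller = caller,
    plus_reads = dplyr::coalesce(as.integer(plus[keep]), 0L),
    minus_reads = dplyr::coalesce(as.integer(minus[keep]), 0L)
  )
}

empty_sv_calls <- function() {
  tibble::tibble(family_id = character(), chrom = character(),
                 start = integer(), end = integer(), svtype = character(),
                 length = integer(), caller = character(),
                 plus_reads = integer(), minus_reads = integer())
}

#' Read the per-family covariate table
#'
#' @param path TSV with one row per family: `family_id`, `cohort`,
#'   `paternal_age_conception`, `child_age_sampling`, `exposure_rank` and
#'   any confounder columns.
#' @return A tibble, `exposure_rank` coerced to integer.
#' @export
read_covariates <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(tab, c("family_id", "cohort", "paternal_age_conception"),
                 "covariate table")
  if ("exposure_rank" %in% names(tab)) {
    tab$exposure_rank <- as.integer(tab$exposure_rank)
  }
  tab
}

#' Read a reference signature matrix (COSMIC-style TSV)
#'
#' First column holds the 96 channel labels (e.g. `A[C>A]A`); remaining
#' columns one signature each. Rows are reordered to the canonical channel
#' order and columns are checked to sum to one.
#'
#' @param path TSV file, channels x signatures.
#' @return A 96 x S numeric matrix with channel rownames and signature
#'   colnames.
#' @export
read_signature_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- labels
  canon <- sbs96_channels()
  if (!setequal(labels, canon)) {
    abort("signature matrix does not contain the 96 SBS channel labels")
  }
  m <- m[canon, , drop = FALSE]
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("signature matrix columns must each sum to 1")
  }
  if (any(m < 0)) abort("signature matrix entries must be non-negative")
  m
}

#' Write / read the accepted de novo mutation table
#'
#' The writer emits a deterministic TSV: fixed column order (`family_id`,
#' `cohort`, `chrom`, `pos`, `ref`, `alt`, `vclass`, `origin`, `signature`)
#' and a stable sort by family, chromosome, position, so write-then-read is
#' the identity on those columns.
#'
#' @param calls Tibble of accepted DNM calls.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dnm_table <- function(calls, path) {
  cols <- c("family_id", "cohort", "chrom", "pos", "ref", "alt", "vclass",
            "origin", "signature")
  for (col in setdiff(cols, names(calls))) calls[[col]] <- NA_character_
  out <- dplyr::arrange(calls[, cols], .data$family_id, .data$chrom, .data$pos)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_dnm_table
#' @export
read_dnm_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    family_id = readr::col_character(),
                    cohort = readr::col_character(),
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    vclass = readr::col_character(),
                    origin = readr::col_character(),
                    signature = readr::col_character()
                  ))
}
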
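# Shared internal helpers: genotype algebra, assertions, seeded evaluation.

# Parse diploid GT strings ("0/0", "0|1", "./.") into a 2-column integer
# matrix of allele indices; any missing allele yields NA for both.
gt_allele_matrix <- function(gt) {
  parts <- stringr::str_split_fixed(gsub("\\|", "/", gt), "/", 2)
  a1 <- suppressWarnings(as.integer(parts[, 1]))
  a2 <- suppressWarnings(as.integer(parts[, 2]))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  cbind(a1, a2)
}

gt_is_missing <- function(gt) {
  is.na(gt_allele_matrix(gt)[, 1])
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards (so package functions never disturb user RNG).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# DNA complement for plain character vectors of single bases.
dna_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

# Union-find with path compression; used by the SV merge closure.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}
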
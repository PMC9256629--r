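# Cohort-comparison statistics: contingency tests, Holm adjustment,
# nonparametric group tests, size-spectrum comparison, negative-binomial
# exposure regression with AIC model choice, the Williams overdispersed
# binomial, bootstrap per-offspring rates and the design power simulation.

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("a 2x2 table is required")
  if (any(m < 0)) abort("cells must be non-negative")
  if (sum(m) <= 0) abort("degenerate margin: empty table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate margin")
  }
  m
}

test_result <- function(method, statistic, df, p, adjusted = NA_real_) {
  tibble::tibble(method = method, statistic = statistic, df = df, p = p,
                 p_adj = adjusted)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with one
#' degree of freedom — the form that reproduces the mutation-spectrum
#' homogeneity statistics (transitions/transversions, deletion/insertion
#' and SV spectra).
#'
#' @param table 2x2 matrix-like of non-negative counts.
#' @return One-row tibble: `method`, `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  m <- as_2x2(table)
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  test_result("chi-square", unname(ct$statistic), 1, ct$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: the p value sums the hypergeometric probabilities
#' of all tables no more likely than the observed one.
#'
#' @inheritParams chi_square_2x2
#' @return One-row tibble: `method`, `statistic` (odds ratio), `df`, `p`.
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  ft <- fisher.test(m)
  test_result("fisher", unname(ft$estimate), NA_real_, ft$p.value)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the raw p values ascending, multiplies the i-th by `m - i + 1`,
#' enforces monotonicity by a running maximum, caps at 1 and returns the
#' adjusted values in the input order.
#'
#' @param p Numeric vector of p values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p values, same order and length.
#' @export
holm_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom. With all observations identical the statistic
#' is 0 and p = 1.
#'
#' @param groups List of numeric vectors, one per group (at least two
#'   groups, each non-empty).
#' @return One-row tibble: `method`, `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("at least two non-empty groups are required")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    return(test_result("kruskal-wallis", 0, length(groups) - 1, 1))
  }
  kt <- kruskal.test(groups)
  test_result("kruskal-wallis", unname(kt$statistic),
              unname(kt$parameter), kt$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D statistic with the asymptotic p value, used for comparing
#' indel and SV size spectra between cohorts.
#'
#' @param sizes_a,sizes_b Non-empty numeric samples.
#' @return One-row tibble: `method`, `statistic` (D), `df`, `p`.
#' @export
ks_two_sample <- function(sizes_a, sizes_b) {
  if (length(sizes_a) == 0 || length(sizes_b) == 0) {
    abort("both samples must be non-empty")
  }
  kt <- suppressWarnings(ks.test(sizes_a, sizes_b, exact = FALSE))
  test_result("kolmogorov-smirnov", unname(kt$statistic), NA_real_, kt$p.value)
}

#' Negative-binomial exposure regression with AIC model comparison
#'
#' Fits a log-link NB2 model (variance `mu + mu^2/theta`, dispersion by
#' maximum likelihood) of a per-offspring count endpoint on an exposure
#' variable, unadjusted and (when confounders are supplied) adjusted.
#' Poisson and normal (gaussian, log-transformed mean via identity on
#' counts) fits of the same adjusted design are reported for AIC
#' comparison. Highly correlated confounder pairs (|r| > 0.7) are pruned to
#' the one ranked higher in `priority` (or the first encountered).
#'
#' @param data Data frame with the endpoint, exposure and confounders.
#' @param response Name of the count column.
#' @param exposure Name of the exposure column.
#' @param confounders Character vector of confounder column names.
#' @param priority Optional ordering of confounders by biological
#'   plausibility, used when pruning correlated pairs.
#' @return Object of class `nb_regression`; see [tidy.nb_regression()] and
#'   [glance.nb_regression()].
#' @export
nb_regression <- function(data, response, exposure, confounders = character(0),
                          priority = NULL) {
  keep <- prune_confounders(data, confounders, priority)
  f_un <- as.formula(paste(response, "~", exposure))
  rhs_adj <- paste(c(exposure, keep), collapse = " + ")
  f_adj <- as.formula(paste(response, "~", rhs_adj))

  fit_nb <- function(f) {
    tryCatch(
      suppressWarnings(MASS::glm.nb(f, data = data)),
      error = function(e) NULL
    )
  }
  nb_un <- fit_nb(f_un)
  nb_adj <- if (length(keep) > 0) fit_nb(f_adj) else nb_un
  pois <- suppressWarnings(glm(f_adj, data = data, family = "poisson"))
  gauss <- lm(f_adj, data = data)

  converged <- !is.null(nb_un) && !is.null(nb_adj) &&
    isTRUE(nb_un$converged) && isTRUE(nb_adj$converged)
  structure(list(
    nb_unadjusted = nb_un, nb_adjusted = nb_adj,
    poisson = pois, gaussian = gauss,
    response = response, exposure = exposure,
    confounders_used = keep, confounders_dropped = setdiff(confounders, keep),
    converged = converged
  ), class = "nb_regression")
}

# Drop one of each confounder pair with |r| > 0.7, keeping the one ranked
# higher in `priority` (earlier = more plausible).
prune_confounders <- function(data, confounders, priority = NULL) {
  numeric_conf <- confounders[vapply(confounders, function(v) {
    is.numeric(data[[v]]) || is.logical(data[[v]])
  }, logical(1))]
  keep <- confounders
  if (length(numeric_conf) >= 2) {
    rank_of <- function(v) {
      r <- match(v, priority %||% confounders)
      ifelse(is.na(r), length(confounders) + 1L, r)
    }
    cm <- suppressWarnings(
      stats::cor(as.data.frame(lapply(data[numeric_conf], as.numeric)),
                 use = "pairwise.complete.obs"))
    for (i in seq_len(length(numeric_conf) - 1)) {
      for (j in seq((i + 1), length(numeric_conf))) {
        vi <- numeric_conf[i]
        vj <- numeric_conf[j]
        if (!vi %in% keep || !vj %in% keep) next
        if (!is.na(cm[i, j]) && abs(cm[i, j]) > 0.7) {
          drop <- if (rank_of(vi) <= rank_of(vj)) vj else vi
          keep <- setdiff(keep, drop)
        }
      }
    }
  }
  keep
}

coef_tibble <- function(fit, model_label) {
  if (is.null(fit)) return(tibble::tibble())
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  tibble::tibble(
    model = model_label,
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - qnorm(0.975) * se),
    conf_high = unname(est + qnorm(0.975) * se),
    p_value = unname(2 * pnorm(-abs(z)))
  )
}

#' @describeIn nb_regression Coefficients (log scale) with Wald 95% CIs for
#'   the unadjusted and adjusted NB models.
#' @param x,object An `nb_regression` object.
#' @param exponentiate Report rate ratios instead of log coefficients.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nb_regression <- function(x, exponentiate = FALSE, ...) {
  out <- dplyr::bind_rows(coef_tibble(x$nb_unadjusted, "unadjusted"),
                          coef_tibble(x$nb_adjusted, "adjusted"))
  if (exponentiate) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf_low = exp(.data$conf_low),
                         conf_high = exp(.data$conf_high))
  }
  out
}

#' @describeIn nb_regression Model-level summary: AICs of the NB, Poisson
#'   and normal fits, the NB dispersion (theta) and convergence flag.
#' @exportS3Method generics::glance
glance.nb_regression <- function(x, ...) {
  tibble::tibble(
    aic_nb = if (!is.null(x$nb_adjusted)) AIC(x$nb_adjusted) else NA_real_,
    aic_poisson = AIC(x$poisson),
    aic_normal = AIC(x$gaussian),
    theta = if (!is.null(x$nb_adjusted)) x$nb_adjusted$theta else NA_real_,
    converged = x$converged,
    confounders_used = paste(x$confounders_used, collapse = ","),
    confounders_dropped = paste(x$confounders_dropped, collapse = ",")
  )
}

#' @export
print.nb_regression <- function(x, ...) {
  cat("Negative-binomial exposure regression\n")
  cat("  endpoint:", x$response, " exposure:", x$exposure, "\n")
  g <- glance(x)
  cat(sprintf("  AIC  NB: %.1f  Poisson: %.1f  Normal: %.1f\n",
              g$aic_nb, g$aic_poisson, g$aic_normal))
  print(tidy(x))
  invisible(x)
}

#' Williams overdispersed binomial group comparison
#'
#' Logistic regression of per-offspring successes out of totals on a group
#' label, with Williams' correction for extra-binomial variation: a
#' heterogeneity factor phi inflates the binomial variance of offspring i
#' to `m_i p q (1 + phi (m_i - 1))`; phi is estimated iteratively by
#' equating the leverage-corrected weighted Pearson statistic to its
#' expectation, and observations are reweighted by
#' `1 / (1 + phi (m_i - 1))` until convergence. With no overdispersion the
#' fit reduces to plain logistic regression (phi = 0).
#'
#' @param successes,totals Integer vectors per offspring
#'   (`successes <= totals`).
#' @param group Two-level factor or character vector.
#' @param max_iter,tol Iteration controls for the phi estimate.
#' @return Object of class `williams_binomial` with the group effect on the
#'   logit scale, 95% CI, p value, `phi` and the mean variance inflation
#'   `scale_factor`.
#' @export
williams_binomial <- function(successes, totals, group, max_iter = 25,
                              tol = 1e-6) {
  if (any(successes > totals)) abort("successes must not exceed totals")
  if (any(totals <= 0)) abort("totals must be positive")
  group <- factor(group)
  if (nlevels(group) != 2) abort("group must have exactly two levels")
  sep_warn <- any(tapply(successes, group, sum) == 0)
  if (sep_warn) warn("a group has zero successes: estimates may be unstable")

  df <- data.frame(s = successes, m = totals, group = group)
  w <- rep(1, nrow(df))
  phi <- 0
  for (iter in seq_len(max_iter)) {
    fit <- suppressWarnings(
      glm(cbind(s, m - s) ~ group, family = quasibinomial(), data = df,
          weights = w))
    x2 <- sum(residuals(fit, type = "pearson")^2)
    h <- hatvalues(fit)
    denom <- sum(w * (1 - h) * (df$m - 1))
    if (denom <= 0) break
    phi_new <- max(0, (x2 - sum(w * (1 - h))) / denom)
    if (abs(phi_new - phi) < tol) {
      phi <- phi_new
      break
    }
    phi <- phi_new
    w <- 1 / (1 + phi * (df$m - 1))
  }
  w <- 1 / (1 + phi * (df$m - 1))
  fit <- suppressWarnings(
    glm(cbind(s, m - s) ~ group, family = quasibinomial(), data = df,
        weights = w))
  sm <- summary(fit, dispersion = 1)
  est <- sm$coefficients[2, "Estimate"]
  se <- sm$coefficients[2, "Std. Error"]
  structure(list(
    estimate = est, std_error = se,
    conf_low = est - qnorm(0.975) * se,
    conf_high = est + qnorm(0.975) * se,
    p = 2 * pnorm(-abs(est / se)),
    phi = phi,
    scale_factor = mean(1 + phi * (totals - 1)),
    separation = sep_warn,
    levels = levels(group),
    fit = fit
  ), class = "williams_binomial")
}

#' @describeIn williams_binomial One-row coefficient tibble (logit scale).
#' @param x An object returned by `williams_binomial()`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.williams_binomial <- function(x, ...) {
  tibble::tibble(term = paste0("group", x$levels[2]),
                 estimate = x$estimate, std_error = x$std_error,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 p_value = x$p)
}

#' @describeIn williams_binomial Heterogeneity summary.
#' @exportS3Method generics::glance
glance.williams_binomial <- function(x, ...) {
  tibble::tibble(phi = x$phi, scale_factor = x$scale_factor,
                 separation = x$separation)
}

#' @export
print.williams_binomial <- function(x, ...) {
  cat("Williams overdispersed binomial comparison\n")
  cat(sprintf("  group effect (logit): %.3f [%.3f, %.3f], p = %.3g\n",
              x$estimate, x$conf_low, x$conf_high, x$p))
  cat(sprintf("  heterogeneity phi = %.4g (mean inflation %.3f)\n",
              x$phi, x$scale_factor))
  invisible(x)
}

#' Per-offspring rate with a bootstrap confidence interval
#'
#' Mean per-offspring count with a seeded percentile bootstrap CI.
#'
#' @param counts Per-offspring counts (at least 2).
#' @param conf Confidence level.
#' @param reps Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: `mean`, `conf_low`, `conf_high`, `n`.
#' @export
rate_with_ci <- function(counts, conf = 0.95, reps = 2000, seed = 1) {
  if (length(counts) < 2) abort("at least two offspring are required")
  alpha <- (1 - conf) / 2
  boots <- with_seed(seed, {
    vapply(seq_len(reps),
           function(i) mean(sample(counts, replace = TRUE)), numeric(1))
  })
  tibble::tibble(mean = mean(counts),
                 conf_low = unname(quantile(boots, alpha)),
                 conf_high = unname(quantile(boots, 1 - alpha)),
                 n = length(counts))
}

#' Simulated power of the two-cohort design
#'
#' Draws per-offspring mutation counts for two cohorts — Poisson with mean
#' `baseline_mean` in one and `baseline_mean * fold` in the other — and
#' tests each replicate with the Kruskal-Wallis rank test at level `alpha`.
#' Reports the rejection fraction (the empirical power) with its
#' Monte-Carlo standard error.
#'
#' @param n_per_group Offspring per cohort.
#' @param baseline_mean Mean DNM count per offspring in the reference
#'   cohort.
#' @param fold Rate ratio between cohorts (1 = null).
#' @param alpha Test level.
#' @param reps Number of simulation replicates (at least 100).
#' @param seed RNG seed.
#' @return One-row tibble: `power`, `mc_se`, `reps`, `n_per_group`,
#'   `fold`, `alpha`.
#' @export
power_simulation <- function(n_per_group = 30, baseline_mean = 62,
                             fold = 1.5, alpha = 0.05, reps = 1000,
                             seed = 1) {
  if (reps < 100) abort("reps must be at least 100")
  rejections <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      a <- rpois(n_per_group, baseline_mean)
      b <- rpois(n_per_group, baseline_mean * fold)
      kruskal_wallis(list(a, b))$p < alpha
    }, logical(1))
  })
  pw <- mean(rejections)
  tibble::tibble(power = pw,
                 mc_se = sqrt(pw * (1 - pw) / reps),
                 reps = reps, n_per_group = n_per_group,
                 fold = fold, alpha = alpha)
}
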
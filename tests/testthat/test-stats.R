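# The statistics layer against textbook oracles and simulation.

test_that("2x2 chi-square equals the textbook O-E formula on random tables", {
  for (seed in 1:20) {
    tab <- withr::with_seed(seed, matrix(sample(5:500, 4), 2))
    got <- chi_square_2x2(tab)
    expect_equal(got$statistic, oracle_chi2(tab), tolerance = 1e-10)
    expect_equal(got$df, 1)
  }
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_2x2(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 9, 9, 1), 2))$p,
               oracle_fisher_p(matrix(c(1, 9, 9, 1), 2)), tolerance = 1e-9)
  expect_equal(round(fisher_exact(matrix(c(1, 9, 9, 1), 2))$p, 4), 0.0011)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_lt(fisher_exact(matrix(c(0, 10, 10, 1), 2))$p, 1e-3)
  for (seed in 1:10) {
    tab <- withr::with_seed(100 + seed, matrix(sample(1:30, 4), 2))
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9)
  }
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  for (seed in 1:10) {
    p <- withr::with_seed(seed, runif(sample(2:12, 1)))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kruskal-Wallis matches the tie-corrected rank formula", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic,
               3.857, tolerance = 1e-3)
  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  for (seed in 1:8) {
    groups <- withr::with_seed(seed, {
      k <- sample(2:4, 1)
      lapply(seq_len(k), function(i) sample(1:10, sample(3:10, 1),
                                            replace = TRUE))
    })
    expect_equal(kruskal_wallis(groups)$statistic, oracle_kw_h(groups),
                 tolerance = 1e-10)
  }
})

test_that("KS statistic matches the ECDF sweep oracle", {
  x <- c(1, 2, 3)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x)$p, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  for (seed in 1:8) {
    a <- withr::with_seed(seed, rnorm(30))
    b <- withr::with_seed(seed + 50, rnorm(40, 0.3))
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_d(a, b),
                 tolerance = 1e-12)
  }
})

test_that("NB regression recovers a planted exposure effect", {
  dat <- withr::with_seed(3, {
    x <- rnorm(200)
    tibble::tibble(x = x, y = rnbinom(200, mu = exp(3 + 0.4 * x), size = 10))
  })
  fit <- nb_regression(dat, "y", "x")
  td <- tidy(fit)
  eff <- td[td$model == "unadjusted" & td$term == "x", ]
  expect_gt(eff$estimate, 0.25)
  expect_lt(eff$estimate, 0.55)
  expect_true(eff$conf_low < 0.4 && eff$conf_high > 0.4)
  # NB beats Poisson on overdispersed counts
  g <- glance(fit)
  expect_lt(g$aic_nb, g$aic_poisson)
  expect_lt(g$aic_nb, g$aic_normal)
})

test_that("NB exposure test holds its nominal level under the null", {
  rej <- withr::with_seed(1, {
    vapply(1:500, function(i) {
      d <- tibble::tibble(y = rpois(200, 60), x = rep(0:1, each = 100))
      td <- tidy(nb_regression(d, "y", "x"))
      td$p_value[td$model == "unadjusted" & td$term == "x"] < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("NB and Poisson agree in the zero-dispersion limit", {
  dat <- withr::with_seed(5, tibble::tibble(y = rpois(300, 50),
                                            x = rnorm(300)))
  g <- glance(nb_regression(dat, "y", "x"))
  # equal likelihoods: AIC gap is the one extra dispersion parameter
  expect_lt(abs(g$aic_nb - g$aic_poisson), 2.1)
})

test_that("correlated confounders are pruned by the priority list", {
  dat <- withr::with_seed(6, {
    z <- rnorm(100)
    tibble::tibble(y = rpois(100, 30), x = rep(0:1, 50),
                   a = z + rnorm(100, sd = 0.1), b = z,
                   c = rnorm(100))
  })
  fit <- nb_regression(dat, "y", "x", confounders = c("a", "b", "c"),
                       priority = c("b", "a", "c"))
  expect_setequal(fit$confounders_used, c("b", "c"))
  expect_equal(fit$confounders_dropped, "a")
})

test_that("Williams model reduces to plain logistic without overdispersion", {
  dat <- withr::with_seed(7, {
    m <- rep(50L, 40)
    g <- rep(c("a", "b"), each = 20)
    tibble::tibble(m = m, g = g,
                   s = rbinom(40, m, ifelse(g == "a", 0.3, 0.35)))
  })
  w <- williams_binomial(dat$s, dat$m, dat$g)
  plain <- glm(cbind(s, m - s) ~ g, family = binomial(), data = dat)
  expect_lt(w$phi, 0.01)
  expect_equal(w$estimate, unname(coef(plain)[2]), tolerance = 0.02)
  expect_gte(w$scale_factor, 1 - 1e-6)
})

test_that("Williams scale factor exceeds 1 under beta-binomial overdispersion", {
  dat <- withr::with_seed(8, {
    m <- rep(60L, 50)
    g <- rep(c("a", "b"), each = 25)
    rho <- 0.1
    ab <- (1 - rho) / rho
    p <- rbeta(50, 0.3 * ab, 0.7 * ab)
    tibble::tibble(m = m, g = g, s = rbinom(50, m, p))
  })
  w <- williams_binomial(dat$s, dat$m, dat$g)
  expect_gt(w$phi, 0)
  expect_gt(w$scale_factor, 1.5)
})

test_that("Williams CI contains zero for equal success proportions", {
  s <- rep(c(10L, 20L), 10)
  m <- rep(c(40L, 80L), 10)
  g <- rep(c("a", "b"), each = 10)
  w <- williams_binomial(s, m, g)
  expect_true(w$conf_low < 0 && w$conf_high > 0)
})

test_that("bootstrap rate CIs are deterministic and degenerate correctly", {
  const <- rate_with_ci(rep(5, 10), seed = 2)
  expect_equal(const$conf_low, 5)
  expect_equal(const$conf_high, 5)
  a <- rate_with_ci(c(1, 5, 9, 3, 7), seed = 11)
  b <- rate_with_ci(c(1, 5, 9, 3, 7), seed = 11)
  expect_equal(a, b)
  expect_error(rate_with_ci(5), "at least two")
})

test_that("bootstrap CI covers the true mean at close to nominal rate", {
  cover <- withr::with_seed(12, {
    vapply(1:150, function(i) {
      x <- rpois(30, 62)
      ci <- rate_with_ci(x, reps = 500, seed = i)
      ci$conf_low <= 62 && 62 <= ci$conf_high
    }, logical(1))
  })
  expect_gt(mean(cover), 0.88)
})

test_that("power simulation is calibrated at the null and monotone in fold", {
  null <- power_simulation(fold = 1, reps = 400, seed = 5)
  expect_lt(abs(null$power - 0.05), 0.03)
  powers <- vapply(c(1, 1.25, 1.5, 2), function(f) {
    power_simulation(fold = f, reps = 300, seed = 9)$power
  }, numeric(1))
  expect_true(all(diff(powers) >= -0.03))
  expect_equal(powers[4], 1, tolerance = 0.01)
})
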
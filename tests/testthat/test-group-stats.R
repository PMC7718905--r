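test_that("mann_whitney: symmetry, exact small-sample p, conventions", {
  x <- c(3.2, 4.1, 5.0, 2.2)
  r <- mann_whitney(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_equal(r$Z, 0)
  expect_equal(r$p, 1)

  # complete separation, n = 3 vs 3: U = 0 under the "x above y" counting,
  # exact two-sided p = 2 * 1/choose(6,3) = 0.1
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)
  expect_identical(sep$method, "exact")
  expect_lt(sep$Z, 0)              # first sample stochastically smaller

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches full enumeration", {
  # enumerate all C(8,3) = 56 assignments of ranks to the first sample
  x <- c(0.3, 2.5, 1.1); y <- c(0.9, 3.2, 0.1, 1.8, 2.9)
  obs <- mann_whitney(x, y)
  nx <- 3; ny <- 5
  pooled_ranks <- seq_len(nx + ny)
  U_all <- apply(utils::combn(pooled_ranks, nx), 2,
                 function(ix) sum(ix) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  p_exact <- mean(abs(U_all - mu) >= abs(obs$U - mu))
  expect_equal(obs$p, p_exact)
})

test_that("tie-corrected variance matches the permutation variance", {
  x <- c(1, 1, 2); y <- c(1, 2, 2)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_all <- apply(utils::combn(6, 3), 2, function(ix) sum(r[ix]) - 6)
  sigma2_perm <- mean(U_all^2) - mean(U_all)^2
  ties <- table(pooled)
  sigma2_formula <- (3 * 3 / 12) * (7 - sum(ties^3 - ties) / (6 * 5))
  expect_equal(sigma2_formula, sigma2_perm)
  # and the reported Z uses that variance (continuity-corrected)
  obs <- mann_whitney(x, y)
  U <- obs$U
  expect_equal(obs$Z, (U - 4.5 - 0.5 * sign(U - 4.5)) / sqrt(sigma2_perm))
})

test_that("mann_whitney invariances: sample swap and U complementarity", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1)) + 0.5
    if (i %% 2) { x <- round(x); y <- round(y) }   # force ties half the time
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_equal(a$p, b$p)
    expect_equal(a$Z, -b$Z)
    expect_equal(a$U + b$U, length(x) * length(y))
  }
})

test_that("cliffs_delta equals the all-pairs definition and is antisymmetric", {
  expect_equal(cliffs_delta(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(cliffs_delta(c(10, 11), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2), c(5, 6)), -1)

  set.seed(31)
  x <- rnorm(13); y <- rnorm(17, mean = 0.4)
  expect_identical(cliffs_delta(x, y), naive_cliffs(x, y))
  xt <- sample(1:6, 13, replace = TRUE); yt <- sample(1:6, 17, replace = TRUE)
  expect_identical(cliffs_delta(xt, yt), naive_cliffs(xt, yt))
  expect_identical(cliffs_delta(xt, yt), -cliffs_delta(yt, xt))
  # invariant under a strictly increasing transform of the pooled data
  expect_identical(cliffs_delta(exp(x), exp(y)), cliffs_delta(x, y))
})

test_that("cv_equality_test: null identity, scale invariance, errors", {
  s <- c(9.5, 10.1, 10.8, 9.9, 10.4)
  r <- cv_equality_test(list(s, s))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1)

  set.seed(5)
  a <- rnorm(30, 10, 1); b <- rnorm(25, 20, 3)
  r1 <- cv_equality_test(list(a, b))
  r2 <- cv_equality_test(list(a * 7, b * 7))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$cv, r2$cv)

  expect_error(cv_equality_test(list(a)), ">= 2 samples")
  expect_error(cv_equality_test(list(a, b - 100)), "non-positive")
  expect_error(cv_equality_test(list(a, 1)), "n >= 2")
})

test_that("cv_equality_test rejects unequal CVs with high power", {
  set.seed(77)
  rej <- mean(replicate(200, {
    a <- rnorm(50, 10, 1)    # CV 0.1
    b <- rnorm(50, 10, 3)    # CV 0.3
    cv_equality_test(list(a, b))$p < 0.05
  }))
  expect_gt(rej, 0.9)
})

test_that("ks_normality screens as specified", {
  expect_error(ks_normality(1:4), "n >= 5")
  set.seed(6)
  big <- rnorm(500)
  expect_gt(ks_normality(big)$p, 0.001)
  hits <- sum(vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(100, -3), rnorm(100, 3))
    ks_normality(x)$p < 0.05
  }, logical(1)))
  expect_gte(hits, 19)
})

test_that("spearman_assoc shares the correlation kernel and calibrates", {
  set.seed(9)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_identical(spearman_assoc(x, y)$rho, spearman_rho(x, y))
  expect_equal(spearman_assoc(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_assoc(1:10, (1:10)^2)$p, 0)
  expect_error(spearman_assoc(1:4, 1:4), "n >= 5")
  expect_warning(r <- spearman_assoc(rep(1, 6), 1:6), "constant")
  expect_true(is.na(r$rho))

  rej <- mean(vapply(1:400, function(s) {
    set.seed(s)
    spearman_assoc(rnorm(100), rnorm(100))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.022); expect_lt(rej, 0.078)   # binomial 99% band, 400 sims
})

test_that("fdr_adjust implements BH step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))^2
    adj <- fdr_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))     # independent reference
    expect_true(all(adj >= p))
  }
  p_na <- c(0.01, NA, 0.04)
  expect_equal(fdr_adjust(p_na), c(0.02, NA, 0.04))
})

test_that("compare_pbsi orients signs, trims outliers, and guards sites", {
  co <- generate_cohort(two_group_spec(seed = 4, n = 30))
  res <- compute_pbsi_table(co$table)
  cmp <- compare_pbsi(res, "B", "A", "CT")     # B (noisy) vs A (tight)
  expect_identical(cmp$subset, c("all", "trimmed"))
  expect_lt(cmp$Z[1], 0)                       # B stochastically smaller
  expect_lt(cmp$cliffs_d[1], 0)
  expect_identical(sign(cmp$cliffs_d[1]), sign(cmp$cliffs_d[2]))
  expect_identical(cmp$n_a[1], 30L)

  none <- compare_pbsi(res, "A", "B", "CT", outlier_policy = "none")
  expect_identical(nrow(none), 1L)

  # two sites: ambiguous without an explicit site or cross_site
  co2 <- generate_cohort(cohort_spec(n_per_group = 10,
                                     groups = c("A", "B"),
                                     sites = c("s1", "s2"),
                                     n_ct_regions = 8, n_sv_regions = 4,
                                     seed = 2))
  res2 <- compute_pbsi_table(co2$table)
  expect_error(compare_pbsi(res2, "A", "B", "CT"), "site")
  ok <- compare_pbsi(res2, "A", "B", "CT", site = "s2")
  expect_identical(ok$site[1], "s2")
  pooled <- compare_pbsi(res2, "A", "B", "CT", cross_site = TRUE)
  expect_identical(pooled$n_a[1], 20L)
})

test_that("tukey_outliers flags exactly the beyond-fence points", {
  x <- c(1:10, 100)
  expect_identical(which(tukey_outliers(x)), 11L)
  expect_identical(sum(tukey_outliers(rep(3, 8))), 0L)
})
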
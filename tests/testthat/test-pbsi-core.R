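test_that("spearman_rho: monotone limits, frozen tied example, errors", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(8, 4, 2, 1)), -1)
  # hand-computed midranks (1, 2.5, 2.5, 4) vs (2, 1, 3.5, 3.5): rho = 9/18
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4)), 0.5)
  expect_error(spearman_rho(1:3, 1:4), "length mismatch")
  expect_error(spearman_rho(1, 1), "length >= 2")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "non-finite")
  expect_warning(r <- spearman_rho(c(2, 2, 2), 1:3), "constant")
  expect_true(is.na(r))
})

test_that("spearman_rho matches the brute-force oracle on tied data", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01 * (i %% 2))
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), naive_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("compute_pbsi analytic limits", {
  p <- matrix(rep(c(2.1, 2.5, 1.9, 3.0, 2.2), each = 5), nrow = 5)
  expect_equal(compute_pbsi(p)$pbsi, rep(1, 5))

  # P1 = P2, P3 is their rank reversal: PBSI = (0, 0, -1)
  p3 <- rbind(1:6, 1:6, 6:1)
  expect_equal(compute_pbsi(p3)$pbsi, c(0, 0, -1))
})

test_that("compute_pbsi equals the double-loop oracle", {
  m <- random_profiles(20, 82, seed = 5)
  expect_equal(compute_pbsi(m)$pbsi, unname(naive_pbsi(m)), tolerance = 1e-12)
})

test_that("PBSI is invariant to subject order, monotone transforms and scale", {
  m <- random_profiles(12, 30, seed = 8)
  base <- compute_pbsi(m)
  perm <- sample(nrow(m))
  shuffled <- compute_pbsi(m[perm, ])
  expect_identical(shuffled$pbsi[order(perm)], base$pbsi)

  m2 <- m
  m2[3, ] <- exp(m2[3, ])            # strictly increasing per-subject transform
  m2[7, ] <- m2[7, ]^3 + 10
  expect_identical(compute_pbsi(m2)$pbsi, base$pbsi)

  expect_identical(compute_pbsi(5 + 0.3 * m)$pbsi, base$pbsi)
})

test_that("constant profiles are excluded, not imputed", {
  m <- random_profiles(6, 10, seed = 2)
  m[4, ] <- 7
  expect_warning(res <- compute_pbsi(m), "s04")
  expect_true(is.na(res$pbsi[4]))
  expect_identical(res$n_peers[-4], rep(4L, 5))
  expect_equal(res$pbsi[-4], unname(naive_pbsi(m[-4, ])), tolerance = 1e-12)
  expect_error(suppressWarnings(compute_pbsi(rbind(rep(1, 5), rep(2, 5), 1:5))),
               "fewer than 2 usable")
})

test_that("compute_pbsi input contract errors", {
  expect_error(compute_pbsi(matrix(1:6, 1)), ">= 2 profiles")
  expect_error(compute_pbsi(matrix(1:6, ncol = 1)), ">= 2 regions")
  m <- random_profiles(3, 4); m[2, 2] <- Inf
  expect_error(compute_pbsi(m), "non-finite")
})

test_that("PBSI stays in bounds and is non-negative in expectation under a shared template", {
  for (seed in 1:8) {
    set.seed(seed)
    template <- rnorm(20)
    m <- t(replicate(6, template + rnorm(20, sd = 0.8)))
    sc <- compute_pbsi(m)$pbsi
    expect_true(all(sc >= -1 & sc <= 1))
    expect_gt(mean(sc), 0)
  }
})

test_that("compute_pbsi_table scores strictly within (group, site) cells", {
  co <- generate_cohort(cohort_spec(
    n_per_group = 6, groups = c("HC", "SZ"), sites = c("A", "B"),
    n_ct_regions = 8, n_sv_regions = 4, seed = 4))
  res <- compute_pbsi_table(co$table)
  expect_identical(nrow(res), 4L * 6L * 2L)   # 4 cells x 6 subjects x 2 modalities
  expect_true(all(res$n_peers == 5L))

  # cell scores match a direct per-cell computation
  sub <- co$table[co$table$group == "SZ" & co$table$site == "B", ]
  mat <- as.matrix(sub[grep("^ct__", names(sub))])
  rownames(mat) <- sub$subject_id
  direct <- compute_pbsi(mat)
  got <- res[res$group == "SZ" & res$site == "B" & res$modality == "CT", ]
  expect_identical(got$pbsi[match(direct$subject_id, got$subject_id)],
                   direct$pbsi)
})

test_that("pooling groups is explicit and labelled", {
  co <- small_cohort()
  pooled <- compute_pbsi_table(co$table, pool_groups = c("HC", "SZ"))
  expect_true(all(pooled$group == "HC+SZ"))
  expect_true(all(pooled$n_peers == 15L))
  expect_error(compute_pbsi_table(co$table, pool_groups = "nope"), "nope")
})
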
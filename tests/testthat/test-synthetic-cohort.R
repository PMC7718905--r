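test_that("cohort generation is deterministic and seed-sensitive", {
  sp <- cohort_spec(n_per_group = 6, groups = c("HC", "SZ"), seed = 11,
                    n_ct_regions = 8, n_sv_regions = 4)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$table, b$table)
  expect_identical(a$noise, b$noise)
  sp2 <- sp; sp2$seed <- 12L
  expect_false(identical(generate_cohort(sp2)$table, a$table))
})

test_that("adding subjects or groups does not perturb existing draws", {
  base <- generate_cohort(cohort_spec(n_per_group = 5, groups = "HC",
                                      n_ct_regions = 6, n_sv_regions = 4,
                                      seed = 3))
  more <- generate_cohort(cohort_spec(n_per_group = 9, groups = c("HC", "BD"),
                                      n_ct_regions = 6, n_sv_regions = 4,
                                      seed = 3))
  sub <- more$table[match(base$table$subject_id, more$table$subject_id), ]
  for (cl in names(base$table))
    expect_identical(unname(base$table[[cl]]), unname(sub[[cl]]))
})

test_that("zero dispersion with no covariate effects reproduces the template", {
  co <- generate_cohort(cohort_spec(n_per_group = 5, groups = "HC",
                                    within_group_dispersion = 0, seed = 2,
                                    n_ct_regions = 10, n_sv_regions = 4))
  ct <- as.matrix(co$table[grep("^ct__", names(co$table))])
  expect_true(all(apply(ct, 2, function(v) diff(range(v)) == 0)))
  for (i in 2:5)
    expect_equal(spearman_rho(ct[1, ], ct[i, ]), 1)
})

test_that("multi-site unbalanced design reproduces its cell counts", {
  m <- matrix(c(52, 44, 93, 41, 78, NA, 87, NA, 75), 3, 3)
  sp <- cohort_spec(n_per_group = m, groups = c("HC", "BD", "SZ"),
                    sites = c("s1", "s2", "s3"),
                    n_ct_regions = 4, n_sv_regions = 3, seed = 1)
  tab <- generate_cohort(sp)$table
  expect_identical(nrow(tab), 470L)
  expect_identical(sum(tab$group == "SZ" & tab$site == "s3"), 75L)
  expect_identical(sum(tab$group == "BD" & tab$site == "s3"), 0L)
  expect_false(anyDuplicated(tab$subject_id) > 0)
  sv <- as.matrix(tab[grep("^sv__", names(tab))])
  expect_true(all(is.finite(sv)) && all(sv > 0))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_per_group = 0, groups = "HC"), "empty")
  expect_error(cohort_spec(n_per_group = -3), "non-negative")
  expect_error(cohort_spec(n_per_group = 5, within_group_dispersion = -1),
               ">= 0")
  expect_error(cohort_spec(n_per_group = 5, n_ct_regions = 1), ">= 2")
  expect_error(cohort_spec(n_per_group = 1, groups = "HC"), "peers")
  expect_error(cohort_spec(n_per_group = 5,
                           template_profile = list(CT = 1:3)),
               "length")
})

test_that("mean within-group PBSI is non-increasing in dispersion", {
  disp_grid <- c(0.05, 0.2, 0.6, 1.5)
  for (seed in 1:5) {
    means <- vapply(disp_grid, function(d) {
      co <- generate_cohort(cohort_spec(n_per_group = 15, groups = "G",
                                        n_ct_regions = 32, n_sv_regions = 4,
                                        within_group_dispersion = d,
                                        seed = seed))
      res <- compute_pbsi_table(co$table, modalities = "CT")
      mean(res$pbsi)
    }, numeric(1))
    expect_true(all(diff(means) <= 0),
                info = sprintf("seed %d: %s", seed, paste(round(means, 3),
                                                          collapse = " ")))
  }
})

test_that("a region-varying sex effect separates pooled male/female PBSI", {
  set.seed(42)
  sex_vec <- rnorm(16, sd = 3)
  co <- generate_cohort(cohort_spec(
    n_per_group = 40, groups = "G", n_ct_regions = 16, n_sv_regions = 4,
    within_group_dispersion = 0.3, sex_effect = list(CT = sex_vec), seed = 9))
  res <- compute_pbsi_table(co$table, modalities = "CT")
  res <- merge(res, co$table[c("subject_id", "sex")], by = "subject_id")
  diff_m <- abs(mean(res$pbsi[res$sex == "F"]) - mean(res$pbsi[res$sex == "M"]))
  expect_gt(diff_m, 0.02)
})

test_that("inject_dominant_region boosts exactly one region's noise", {
  co <- small_cohort()
  expect_identical(inject_dominant_region(co, "ct__region03", 1)$table, co$table)
  expect_error(inject_dominant_region(co, "ct__nosuch", 20), "unknown region")
  expect_error(inject_dominant_region(co, "ct__region03", -2), "non-negative")

  boosted <- inject_dominant_region(co, "ct__region03", 20)
  others <- setdiff(names(co$table), "ct__region03")
  expect_identical(boosted$table[others], co$table[others])

  # the boosted region has the largest within-group CV among CT regions
  ctcols <- grep("^ct__", names(boosted$table), value = TRUE)
  g <- boosted$table[boosted$table$group == "HC", ]
  cvs <- vapply(ctcols, function(cl) sd(g[[cl]]) / mean(g[[cl]]), numeric(1))
  expect_identical(names(which.max(cvs)), "ct__region03")
})
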
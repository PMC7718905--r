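# Independent brute-force oracles. These deliberately avoid rank()/cor()
# and the package's own code paths: midranks are built by pair counting and
# Pearson uses the closed-form sum formula.

naive_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

naive_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

naive_spearman <- function(x, y) naive_pearson(naive_midranks(x), naive_midranks(y))

# Double-loop PBSI: every pairwise correlation recomputed independently.
naive_pbsi <- function(mat) {
  n <- nrow(mat)
  vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i),
                function(j) naive_spearman(mat[i, ], mat[j, ]), numeric(1)))
  }, numeric(1))
}

# All-pairs Cliff's delta.
naive_cliffs <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) - sum(xi < y)
  s / (length(x) * length(y))
}

random_profiles <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  m
}

two_group_spec <- function(seed, n = 60, disp = c(A = 0.1, B = 1.0)) {
  cohort_spec(n_per_group = n, groups = names(disp), sites = "siteA",
              n_ct_regions = 64, n_sv_regions = 18,
              within_group_dispersion = disp, seed = seed)
}

# Small cohort used across io/pipeline tests.
small_cohort <- function(seed = 7, n = 8, groups = c("HC", "SZ")) {
  generate_cohort(cohort_spec(
    n_per_group = n, groups = groups, sites = "siteA",
    n_ct_regions = 6, n_sv_regions = 4,
    within_group_dispersion = 0.5, seed = seed))
}
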
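#' Non-parametric inferential toolkit
#'
#' The comparison battery used on similarity scores: a Kolmogorov–Smirnov
#' normality screen to route between parametric and rank-based tests, the
#' Mann–Whitney U test with tie-corrected normal approximation (exact
#' enumeration for small tie-free inputs), Cliff's delta as the effect size,
#' the Feltz–Miller asymptotic test for equality of coefficients of
#' variation, Spearman associations, and Benjamini–Hochberg FDR adjustment.
#'
#' Sign convention, fixed throughout: the first sample (`x`, "group A") is
#' the reference; negative Z or delta means group A is stochastically
#' smaller than group B.
#'
#' @name group-stats
NULL

#' Kolmogorov–Smirnov normality screen
#'
#' One-sample KS statistic of `x` against a normal with the sample's own
#' mean and standard deviation.  With estimated parameters the p-value is
#' conservative (the Lilliefors caveat); it is used only to route between
#' the t-test and the Mann–Whitney test, never as a reported result.
#'
#' @param x Numeric vector, n >= 5, finite.
#' @return A list with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop_data("normality screen needs n >= 5, got %d", length(x))
  if (!all(is.finite(x))) stop_data("non-finite values in input")
  if (stats::sd(x) == 0) return(list(statistic = 1, p = 0))
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Mann–Whitney U test
#'
#' `U` counts, over all cross pairs, how often an `x` value exceeds a `y`
#' value (ties count one half); equivalently the rank-sum of `x` in the
#' pooled midranks minus `n_x(n_x+1)/2`.  `Z = (U - n_x n_y/2) / sigma_U`
#' with the tie-corrected variance
#' `sigma_U^2 = n_x n_y / 12 * ((N+1) - sum(t^3 - t) / (N(N-1)))`
#' and a continuity correction of 1/2 toward the null.  The two-sided p uses
#' exact enumeration of the U distribution when `n_x * n_y <= 400` and there
#' are no ties, otherwise the normal approximation.
#'
#' @param x,y Numeric vectors (n >= 1 each), finite; `x` is group A.
#' @return A list with `U`, `Z`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop_data("both samples must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_data("non-finite values in input")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  N <- nx + ny
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))

  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1, method = "degenerate"))
  cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
  Z <- (U - mu - cc) / sqrt(sigma2)

  if (nx * ny <= 400 && tie_term == 0) {
    # exact null distribution of U (no ties)
    p <- if (U == mu) 1
         else if (U > mu) 2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
         else 2 * stats::pwilcox(U, nx, ny)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal"
  }
  list(U = U, Z = Z, p = min(1, p), method = method)
}

#' Cliff's delta effect size
#'
#' `d = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x n_y)`: the probability that
#' a random group-A value exceeds a random group-B value minus the reverse.
#' Computed in O(n log n) via pooled midranks -- `d = (2U - n_x n_y) /
#' (n_x n_y)` with the half-tie counting of [mann_whitney()] -- which equals
#' the all-pairs definition exactly (midranks are sums of halves, exact in
#' binary floating point).
#'
#' @param x,y Numeric vectors (n >= 1 each), finite.
#' @return A scalar in \[-1, 1\]; positive means group A stochastically larger.
#' @export
cliffs_delta <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop_data("both samples must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_data("non-finite values in input")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  (2 * U - nx * ny) / (nx * ny)
}

#' Asymptotic test for equality of coefficients of variation
#'
#' Feltz–Miller chi-square statistic: with per-group CV `c_i = s_i / xbar_i`
#' and weights `m_i = n_i - 1`, the pooled CV is `cbar = sum(m_i c_i) /
#' sum(m_i)` and the statistic `sum(m_i (c_i - cbar)^2) / (cbar^2 (0.5 +
#' cbar^2))` is referred to chi-square with k - 1 degrees of freedom.  CV is
#' only defined for strictly positive means (thicknesses, volumes).
#'
#' @param samples List of k >= 2 numeric vectors, each n >= 2 with a strictly
#'   positive mean.
#' @return A list with `statistic`, `df`, `p` and `cv` (per-group CVs).
#' @export
cv_equality_test <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop_data("need a list of >= 2 samples")
  n <- lengths(samples)
  if (any(n < 2)) stop_data("every sample needs n >= 2")
  means <- vapply(samples, mean, numeric(1))
  if (any(!is.finite(means)) || any(means <= 0))
    stop_data("coefficient of variation undefined: non-positive sample mean")
  cv <- vapply(samples, stats::sd, numeric(1)) / means
  m <- n - 1
  cbar <- sum(m * cv) / sum(m)
  if (cbar == 0) {
    stat <- 0
  } else {
    stat <- sum(m * (cv - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  }
  df <- length(samples) - 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), cv = cv)
}

#' Spearman association with t-approximation p-value
#'
#' Rank correlation via [spearman_rho()]; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 5.
#' @return A list with `rho`, `p`, `n`.  Constant input gives `rho = NA`
#'   (undefined) with a warning.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) < 5) stop_data("association needs n >= 5, got %d", length(x))
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, n = n))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, clip at 1, restore input order.  `NA`s are passed through
#' and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop_data("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
    # p * m / j can round a hair below p; the step-up value is >= p by
    # definition, so enforce the bound exactly
    out[ok] <- pmax(adj[order(o)], pv)
  }
  out
}

#' Tukey-fence outlier flags
#'
#' Points beyond 1.5 times the interquartile range outside the quartiles
#' (linear-interpolation quantiles), the convention of the standard boxplot.
#'
#' @param x Numeric vector.
#' @param k Fence multiplier, default 1.5.
#' @return Logical vector, `TRUE` for outliers.
#' @export
tukey_outliers <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Compare PBSI scores between two groups
#'
#' Runs the Mann–Whitney test and Cliff's delta on the similarity scores of
#' two diagnostic groups, within one site and one modality (cross-site
#' contrasts require the explicit `cross_site` override — scores from
#' different sites are never comparable by default).  The comparison is
#' reported twice: on all subjects and after removing per-group Tukey-fence
#' outliers, so robustness to outlier exclusion is always visible.
#'
#' @param results A long `pbsi_result` table (from [compute_pbsi_table()]).
#' @param group_a,group_b Group labels; `group_a` is the reference (negative
#'   Z / delta means `group_a` stochastically smaller).
#' @param modality `"CT"` or `"SV"`.
#' @param site Site label; may be omitted when both groups live in a single
#'   common site.
#' @param outlier_policy `"tukey"` (default) or `"none"` (skip the trimmed
#'   pass).
#' @param cross_site Set `TRUE` to pool scores across sites (each score is
#'   still computed within its own site cell).
#' @return A `data.frame` of class `group_comparison` with one row per
#'   analysis pass (`subset` = `"all"` / `"trimmed"`): `group_a`, `group_b`,
#'   `modality`, `site`, `subset`, `n_a`, `n_b`, `U`, `Z`, `p_raw`,
#'   `cliffs_d`, `n_removed`.  FDR adjustment across a declared family is
#'   applied downstream, not here.
#' @export
compare_pbsi <- function(results, group_a, group_b, modality,
                         site = NULL, outlier_policy = c("tukey", "none"),
                         cross_site = FALSE) {
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(is.data.frame(results))
  res <- results[results$modality == modality & !is.na(results$pbsi), ]
  a <- res[res$group == group_a, ]; b <- res[res$group == group_b, ]
  if (!nrow(a) || !nrow(b))
    stop_data("no scores for contrast %s vs %s (%s)", group_a, group_b, modality)
  if (!cross_site) {
    if (is.null(site)) {
      common <- intersect(unique(a$site), unique(b$site))
      if (length(common) != 1)
        stop_data(paste("groups %s and %s do not share exactly one site;",
                        "pass `site` or set cross_site = TRUE"),
                  group_a, group_b)
      site <- common
    }
    a <- a[a$site == site, ]; b <- b[b$site == site, ]
    if (!nrow(a) || !nrow(b))
      stop_data("no scores at site %s for %s vs %s", site, group_a, group_b)
  } else site <- site %||% "pooled"

  one_pass <- function(xa, xb, subset, removed) {
    mw <- mann_whitney(xa, xb)
    data.frame(group_a = group_a, group_b = group_b, modality = modality,
               site = site, subset = subset,
               n_a = length(xa), n_b = length(xb),
               U = mw$U, Z = mw$Z, p_raw = mw$p,
               cliffs_d = cliffs_delta(xa, xb), n_removed = removed,
               stringsAsFactors = FALSE)
  }
  out <- one_pass(a$pbsi, b$pbsi, "all", 0L)
  if (outlier_policy == "tukey") {
    ka <- !tukey_outliers(a$pbsi); kb <- !tukey_outliers(b$pbsi)
    out <- rbind(out, one_pass(a$pbsi[ka], b$pbsi[kb], "trimmed",
                               sum(!ka) + sum(!kb)))
  }
  class(out) <- c("group_comparison", "data.frame")
  out
}
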
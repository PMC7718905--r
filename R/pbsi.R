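#' Person-based similarity index
#'
#' A subject's morphometric profile is their ordered vector of regional
#' measures of one modality.  Within a cell -- one diagnostic group at one
#' site, one modality -- every pair of profiles is compared by Spearman rank
#' correlation, and each subject's PBSI is the mean of their n - 1 pairwise
#' correlations with the other cell members.  Because only within-subject
#' ranks enter, the index captures the relative inter-regional pattern and is
#' independent of global scale (intracranial volume, mean thickness) and of
#' any monotone per-subject transform.
#'
#' @name pbsi-core
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed vectors (average ranks for
#' ties).  Returns `NA` with a warning if either vector is constant (zero
#' rank variance makes the coefficient undefined).
#'
#' @param x,y Numeric vectors of equal length >= 2, all values finite.
#' @return A scalar in \[-1, 1\], or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_data("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2) stop_data("need length >= 2, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_data("non-finite values in input")
  # Midranks always average to (n + 1) / 2 (ties or not), so centring is
  # exact in binary floating point; with sqrt(S_xx * S_yy) computed as one
  # product, perfectly monotone pairs yield exactly +/-1.
  n <- length(x)
  cx <- rank(x) - (n + 1) / 2
  cy <- rank(y) - (n + 1) / 2
  sxx <- sum(cx * cx); syy <- sum(cy * cy)
  if (sxx == 0 || syy == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  min(1, max(-1, sum(cx * cy) / sqrt(sxx * syy)))
}

# Profile matrix for one modality: subjects x regions, rownames subject ids.
profile_matrix <- function(table, rs) {
  m <- as.matrix(table[, region_cols(rs), drop = FALSE])
  rownames(m) <- table$subject_id
  m
}

#' Compute PBSI scores for one cell
#'
#' Takes the profiles of all members of one cell as a subjects x regions
#' matrix, rank-transforms each subject's profile once, computes the full
#' pairwise Spearman correlation matrix in a single `cor()` call, and
#' averages each row off the diagonal.  The matrix is exactly symmetric, so
#' the correlation between subjects i and j contributes identically to both
#' means, and the result does not depend on subject order.
#'
#' Subjects with a constant profile (zero rank variance, undefined
#' correlations) are excluded from the cell with a warning and reported with
#' `pbsi = NA`; imputing zero correlations instead would bias every mean.
#'
#' @param profiles Numeric matrix, one row per subject (rownames are subject
#'   ids) and one column per region in canonical order; >= 2 rows, >= 2
#'   columns, all finite.
#' @param cell Optional named list/vector describing the cell (group, site,
#'   modality); attached to the result for provenance.
#' @return A `data.frame` with columns `subject_id`, `pbsi`, `n_peers`, of
#'   class `pbsi_result`, with attributes `cell` and `regions`.
#' @export
compute_pbsi <- function(profiles, cell = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2)
    stop_data("need >= 2 profiles in a cell, got %d", nrow(profiles))
  if (ncol(profiles) < 2)
    stop_data("profiles need >= 2 regions, got %d", ncol(profiles))
  if (!all(is.finite(profiles))) stop_data("non-finite values in profiles")
  ids <- rownames(profiles) %||% sprintf("subject%03d", seq_len(nrow(profiles)))

  p <- ncol(profiles)
  cranks <- apply(profiles, 1L, rank) - (p + 1) / 2   # regions x subjects, exact
  S <- crossprod(cranks)
  ok <- diag(S) > 0
  if (any(!ok)) {
    warning(sprintf("excluding %d constant profile(s): %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")), call. = FALSE)
    if (sum(ok) < 2)
      stop_data("fewer than 2 usable profiles after excluding constant ones")
    S <- S[ok, ok, drop = FALSE]
  }
  # Spearman matrix: centred-rank crossproducts are exact half-integer sums,
  # and sqrt(S_ii * S_jj) recovers S_ii exactly on the diagonal, so identical
  # profiles correlate at exactly 1.
  C <- S / sqrt(outer(diag(S), diag(S)))
  C[C > 1] <- 1; C[C < -1] <- -1
  n <- sum(ok)
  # summing each subject's correlations in sorted order makes the result
  # exactly invariant to subject input order (float addition is not
  # associative); the diagonal 1 is dropped after the sum
  scores <- vapply(seq_len(n), function(i) (sum(sort(C[, i])) - 1) / (n - 1),
                   numeric(1))
  scores <- pmin(1, pmax(-1, scores))

  out <- data.frame(subject_id = ids, pbsi = NA_real_, n_peers = NA_integer_,
                    stringsAsFactors = FALSE)
  out$pbsi[ok] <- scores
  out$n_peers[ok] <- n - 1L
  attr(out, "cell") <- cell
  attr(out, "regions") <- colnames(profiles)
  class(out) <- c("pbsi_result", "data.frame")
  out
}

#' Compute PBSI per (group, site, modality) cell of a morphometry table
#'
#' Splits the table strictly by the `by` columns (default diagnostic group
#' within site -- scores are never computed across groups or sites unless the
#' caller pools explicitly) and computes PBSI per modality in each cell.
#'
#' @param table A morphometry `data.frame` (see [read_morphometry()]).
#' @param schema Optional region schema; defaults to the table's attached or
#'   derived schema.
#' @param by Character vector of stratification columns; default
#'   `c("group", "site")`.
#' @param modalities Modalities to score; default all in the schema.
#' @param pool_groups Optional character vector of group labels to merge into
#'   one pooled cell (label `"A+B"`) before scoring, e.g. for a combined
#'   patient group; never a default.
#' @return A long `data.frame` of class `pbsi_result` with columns
#'   `subject_id`, `group`, `site`, `modality`, `pbsi`, `n_peers`.
#' @export
compute_pbsi_table <- function(table, schema = NULL, by = c("group", "site"),
                               modalities = NULL, pool_groups = NULL) {
  schema <- schema %||% attr(table, "schema") %||% schema_from_table(table)
  validate_morphometry(table, schema)
  if (!all(by %in% names(table)))
    stop_config("stratification columns missing: %s",
                paste(setdiff(by, names(table)), collapse = ", "))
  if (!is.null(pool_groups)) {
    unknown <- setdiff(pool_groups, unique(table$group))
    if (length(unknown))
      stop_config("pool_groups not in table: %s", paste(unknown, collapse = ", "))
    table$group[table$group %in% pool_groups] <-
      paste(pool_groups, collapse = "+")
  }
  modalities <- modalities %||% names(schema)

  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  pieces <- list()
  for (cell_rows in split(seq_len(nrow(table)), key)) {
    sub <- table[cell_rows, , drop = FALSE]
    cell_lab <- paste(vapply(by, function(b) sub[[b]][1], ""), collapse = "/")
    if (nrow(sub) < 2) {
      warning(sprintf("cell %s has < 2 subjects; skipped", cell_lab), call. = FALSE)
      next
    }
    for (m in modalities) {
      res <- compute_pbsi(profile_matrix(sub, schema[[m]]),
                          cell = c(stats::setNames(as.list(sub[1, by]), by),
                                   modality = m))
      pieces[[length(pieces) + 1L]] <- data.frame(
        subject_id = res$subject_id,
        group = sub$group, site = sub$site, modality = m,
        pbsi = res$pbsi, n_peers = res$n_peers,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) stop_data("no cell had >= 2 subjects")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("pbsi_result", "data.frame")
  out
}
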
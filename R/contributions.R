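#' Regional contribution diagnostics
#'
#' Two complementary checks that the similarity index is not driven by a
#' handful of regions: (i) leave-one-out -- recompute every subject's score
#' with one region removed and report the mean absolute change per region;
#' (ii) subset resampling -- recompute scores on random region subsets of
#' increasing size and summarize how well they agree with the full-profile
#' scores.
#'
#' @name contributions
NULL

#' Leave-one-out regional contributions for one cell
#'
#' For each region r, PBSI is recomputed on profiles with r removed; the
#' contribution of r is the mean over subjects of |PBSI_without_r -
#' PBSI_full|.  Identical by definition to calling [compute_pbsi()] on
#' pre-truncated profiles.
#'
#' @param profiles Subjects x regions numeric matrix (>= 3 regions).
#' @param cell Optional cell descriptor for provenance.
#' @return A `data.frame` with columns `region` and `mean_abs_delta`
#'   (class `loo_contributions`), region order preserved.
#' @export
leave_one_out_contributions <- function(profiles, cell = NULL) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3)
    stop_data("leave-one-out needs >= 3 regions, got %d", ncol(profiles))
  full <- compute_pbsi(profiles, cell)$pbsi
  regions <- colnames(profiles) %||% sprintf("region%02d", seq_len(ncol(profiles)))
  deltas <- vapply(seq_len(ncol(profiles)), function(r) {
    red <- compute_pbsi(profiles[, -r, drop = FALSE], cell)$pbsi
    mean(abs(red - full))
  }, numeric(1))
  out <- data.frame(region = regions, mean_abs_delta = deltas,
                    stringsAsFactors = FALSE)
  attr(out, "cell") <- cell
  class(out) <- c("loo_contributions", "data.frame")
  out
}

#' Subset-resampling stability for one cell
#'
#' For each subset size in `sizes` and each of `reps` repetitions, samples
#' that many regions uniformly without replacement, recomputes PBSI on the
#' restricted profiles, and records the per-subject scores together with the
#' regions used.  Subsets are sampled independently per (size, repetition)
#' from streams split deterministically off the master seed, so any single
#' run is individually reproducible.  The stability summary per size gives
#' the mean (over repetitions) Spearman correlation across subjects between
#' subset and full-profile scores, and the mean absolute difference; both
#' are reported, neither privileged.
#'
#' @param profiles Subjects x regions numeric matrix.
#' @param sizes Integer vector of subset sizes, each in \[2, n regions\].
#' @param reps Repetitions per size (>= 1).
#' @param seed Master seed for the subset draws.
#' @param cell Optional cell descriptor; also salts the random streams so
#'   different cells draw different subsets.
#' @return A list of class `subset_resampling`: `runs` (long `data.frame`
#'   with `size`, `rep`, `subject_id`, `pbsi`), `subsets` (`size`, `rep`,
#'   `regions` — semicolon-joined), and `stability` (`size`,
#'   `mean_spearman_with_full`, `mean_abs_diff`).
#' @export
subset_resampling <- function(profiles, sizes, reps = 100, seed = 1L,
                              cell = NULL) {
  profiles <- as.matrix(profiles)
  nreg <- ncol(profiles)
  sizes <- as.integer(sizes)
  if (any(sizes > nreg)) stop_data("subset size exceeds region count %d", nreg)
  if (any(sizes < 2)) stop_data("subset sizes must be >= 2")
  if (reps < 1) stop_config("reps must be >= 1")
  regions <- colnames(profiles) %||% sprintf("region%02d", seq_len(nreg))
  colnames(profiles) <- regions
  full <- compute_pbsi(profiles, cell)$pbsi
  ids <- rownames(profiles) %||% sprintf("subject%03d", seq_len(nrow(profiles)))
  cell_tag <- paste(unlist(cell), collapse = "/")

  runs <- vector("list", length(sizes) * reps)
  subsets <- vector("list", length(sizes) * reps)
  stab <- vector("list", length(sizes))
  i <- 0L
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    rho_reps <- mad_reps <- numeric(reps)
    for (r in seq_len(reps)) {
      pick <- with_seed(mix_seed(seed, "subset", cell_tag, size, r),
                        sort(sample.int(nreg, size)))
      sub_pbsi <- compute_pbsi(profiles[, pick, drop = FALSE], cell)$pbsi
      i <- i + 1L
      runs[[i]] <- data.frame(size = size, rep = r, subject_id = ids,
                              pbsi = sub_pbsi, stringsAsFactors = FALSE)
      subsets[[i]] <- data.frame(size = size, rep = r,
                                 regions = paste(regions[pick], collapse = ";"),
                                 stringsAsFactors = FALSE)
      rho_reps[r] <- if (size == nreg) 1 else
        suppressWarnings(spearman_rho(sub_pbsi, full))
      mad_reps[r] <- mean(abs(sub_pbsi - full))
    }
    stab[[si]] <- data.frame(size = size,
                             mean_spearman_with_full = mean(rho_reps, na.rm = TRUE),
                             mean_abs_diff = mean(mad_reps))
  }
  structure(list(runs = do.call(rbind, runs),
                 subsets = do.call(rbind, subsets),
                 stability = do.call(rbind, stab)),
            class = "subset_resampling")
}

#' Full contribution report per cell of a morphometry table
#'
#' Runs the leave-one-out analysis and (optionally) subset resampling in
#' every (group, site, modality) cell.  The default subset grids follow the
#' two modalities' conventions: cortical thickness uses sizes 10 to 60 in
#' steps of 10 (capped at the region count), subcortical volume uses half
#' the regions; 100 repetitions each.
#'
#' @param table A morphometry `data.frame`.
#' @param schema Optional region schema.
#' @param by Stratification columns, default `c("group", "site")`.
#' @param sizes Named list per modality of subset-size grids, or `NULL` for
#'   the defaults above.
#' @param reps Repetitions per size (default 100).
#' @param seed Master seed.
#' @param run_subsets Set `FALSE` to skip the resampling stage.
#' @return A list of class `contribution_report` with `loo` (long
#'   `data.frame`: `region`, `group`, `site`, `modality`, `mean_abs_delta`),
#'   `subset_runs`, `subset_stability`.
#' @export
contribution_report <- function(table, schema = NULL, by = c("group", "site"),
                                sizes = NULL, reps = 100, seed = 1L,
                                run_subsets = TRUE) {
  schema <- schema %||% attr(table, "schema") %||% schema_from_table(table)
  validate_morphometry(table, schema)
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)

  loo <- list(); sruns <- list(); sstab <- list()
  for (cell_rows in split(seq_len(nrow(table)), key)) {
    sub <- table[cell_rows, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (m in names(schema)) {
      cell <- c(stats::setNames(as.list(sub[1, by]), by), modality = m)
      mat <- profile_matrix(sub, schema[[m]])
      lo <- leave_one_out_contributions(mat, cell)
      loo[[length(loo) + 1L]] <- data.frame(
        region = sub("^(ct|sv)__", "", lo$region),
        group = sub$group[1], site = sub$site[1],
        modality = m, mean_abs_delta = lo$mean_abs_delta,
        stringsAsFactors = FALSE)
      if (run_subsets) {
        grid <- sizes[[m]] %||% default_subset_sizes(m, ncol(mat))
        sr <- subset_resampling(mat, grid, reps = reps, seed = seed, cell = cell)
        ann <- function(df) data.frame(group = sub$group[1], site = sub$site[1],
                                       modality = m, df, stringsAsFactors = FALSE)
        sruns[[length(sruns) + 1L]] <- ann(sr$runs)
        sstab[[length(sstab) + 1L]] <- ann(sr$stability)
      }
    }
  }
  structure(list(
    loo = do.call(rbind, loo),
    subset_runs = if (length(sruns)) do.call(rbind, sruns),
    subset_stability = if (length(sstab)) do.call(rbind, sstab)),
    class = "contribution_report")
}

# CT: random subsets in increments of 10 from 10 up to (region count - few);
# SV: one size = half the regions.  Degrades gracefully for small schemas.
default_subset_sizes <- function(modality, nreg) {
  if (modality == "CT" && nreg > 10) {
    s <- seq(10, min(60, nreg - 1), by = 10)
    if (length(s)) s else max(2, nreg - 1)
  } else {
    max(2, floor(nreg / 2))
  }
}
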
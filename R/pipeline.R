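#' End-to-end analysis pipeline
#'
#' One call runs the whole battery on a real or simulated cohort: ingest or
#' simulate -> similarity scores per (group, site, modality) cell ->
#' leave-one-out and subset-resampling diagnostics -> regional
#' coefficient-of-variation tables with equality tests -> group contrasts,
#' covariate associations and FDR adjustment -> a machine-readable report.
#' Every stage's outputs are written before the next begins, and re-running
#' with the same config and seed reproduces every output byte for byte (no
#' timestamps enter any file).
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param input Path to a morphometry CSV/TSV, or `NULL` when `spec` is given.
#' @param spec A [cohort_spec()] to simulate from (alternative to `input`).
#' @param schema Optional path to a region schema YAML.
#' @param modalities Modalities to analyse, default all in the schema.
#' @param contrasts List of contrasts, each a list with `a`, `b` (group
#'   labels), optional `site` and optional FDR `family` (default
#'   `"contrasts"`).
#' @param covariates Character vector of covariate columns to associate with
#'   the scores (numeric columns via Spearman, two-level columns via
#'   Mann–Whitney), or a list of lists with `variable` and optional `filter`
#'   (an expression string evaluated in the table, e.g. `"age >= 40"`).
#' @param pool_groups Optional character vector of groups to pool into one
#'   cell before scoring (an additional pooled scoring pass; the unpooled
#'   scores are always computed too).
#' @param subset_reps Subset-resampling repetitions per size (default 100).
#' @param subset_sizes Optional named list per modality of size grids.
#' @param run_subsets Logical, default `TRUE`.
#' @param outlier_policy `"tukey"` or `"none"`.
#' @param seed Master seed for every random element of the run.
#' @param output_dir Where outputs are written.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, spec = NULL, schema = NULL,
                       modalities = NULL, contrasts = list(),
                       covariates = c("age", "sex"), pool_groups = NULL,
                       subset_reps = 100, subset_sizes = NULL,
                       run_subsets = TRUE,
                       outlier_policy = c("tukey", "none"),
                       seed = 1L, output_dir = "pbsi_run") {
  if (is.null(input) && is.null(spec))
    stop_config("config needs either `input` (a table) or `spec` (a simulation)")
  if (!is.null(spec) && !inherits(spec, "cohort_spec"))
    stop_config("`spec` must be a cohort_spec")
  for (ct in contrasts)
    if (is.null(ct$a) || is.null(ct$b))
      stop_config("every contrast needs group labels `a` and `b`")
  if (is.character(covariates))
    covariates <- lapply(covariates, function(v) list(variable = v))
  structure(list(input = input, spec = spec, schema = schema,
                 modalities = modalities, contrasts = contrasts,
                 covariates = covariates, pool_groups = pool_groups,
                 subset_reps = subset_reps, subset_sizes = subset_sizes,
                 run_subsets = isTRUE(run_subsets),
                 outlier_policy = match.arg(outlier_policy),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts the same fields as [run_config()]; a `spec` block is passed to
#' [cohort_spec()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$spec)) {
    sp <- raw$spec
    if (!is.null(sp$n_per_group) && is.list(sp$n_per_group))
      sp$n_per_group <- unlist(sp$n_per_group)
    raw$spec <- do.call(cohort_spec, sp)
  }
  do.call(run_config, raw)
}

#' Tukey five-number boxplot summary
#'
#' Median and quartiles under the linear-interpolation quantile rule (type
#' 7), whiskers at the most extreme data points within 1.5 IQR of the
#' quartiles, and the points beyond the fences as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return A list: `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
summarize_boxplot <- function(values) {
  if (!length(values)) stop_data("empty input")
  if (!all(is.finite(values))) stop_data("non-finite values in input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

# Regional CV table and Feltz-Miller equality tests across groups, per
# (site, modality, region); FDR adjusted within modality.
cv_tables <- function(table, schema) {
  rows <- list()
  for (s in unique(table$site)) {
    sub <- table[table$site == s, , drop = FALSE]
    groups <- unique(sub$group)
    groups <- groups[vapply(groups, function(g) sum(sub$group == g) >= 2, TRUE)]
    if (length(groups) < 2) next
    for (m in names(schema)) for (cl in region_cols(schema[[m]])) {
      samples <- lapply(groups, function(g) sub[[cl]][sub$group == g])
      tst <- cv_equality_test(samples)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, modality = m,
        region = sub("^(ct|sv)__", "", cl),
        t(stats::setNames(tst$cv, paste0("cv_", groups))),
        statistic = tst$statistic, df = tst$df, p_raw = tst$p,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (m in unique(out$modality)) {
    i <- out$modality == m
    out$p_adj[i] <- fdr_adjust(out$p_raw[i])
  }
  rownames(out) <- NULL
  out
}

# Covariate associations with the scores, per modality, pooled across cells.
covariate_associations <- function(pbsi_tab, table, covariates) {
  rows <- list()
  merged <- merge(pbsi_tab, table[!duplicated(table$subject_id), ,
                                  drop = FALSE][, c("subject_id",
                   setdiff(names(table), c(names(pbsi_tab), "subject_id"))),
                   drop = FALSE], by = "subject_id", sort = TRUE)
  for (cv in covariates) {
    v <- cv$variable
    if (!v %in% names(merged))
      stop_config("covariate '%s' not found in the table", v)
    dat <- merged[!is.na(merged$pbsi), , drop = FALSE]
    if (!is.null(cv$filter))
      dat <- dat[eval(parse(text = cv$filter), dat), , drop = FALSE]
    for (m in unique(dat$modality)) {
      d <- dat[dat$modality == m, ]
      if (nrow(d) < 5) next
      if (is.numeric(d[[v]])) {
        as_ <- spearman_assoc(d[[v]], d$pbsi)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, filter = cv$filter %||% "", modality = m,
          test = "spearman", estimate = as_$rho, Z = NA_real_,
          p_raw = as_$p, n = as_$n, stringsAsFactors = FALSE)
      } else {
        lev <- sort(unique(as.character(d[[v]])))
        if (length(lev) != 2) {
          warning(sprintf("covariate '%s' is not numeric or two-level; skipped", v),
                  call. = FALSE)
          next
        }
        xa <- d$pbsi[d[[v]] == lev[1]]; xb <- d$pbsi[d[[v]] == lev[2]]
        mw <- mann_whitney(xa, xb)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, filter = cv$filter %||% "", modality = m,
          test = sprintf("mann_whitney:%svs%s", lev[1], lev[2]),
          estimate = cliffs_delta(xa, xb), Z = mw$Z,
          p_raw = mw$p, n = nrow(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p_raw)
  out
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing each stage's CSVs into
#' `config$output_dir` before the next stage starts, and finishes with
#' `report.md` (per-cell boxplot summaries and provenance) plus a `STATUS`
#' file that reads `complete` only when every stage succeeded.  Any stage
#' error aborts with the stage name; partial outputs stay on disk with
#' `STATUS` = `incomplete: <stage>`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `table`, `pbsi`,
#'   `contributions`, `cv`, `comparisons`, `associations`, `cell_summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status_path <- file.path(out_dir, "STATUS")
  stage <- "setup"
  writeLines(paste("incomplete:", stage), status_path)
  run_stage <- function(name, expr) {
    stage <<- name
    writeLines(paste("incomplete:", name), status_path)
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c(class(e)[1], "pbsi_error")))
    })
  }

  # -- stage 1: ingest or simulate ------------------------------------------
  ingest <- run_stage("ingest", {
    if (!is.null(config$spec)) {
      cohort <- generate_cohort(config$spec)
      write_cohort(cohort, out_dir)
      list(table = cohort$table, schema = attr(cohort$table, "schema"))
    } else {
      schema <- if (!is.null(config$schema)) read_region_schema(config$schema)
      table <- read_morphometry(config$input, schema)
      write_morphometry(table, file.path(out_dir, "cohort.csv"))
      list(table = table, schema = attr(table, "schema"))
    }
  })
  table <- ingest$table
  schema <- ingest$schema
  if (!is.null(config$modalities))
    schema <- schema[intersect(names(schema), config$modalities)]

  # -- stage 2: similarity scores per cell ----------------------------------
  pbsi_tab <- run_stage("pbsi", {
    res <- compute_pbsi_table(table, schema)
    if (!is.null(config$pool_groups)) {
      pooled <- compute_pbsi_table(table, schema,
                                   pool_groups = config$pool_groups)
      pooled <- pooled[grepl("+", pooled$group, fixed = TRUE), , drop = FALSE]
      res <- rbind(res, pooled)
    }
    write_results(res, file.path(out_dir, "pbsi.csv"))
    res
  })

  # -- stage 3: contribution diagnostics ------------------------------------
  contrib <- run_stage("contributions", {
    cr <- contribution_report(table, schema, sizes = config$subset_sizes,
                              reps = config$subset_reps, seed = config$seed,
                              run_subsets = config$run_subsets)
    write_results(cr$loo, file.path(out_dir, "contributions_loo.csv"))
    if (!is.null(cr$subset_stability)) {
      write_results(cr$subset_stability, file.path(out_dir, "subset_stability.csv"))
      write_results(cr$subset_runs, file.path(out_dir, "subset_runs.csv"))
    }
    cr
  })

  # -- stage 4: regional variability ----------------------------------------
  cv <- run_stage("cv", {
    tab <- cv_tables(table, schema)
    if (!is.null(tab)) write_results(tab, file.path(out_dir, "cv_tests.csv"))
    tab
  })

  # -- stage 5: contrasts, associations, FDR --------------------------------
  comparisons <- run_stage("comparisons", {
    if (!length(config$contrasts)) return(NULL)
    rows <- lapply(config$contrasts, function(ct) {
      fam <- ct$family %||% "contrasts"
      do.call(rbind, lapply(names(schema), function(m) {
        cmp <- compare_pbsi(pbsi_tab, ct$a, ct$b, m, site = ct$site,
                            outlier_policy = config$outlier_policy)
        cmp$family <- fam
        cmp
      }))
    })
    out <- do.call(rbind, rows)
    out$p_adj <- NA_real_
    for (key in split(seq_len(nrow(out)),
                      paste(out$family, out$subset)))
      out$p_adj[key] <- fdr_adjust(out$p_raw[key])
    write_results(out, file.path(out_dir, "comparisons.csv"))
    out
  })
  associations <- run_stage("associations", {
    if (!length(config$covariates)) return(NULL)
    out <- covariate_associations(pbsi_tab, table, config$covariates)
    if (!is.null(out)) write_results(out, file.path(out_dir, "associations.csv"))
    out
  })

  # -- stage 6: report -------------------------------------------------------
  cell_summary <- run_stage("report", {
    scored <- pbsi_tab[!is.na(pbsi_tab$pbsi), , drop = FALSE]
    cells <- split(scored, interaction(scored$group, scored$site,
                                       scored$modality,
                                       drop = TRUE, lex.order = TRUE))
    summ <- do.call(rbind, lapply(cells, function(d) {
      bx <- summarize_boxplot(d$pbsi)
      data.frame(group = d$group[1], site = d$site[1], modality = d$modality[1],
                 n = nrow(d), median = bx$median, q25 = bx$q25, q75 = bx$q75,
                 whisker_lo = bx$whisker_lo, whisker_hi = bx$whisker_hi,
                 n_outliers = length(bx$outliers), stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    write_results(summ, file.path(out_dir, "cell_summary.csv"))
    write_report_md(file.path(out_dir, "report.md"), config, summ, comparisons)
    summ
  })

  writeLines("complete", status_path)
  invisible(list(table = table, pbsi = pbsi_tab, contributions = contrib,
                 cv = cv, comparisons = comparisons,
                 associations = associations, cell_summary = cell_summary))
}

# Human-readable summary; deliberately timestamp-free so identical runs
# produce identical bytes.
write_report_md <- function(path, config, cell_summary, comparisons) {
  prov <- list(seed = config$seed,
               outlier_policy = config$outlier_policy,
               subset_reps = config$subset_reps,
               package_version = as.character(utils::packageVersion("pbsi")))
  lines <- c(
    "# PBSI run report", "",
    "## Per-cell similarity summaries (boxplot statistics)", "",
    df_to_md(cell_summary), "")
  if (!is.null(comparisons)) {
    lines <- c(lines, "## Group contrasts", "",
               df_to_md(comparisons[, c("group_a", "group_b", "modality", "site",
                                        "subset", "Z", "p_raw", "p_adj",
                                        "cliffs_d")]), "")
  }
  lines <- c(lines, "## Provenance", "", "```json",
             jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE), "```")
  writeLines(lines, path)
  invisible(path)
}

df_to_md <- function(df) {
  fmt <- function(v) if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
  m <- as.matrix(as.data.frame(lapply(df, fmt), check.names = FALSE,
                               stringsAsFactors = FALSE))
  body <- apply(m, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    body)
}
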
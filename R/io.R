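#' Region sets and morphometry table I/O
#'
#' A morphometry table holds one row per subject with annotation columns
#' (`subject_id`, `group`, `site`, `sex`, `age`, plus optional numeric
#' covariates) and one numeric column per regional measure.  Region columns
#' are tagged with their modality by a name prefix: `ct__` for cortical
#' thickness (mm) and `sv__` for subcortical volume (mm^3).  The column order
#' of the region columns is the canonical profile order: profiles are
#' compared position-wise across subjects, so this order must be identical
#' for every subject, which a single table guarantees by construction.
#'
#' @name morphometry-io
NULL

MODALITIES <- c("CT", "SV")
MODALITY_PREFIX <- c(CT = "ct__", SV = "sv__")
ANNOTATION_COLS <- c("subject_id", "group", "site", "sex", "age")

#' Construct a region set
#'
#' An ordered list of region identifiers of a single modality.  Ordering is
#' fixed: it defines the position-wise layout of every subject's profile.
#'
#' @param modality `"CT"` (cortical thickness) or `"SV"` (subcortical volume).
#' @param region_ids Character vector of unique region labels, length >= 2.
#' @return An object of class `region_set`.
#' @export
region_set <- function(modality, region_ids) {
  modality <- match.arg(toupper(modality), MODALITIES)
  region_ids <- as.character(region_ids)
  if (length(region_ids) < 2)
    stop_config("a region set needs >= 2 regions, got %d", length(region_ids))
  if (anyDuplicated(region_ids))
    stop_config("duplicated region ids: %s",
                paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  structure(list(modality = modality, region_ids = region_ids),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set %s: %d regions>\n", x$modality, length(x$region_ids)))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$region_ids)

region_cols <- function(rs) paste0(MODALITY_PREFIX[[rs$modality]], rs$region_ids)

#' Default region schema (reconstructed Desikan-style listing)
#'
#' A best-effort reconstruction of a standard FreeSurfer export: 64
#' cortical-thickness regions (32 bilateral Desikan parcels, excluding the
#' frontal and temporal poles) and 18 subcortical volumes (9 bilateral
#' structures).  This listing is synthetic in the sense that it was assembled
#' from the public Desikan atlas labels, not copied from any particular
#' study's supplementary table; any schema with >= 2 regions per modality is
#' equally valid input for the pipeline.
#'
#' @return A named list with elements `CT` and `SV`, each a [region_set].
#' @export
default_region_schema <- function() {
  desikan32 <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "transversetemporal", "insula")
  aseg9 <- c("Thalamus", "Caudate", "Putamen", "Pallidum", "Hippocampus",
             "Amygdala", "Accumbens", "LateralVentricle", "InfLatVentricle")
  list(
    CT = region_set("CT", c(paste0("lh_", desikan32), paste0("rh_", desikan32))),
    SV = region_set("SV", c(paste0("Left_", aseg9), paste0("Right_", aseg9)))
  )
}

# Derive the schema from the region-column prefixes of a table, preserving
# column order (the canonical profile order).
schema_from_table <- function(table) {
  out <- list()
  for (m in MODALITIES) {
    pre <- MODALITY_PREFIX[[m]]
    cols <- grep(paste0("^", pre), names(table), value = TRUE)
    if (length(cols) >= 2)
      out[[m]] <- region_set(m, substring(cols, nchar(pre) + 1))
  }
  if (!length(out))
    stop_data("no region columns found (expected 'ct__' / 'sv__' prefixes)")
  out
}

#' Read and write a region schema file
#'
#' The schema file is YAML with one key per modality (`CT`, `SV`) listing the
#' region identifiers in canonical profile order.
#'
#' @param path File path.
#' @return `read_region_schema()` returns a named list of [region_set]s.
#' @export
read_region_schema <- function(path) {
  if (!file.exists(path)) stop_config("schema file not found: %s", path)
  raw <- yaml::read_yaml(path)
  keep <- intersect(toupper(names(raw)), MODALITIES)
  if (!length(keep)) stop_config("schema file defines no CT/SV modality: %s", path)
  names(raw) <- toupper(names(raw))
  stats::setNames(lapply(keep, function(m) region_set(m, unlist(raw[[m]]))), keep)
}

#' @param schema Named list of [region_set]s (as from [default_region_schema()]).
#' @rdname read_region_schema
#' @export
write_region_schema <- function(schema, path) {
  yaml::write_yaml(lapply(schema, function(rs) as.list(rs$region_ids)), path)
  invisible(path)
}

validate_morphometry <- function(table, schema = NULL) {
  missing <- setdiff(ANNOTATION_COLS, names(table))
  if (length(missing))
    stop_data("missing mandatory columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(table$subject_id)) {
    dup <- unique(table$subject_id[duplicated(table$subject_id)])
    stop_data("duplicated subject_id: %s", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(names(table)))
    stop_data("duplicated column names: %s",
              paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  schema <- schema %||% schema_from_table(table)
  for (rs in schema) {
    cols <- region_cols(rs)
    absent <- setdiff(cols, names(table))
    if (length(absent))
      stop_data("schema %s regions absent from table: %s", rs$modality,
                paste(absent, collapse = ", "))
    for (cl in cols)
      if (!is.numeric(table[[cl]]))
        stop_data("region column '%s' is not numeric", cl)
  }
  invisible(schema)
}

#' Read a morphometry table
#'
#' Reads a CSV or TSV morphometry table (delimiter auto-detected from the
#' header line), validates the column contract, coerces region columns to
#' numeric, and drops subjects with any missing or non-finite region value
#' (a profile with holes cannot enter a position-wise rank correlation); the
#' dropped subjects are reported in a warning.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param schema Optional named list of [region_set]s; if `NULL` the schema is
#'   derived from the `ct__` / `sv__` column-name prefixes.
#' @return A validated `data.frame`, one row per retained subject, with the
#'   detected schema attached as attribute `"schema"`.
#' @export
read_morphometry <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  table <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(table)) stop_data("no subjects in %s", path)
  if ("subject_id" %in% names(table))
    table$subject_id <- as.character(table$subject_id)

  # Coerce region columns read as character (e.g. stray text) to numeric,
  # failing loudly with the offending cell rather than silently NA-ing it.
  sch <- validate_region_presence(table, schema)
  for (rs in sch) {
    for (cl in region_cols(rs)) {
      v <- table[[cl]]
      if (!is.numeric(v)) {
        suppress_na <- is.na(v)
        num <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(num) & !suppress_na)
        if (length(bad))
          stop_data("non-numeric value in column '%s', row %d ('%s')",
                    cl, bad[1], v[bad[1]])
        table[[cl]] <- num
      }
    }
  }
  allcols <- unlist(lapply(sch, region_cols))
  ok <- rowSums(!is.finite(as.matrix(table[allcols]))) == 0
  if (any(!ok)) {
    warning(sprintf("dropped %d subject(s) with missing region values: %s",
                    sum(!ok), paste(table$subject_id[!ok], collapse = ", ")),
            call. = FALSE)
    table <- table[ok, , drop = FALSE]
    rownames(table) <- NULL
  }
  if (!nrow(table)) stop_data("zero subjects left after dropping incomplete rows")
  validate_morphometry(table, sch)
  attr(table, "schema") <- sch
  table
}

# Column-presence half of validation, runnable before numeric coercion.
validate_region_presence <- function(table, schema = NULL) {
  missing <- setdiff(ANNOTATION_COLS, names(table))
  if (length(missing))
    stop_data("missing mandatory columns: %s", paste(missing, collapse = ", "))
  schema <- schema %||% schema_from_table(table)
  for (rs in schema) {
    absent <- setdiff(region_cols(rs), names(table))
    if (length(absent))
      stop_data("schema %s regions absent from table: %s", rs$modality,
                paste(absent, collapse = ", "))
  }
  schema
}

#' Write a morphometry table
#'
#' @param table A morphometry `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(table, path) {
  write_precise_csv(as.data.frame(table), path)
}

# Full-precision CSV writer: finite doubles survive a write -> read
# round trip exactly ("%.17g" is lossless for IEEE doubles).
write_precise_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_data("cannot write to %s", path)
  invisible(path)
}

#' Write and read pipeline result tables
#'
#' All pipeline results (`pbsi_result`, `contribution_report` components,
#' `group_comparison`, `cv_comparison`) are tidy long-format data frames;
#' they are written as full-precision CSV so that `read_results()` reproduces
#' every double exactly.
#'
#' @param results A result `data.frame`.
#' @param path Output CSV path.
#' @return `path` invisibly (`write_results`); a `data.frame` (`read_results`).
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results))
    stop_config("write_results expects a data.frame result table")
  write_precise_csv(results, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
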
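#' Synthetic multi-site morphometric cohorts
#'
#' The generator emulates the statistical structure the similarity analysis
#' assumes: every subject shares a modality-specific template profile across
#' regions (the inter-regional "shape" that rank correlations pick up),
#' additive age and sex effects shift the profile, and independent Gaussian
#' region-level noise -- scaled per diagnostic group by the
#' `within_group_dispersion` knob -- makes subjects idiosyncratic.  Larger
#' dispersion disrupts the shared rank order more, which lowers within-group
#' similarity; the knob is the operational definition of morphometric
#' heterogeneity here.
#'
#' Internally each modality lives on a standardized scale that is mapped
#' affinely to measurement units (cortical thickness: 2.5 mm baseline,
#' 0.25 mm per standardized unit; subcortical volume: 4000 mm^3 baseline,
#' 400 mm^3 per unit -- both baselines sit 10 standardized units above
#' zero).  Rank correlations are invariant to that affine map, so
#' `between_region_sd`, `within_group_dispersion`, `age_effect` and
#' `sex_effect` have the same standardized meaning in both modalities, and
#' volumes stay strictly positive by construction (baseline many noise
#' standard deviations above zero) rather than by truncation.
#'
#' @name synthetic-cohort
NULL

MODALITY_OFFSET <- c(CT = 2.5,  SV = 4000)
MODALITY_UNIT   <- c(CT = 0.25, SV = 400)

#' Specify a synthetic cohort
#'
#' @param n_per_group Subjects per (group, site) cell: a scalar (every cell),
#'   a vector named by group (same at every site), or a groups x sites matrix
#'   where `NA`/0 marks a group not recruited at a site.
#' @param groups Character vector of diagnostic group labels.
#' @param sites Character vector of site labels.
#' @param n_ct_regions,n_sv_regions Region counts per modality (>= 2 each).
#' @param template_profile Optional named list (`CT`, `SV`) of region-level
#'   population means in measurement units; `NULL` draws a template from the
#'   seed with spread `between_region_sd`.
#' @param between_region_sd Standard deviation of the template across regions,
#'   in standardized units (1 unit = 0.25 mm CT, 400 mm^3 SV).  This is the
#'   signal that all subjects share.
#' @param within_group_dispersion Per-group non-negative scalar (scalar or
#'   vector named by group): the standard deviation of each subject's
#'   idiosyncratic region-level noise, in standardized units.  The
#'   heterogeneity knob.
#' @param age_range Two-element numeric vector of years; ages are drawn
#'   uniformly on this interval.
#' @param age_effect Per-region slope (standardized units per year of age
#'   centred on the middle of `age_range`); a scalar recycles over regions, a
#'   named list (`CT`, `SV`) gives per-modality vectors.  Default 0.
#' @param sex_effect Per-region offset added for female subjects (the
#'   reference sex level); same shapes as `age_effect`.  Default 0.
#' @param seed Master integer seed; every random draw in the cohort is a
#'   deterministic function of it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group,
                        groups = c("HC", "BD", "SZ"),
                        sites = "siteA",
                        n_ct_regions = 64,
                        n_sv_regions = 18,
                        template_profile = NULL,
                        between_region_sd = 1,
                        within_group_dispersion = 0.5,
                        age_range = c(18, 65),
                        age_effect = 0,
                        sex_effect = 0,
                        seed = 1L) {
  groups <- as.character(groups); sites <- as.character(sites)
  if (n_ct_regions < 2 || n_sv_regions < 2)
    stop_config("need >= 2 regions per modality (rank correlation needs >= 2 ranks)")

  counts <- expand_counts(n_per_group, groups, sites)
  if (any(counts[!is.na(counts)] < 0))
    stop_config("n_per_group must be non-negative")
  if (all(is.na(counts) | counts == 0))
    stop_config("n_per_group yields an empty cohort")
  if (any(!is.na(counts) & counts > 0 & counts == 1))
    stop_config("a cell of size 1 has no peers; use n >= 2 or mark the cell absent")

  disp <- expand_by_group(within_group_dispersion, groups, "within_group_dispersion")
  if (any(disp < 0)) stop_config("within_group_dispersion must be >= 0")

  nreg <- c(CT = n_ct_regions, SV = n_sv_regions)
  if (!is.null(template_profile)) {
    for (m in names(nreg)) {
      tp <- template_profile[[m]]
      if (!is.null(tp) && length(tp) != nreg[[m]])
        stop_config("template_profile$%s has length %d, expected %d",
                    m, length(tp), nreg[[m]])
    }
  }
  spec <- structure(list(
    counts = counts, groups = groups, sites = sites,
    n_ct_regions = as.integer(n_ct_regions),
    n_sv_regions = as.integer(n_sv_regions),
    template_profile = template_profile,
    between_region_sd = between_region_sd,
    within_group_dispersion = disp,
    age_range = as.numeric(age_range),
    age_effect = expand_by_modality(age_effect, nreg, "age_effect"),
    sex_effect = expand_by_modality(sex_effect, nreg, "sex_effect"),
    seed = as.integer(seed)), class = "cohort_spec")
  spec
}

expand_counts <- function(n, groups, sites) {
  if (is.matrix(n)) {
    if (nrow(n) != length(groups) || ncol(n) != length(sites))
      stop_config("n_per_group matrix must be groups x sites (%d x %d)",
                  length(groups), length(sites))
    m <- n
  } else if (!is.null(names(n))) {
    if (!all(groups %in% names(n)))
      stop_config("n_per_group names must cover all groups")
    m <- matrix(n[groups], length(groups), length(sites))
  } else if (length(n) == 1) {
    m <- matrix(n, length(groups), length(sites))
  } else stop_config("n_per_group must be scalar, named by group, or a matrix")
  dimnames(m) <- list(groups, sites)
  storage.mode(m) <- "integer"
  m
}

expand_by_group <- function(x, groups, what) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(groups)), groups))
  if (!all(groups %in% names(x)))
    stop_config("%s must be scalar or named for every group", what)
  stats::setNames(as.numeric(x[groups]), groups)
}

expand_by_modality <- function(x, nreg, what) {
  if (is.list(x)) {
    out <- lapply(names(nreg), function(m) {
      v <- x[[m]] %||% 0
      if (length(v) == 1) v <- rep(v, nreg[[m]])
      if (length(v) != nreg[[m]])
        stop_config("%s$%s has length %d, expected %d", what, m, length(v), nreg[[m]])
      as.numeric(v)
    })
    return(stats::setNames(out, names(nreg)))
  }
  if (length(x) != 1)
    stop_config("%s must be a scalar or a named list per modality", what)
  lapply(nreg, function(k) rep(as.numeric(x), k))
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a [cohort_spec()].  For subject \eqn{i} in
#' group \eqn{g}, each regional measure is
#' \deqn{x = T_r + u_m\,(\beta_r (a_i - \bar a) + \gamma_r 1[s_i = F]
#'       + \sigma_g \epsilon_{ir}),}
#' with template \eqn{T}, modality unit \eqn{u_m}, age slope \eqn{\beta}, sex
#' offset \eqn{\gamma}, group dispersion \eqn{\sigma_g} and independent
#' standard-normal \eqn{\epsilon}.  Ages are uniform on `age_range`, sexes
#' alternate F/M within each cell (balanced).  One pseudo-random stream per
#' subject is split deterministically from the master seed by (site, group,
#' index), so adding subjects, groups or sites never perturbs existing ones.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `table` (the
#'   morphometry `data.frame`), `spec`, and `noise` (the realized per-subject
#'   idiosyncratic noise, in measurement units — the generative truth used by
#'   [inject_dominant_region()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nreg <- c(CT = spec$n_ct_regions, SV = spec$n_sv_regions)

  template <- lapply(stats::setNames(names(nreg), names(nreg)), function(m) {
    tp <- spec$template_profile[[m]]
    if (!is.null(tp)) return(as.numeric(tp))
    z <- with_seed(mix_seed(spec$seed, "template", m), stats::rnorm(nreg[[m]]))
    MODALITY_OFFSET[[m]] + MODALITY_UNIT[[m]] * spec$between_region_sd * z
  })

  schema <- list(
    CT = region_set("CT", sprintf("region%02d", seq_len(nreg[["CT"]]))),
    SV = region_set("SV", sprintf("region%02d", seq_len(nreg[["SV"]])))
  )
  cols <- unlist(lapply(schema, region_cols), use.names = FALSE)
  mid_age <- mean(spec$age_range)

  rows <- list(); noise <- list()
  for (s in spec$sites) for (g in spec$groups) {
    n <- spec$counts[g, s]
    if (is.na(n) || n == 0) next
    sigma <- spec$within_group_dispersion[[g]]
    for (k in seq_len(n)) {
      draws <- with_seed(mix_seed(spec$seed, "subject", s, g, k), {
        list(age = stats::runif(1, spec$age_range[1], spec$age_range[2]),
             eps = stats::rnorm(sum(nreg)))
      })
      sex <- if (k %% 2 == 1) "F" else "M"
      eps <- split(draws$eps, rep(names(nreg), nreg))
      vals <- nse <- numeric(0)
      for (m in names(nreg)) {
        nm <- MODALITY_UNIT[[m]] * sigma * eps[[m]]
        vm <- template[[m]] + MODALITY_UNIT[[m]] *
          (spec$age_effect[[m]] * (draws$age - mid_age) +
             spec$sex_effect[[m]] * (sex == "F")) + nm
        vals <- c(vals, vm); nse <- c(nse, nm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%s_%03d", s, g, k),
        group = g, site = s, sex = sex, age = draws$age,
        rbind(stats::setNames(vals, cols)), check.names = FALSE,
        stringsAsFactors = FALSE)
      noise[[length(noise) + 1L]] <- nse
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  noise <- do.call(rbind, noise)
  dimnames(noise) <- list(table$subject_id, cols)

  if (!all(is.finite(as.matrix(table[cols]))))
    stop_data("generated non-finite measures; check spec parameters")
  svc <- region_cols(schema$SV)
  if (any(as.matrix(table[svc]) <= 0))
    stop_data(paste("generated non-positive volumes; the dispersion/template",
                    "settings violate the positivity-by-construction contract"))
  validate_morphometry(table, schema)
  attr(table, "schema") <- schema
  structure(list(table = table, spec = spec, noise = noise),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects, %d sites, %d groups, %d+%d regions>\n",
              nrow(x$table), length(unique(x$table$site)),
              length(unique(x$table$group)),
              x$spec$n_ct_regions, x$spec$n_sv_regions))
  invisible(x)
}

#' Boost one region's idiosyncratic noise
#'
#' Multiplies the realized subject-level noise of a single region by `boost`
#' for every subject, leaving template, covariate effects and all other
#' regions untouched.  A large boost makes that region a known dominant
#' contributor, which the leave-one-out contribution analysis must detect;
#' this is a test fixture, not a biological model.
#'
#' @param cohort A `synthetic_cohort`.
#' @param region_id Region column name (e.g. `"ct__region05"`).
#' @param boost Non-negative multiplier; `1` is the identity.
#' @return The modified `synthetic_cohort`.
#' @export
inject_dominant_region <- function(cohort, region_id, boost) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!region_id %in% colnames(cohort$noise))
    stop_config("unknown region: %s", region_id)
  if (!is.numeric(boost) || length(boost) != 1 || boost < 0)
    stop_config("boost must be a non-negative scalar")
  delta <- (boost - 1) * cohort$noise[, region_id]
  cohort$table[[region_id]] <- cohort$table[[region_id]] + delta
  cohort$noise[, region_id] <- boost * cohort$noise[, region_id]
  cohort
}

#' Write a cohort with its generative truth sidecar
#'
#' Writes `cohort.csv` (the morphometry table), `schema.yaml` (region
#' schema), and `truth.json` (the cohort specification and seed that
#' generated it).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_morphometry(cohort$table, file.path(dir, "cohort.csv"))
  write_region_schema(attr(cohort$table, "schema"), file.path(dir, "schema.yaml"))
  truth <- cohort$spec
  truth$counts <- as.data.frame(as.table(truth$counts),
                                responseName = "n", stringsAsFactors = FALSE)
  names(truth$counts)[1:2] <- c("group", "site")
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
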
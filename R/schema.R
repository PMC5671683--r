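#' matgrade: degrees of maternal morbidity from routine birth registries
#'
#' Tools to grade every woman in a perinatal registry along a severity
#' gradient of maternal morbidity -- maternal death (MD), maternal near miss
#' (MNM), potentially life-threatening condition (PLTC), less severe maternal
#' morbidity (LSMM), or no morbidity -- from pragmatic, registry-recordable
#' criteria, and to turn the classified cohort into the standard surveillance
#' outputs: the indicator panel (MMR, MNMR, SMOR, PLTCR, LSMMR, AMMR),
#' severity-stratified contingency tables with cluster-design-corrected
#' chi-square tests, and crude/adjusted prevalence ratios with cluster-robust
#' confidence intervals.
#'
#' @section Typical workflow:
#' \enumerate{
#'   \item \code{\link{read_cohort}} (or \code{\link{generate_cohort}} for a
#'     synthetic registry) to obtain a cohort data frame;
#'   \item \code{\link{classify_cohort}} to attach the severity and neonatal
#'     near-miss columns;
#'   \item \code{\link{indicator_panel}}, \code{\link{crosstab}},
#'     \code{\link{crude_pr}} and \code{\link{adjusted_pr}} for the analyses;
#'   \item or \code{\link{run_pipeline}} to do all of it in one reproducible
#'     run with a manifest.
#' }
#'
#' @docType package
#' @name matgrade-package
#' @aliases matgrade
"_PACKAGE"

# ---------------------------------------------------------------------------
# Schema: the data dictionary for one-row-per-woman perinatal records.
# ---------------------------------------------------------------------------

.flag_levels <- c("present", "absent")

.mnm_flags <- c("blood_transfusion", "haemorrhage_any", "eclampsia_or_mgso4",
                "cardiac_disease", "renal_disease")

.pltc_flags <- c("abruptio_placentae", "ectopic_pregnancy", "uterine_rupture",
                 "postpartum_haemorrhage", "puerperal_sepsis",
                 "puerperal_infection", "severe_preeclampsia_no_mgso4",
                 "severe_hypertension", "placenta_previa_with_haemorrhage",
                 "other_severe_condition")

.lsmm_flags <- c("anaemia", "hiv_positive", "diabetes", "antenatal_admission",
                 "ovular_infection", "urinary_tract_infection",
                 "other_maternal_condition", "retained_placenta", "referred")

.prev_flags <- c("prev_diabetes", "prev_hypertension", "prev_preeclampsia",
                 "prev_eclampsia", "prev_cardiac_disease", "prev_renal_disease",
                 "prev_other_severe", "prev_any")

#' Data dictionary for the cohort CSV schema
#'
#' One row per field of the perinatal record: the column name, its type
#' (\code{"id"}, \code{"category"}, \code{"flag"}, \code{"integer"},
#' \code{"numeric"}), and for categories the allowed levels (semicolon
#' separated). Condition flags are tri-state: \code{"present"},
#' \code{"absent"}, or an empty CSV cell for missing/unrecorded --
#' missing is a first-class state, distinct from absent, and survives a
#' read/write round trip.
#'
#' @return A data frame with columns \code{field}, \code{type},
#'   \code{levels}.
#' @export
#' @examples
#' head(cohort_schema())
cohort_schema <- function() {
  cat_field <- function(field, levels) {
    data.frame(field = field, type = "category",
               levels = paste(levels, collapse = ";"))
  }
  flag_field <- function(field) {
    data.frame(field = field, type = "flag",
               levels = paste(.flag_levels, collapse = ";"))
  }
  num_field <- function(field, type) data.frame(field = field, type = type,
                                                levels = "")
  rbind(
    data.frame(field = c("record_id", "cluster_id"), type = "id", levels = ""),
    num_field("maternal_age", "integer"),
    cat_field("ethnicity", c("white", "mixed", "other")),
    cat_field("literacy", c("none_or_primary", "secondary_or_university")),
    cat_field("marital_status", c("married_or_stable", "single_or_other")),
    cat_field("parity", c("nullipara", "multipara")),
    num_field("prenatal_visits", "integer"),
    flag_field("risk_exposure"),
    flag_field("previous_csection"),
    cat_field("labour_onset", c("spontaneous", "induced", "elective_csection")),
    cat_field("delivery_mode", c("csection", "vaginal")),
    cat_field("death_status",
              c("alive", "died_at_facility", "died_in_transport_or_referral")),
    num_field("hospital_stay_days", "integer"),
    do.call(rbind, lapply(c(.mnm_flags, .pltc_flags, .lsmm_flags, .prev_flags),
                          flag_field)),
    num_field("gestational_age_weeks", "numeric"),
    num_field("birthweight_g", "numeric"),
    num_field("apgar5", "integer"),
    cat_field("vital_status_at_birth", c("live", "fetal_death")),
    cat_field("child_discharge_status", c("alive", "neonatal_death", "referred"))
  )
}

.schema_fields <- function() cohort_schema()$field

#' Tri-state flag helpers
#'
#' A condition flag takes the values \code{"present"}, \code{"absent"}, or
#' \code{NA} (unrecorded). \code{flag_present()} maps a flag vector to
#' logical with the registry convention that an unrecorded diagnosis never
#' satisfies a criterion: \code{NA} and \code{"absent"} both give
#' \code{FALSE}.
#'
#' @param x Character vector of flag states.
#' @return Logical vector, no \code{NA}.
#' @export
flag_present <- function(x) !is.na(x) & x == "present"

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Validate a cohort against the schema invariants
#'
#' Checks range invariants (maternal age in \[10, 55\], Apgar in \[0, 10\],
#' gestational age in (10, 46) weeks, birthweight in (200, 7000) g, counts
#' non-negative), flag/category level validity, record-id uniqueness, and the
#' consistency of \code{prev_any} with its component previous conditions
#' (checked only when all components are recorded). Missing values never
#' violate a range invariant.
#'
#' @param cohort A cohort data frame.
#' @param strict If \code{TRUE}, any violation aborts with an error naming the
#'   offending \code{record_id}; otherwise violations are returned.
#' @return Invisibly, a data frame of violations (zero rows when clean) with
#'   columns \code{record_id}, \code{field}, \code{problem}.
#' @export
validate_cohort <- function(cohort, strict = FALSE) {
  stopifnot(is.data.frame(cohort))
  schema <- cohort_schema()
  unknown <- setdiff(names(cohort),
                     c(schema$field, "severity", "neonatal_near_miss"))
  if (length(unknown))
    stop("unknown column(s) not in the cohort schema: ",
         paste(unknown, collapse = ", "))
  missing_cols <- setdiff(schema$field, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing schema column(s): ",
         paste(missing_cols, collapse = ", "))

  issues <- list()
  bad <- function(idx, field, problem) {
    if (any(idx)) issues[[length(issues) + 1L]] <<- data.frame(
      record_id = as.character(cohort$record_id[idx]),
      field = field, problem = problem)
  }

  rng <- function(x, lo, hi, open = FALSE) {
    v <- suppressWarnings(as.numeric(x))
    if (open) !is.na(v) & (v <= lo | v >= hi) else !is.na(v) & (v < lo | v > hi)
  }
  bad(rng(cohort$maternal_age, 10, 55), "maternal_age", "outside [10, 55]")
  bad(rng(cohort$apgar5, 0, 10), "apgar5", "outside [0, 10]")
  bad(rng(cohort$gestational_age_weeks, 10, 46, open = TRUE),
      "gestational_age_weeks", "outside (10, 46)")
  bad(rng(cohort$birthweight_g, 200, 7000, open = TRUE),
      "birthweight_g", "outside (200, 7000)")
  for (f in c("prenatal_visits", "hospital_stay_days"))
    bad(rng(cohort[[f]], 0, Inf), f, "negative count")

  for (i in seq_len(nrow(schema))) {
    f <- schema$field[i]
    if (schema$type[i] %in% c("category", "flag")) {
      lv <- strsplit(schema$levels[i], ";", fixed = TRUE)[[1]]
      x <- cohort[[f]]
      bad(!is.na(x) & !(x %in% lv), f,
          paste0("level not in {", schema$levels[i], "}"))
    }
  }

  if (anyDuplicated(cohort$record_id))
    bad(duplicated(cohort$record_id), "record_id", "duplicated id")

  # prev_any must agree with its components where everything is recorded
  comp <- .prev_flags[.prev_flags != "prev_any"]
  n_na <- Reduce(`+`, lapply(comp, function(f) is.na(cohort[[f]])))
  any_comp <- Reduce(`|`, lapply(comp, function(f) flag_present(cohort[[f]])))
  all_recorded <- !is.na(cohort$prev_any) & n_na == 0L
  bad(all_recorded & (cohort$prev_any == "present") != any_comp,
      "prev_any", "inconsistent with component previous conditions")

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(record_id = character(), field = character(),
               problem = character())
  if (strict && nrow(issues))
    stop("cohort validation failed for record(s) ",
         paste(unique(issues$record_id), collapse = ", "), ": ",
         issues$field[1L], " ", issues$problem[1L])
  invisible(issues)
}

#' Per-field missingness of a cohort
#'
#' @param cohort A cohort data frame.
#' @return Named numeric vector: fraction of records with the field
#'   unrecorded, one entry per schema field.
#' @export
missingness <- function(cohort) {
  fields <- intersect(.schema_fields(), names(cohort))
  vapply(cohort[fields], function(x) mean(is.na(x)), numeric(1))
}
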
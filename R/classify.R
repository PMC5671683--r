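# Severity grading: mutually exclusive classes assigned by fixed precedence
# MD > MNM > PLTC > LSMM > NONE, so a woman is graded by the most severe
# criterion she meets. Derived unions: SMO = MD + MNM, AMM = everything but
# NONE.

.severity_levels <- c("MD", "MNM", "PLTC", "LSMM", "NONE")

#' Maternal death indicator
#'
#' A record counts as a maternal death if the woman died at the health
#' facility or during transport/referral. An unrecorded death status never
#' counts as a death.
#'
#' @param cohort A cohort data frame.
#' @return Logical vector, one element per record.
#' @export
is_md <- function(cohort) {
  x <- cohort$death_status
  !is.na(x) & x %in% c("died_at_facility", "died_in_transport_or_referral")
}

#' Neonatal near miss composite
#'
#' Birthweight below 1750 g, or 5th-minute Apgar below 7, or gestational age
#' below 33 weeks (strict inequalities). Unrecorded components never
#' qualify. The composite is not applicable to fetal deaths, and is
#' \code{NA} when all three components are unrecorded.
#'
#' @param cohort A cohort data frame.
#' @return Logical vector (\code{NA} = not applicable / not assessable).
#' @export
neonatal_near_miss <- function(cohort) {
  lt <- function(x, cut) !is.na(x) & x < cut
  out <- lt(cohort$birthweight_g, 1750) | lt(cohort$apgar5, 7) |
    lt(cohort$gestational_age_weeks, 33)
  out[is.na(cohort$birthweight_g) & is.na(cohort$apgar5) &
        is.na(cohort$gestational_age_weeks)] <- NA
  vs <- cohort$vital_status_at_birth
  out[!is.na(vs) & vs == "fetal_death"] <- NA
  out
}

#' Classify a cohort along the maternal-morbidity severity gradient
#'
#' Assigns each record exactly one of \code{MD}, \code{MNM}, \code{PLTC},
#' \code{LSMM}, \code{NONE}: the first level, in that order of severity,
#' whose criteria the record meets. Classes are therefore mutually exclusive
#' and exhaustive, and adding a higher-severity condition to a record can
#' never lower its class. Also appends the neonatal near-miss composite.
#'
#' @param cohort A cohort data frame.
#' @param criteria Named list with \code{MNM}, \code{PLTC} and \code{LSMM}
#'   \code{\link{criteria_set}}s; defaults to \code{\link{default_criteria}()}.
#' @return The cohort with two added columns: \code{severity} (factor with
#'   levels MD, MNM, PLTC, LSMM, NONE) and \code{neonatal_near_miss}
#'   (logical, \code{NA} where not applicable).
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n = 500, seed = 1))
#' table(classify_cohort(coh)$severity)
classify_cohort <- function(cohort, criteria = default_criteria()) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("MNM", "PLTC", "LSMM") %in% names(criteria)))
    stop("criteria must contain MNM, PLTC and LSMM sets")
  sev <- rep("NONE", nrow(cohort))
  sev[meets_criteria(cohort, criteria$LSMM)] <- "LSMM"
  sev[meets_criteria(cohort, criteria$PLTC)] <- "PLTC"
  sev[meets_criteria(cohort, criteria$MNM)] <- "MNM"
  sev[is_md(cohort)] <- "MD"
  cohort$severity <- factor(sev, levels = .severity_levels)
  cohort$neonatal_near_miss <- neonatal_near_miss(cohort)
  cohort
}

#' Severity class counts including the derived unions
#'
#' @param classified A cohort with a \code{severity} column.
#' @return Named integer vector with MD, MNM, SMO (= MD + MNM), PLTC, LSMM,
#'   AMM (= all morbidity classes), NONE, and TOTAL.
#' @export
severity_counts <- function(classified) {
  if (is.null(classified$severity))
    stop("cohort has no severity column; run classify_cohort() first")
  n <- table(factor(classified$severity, levels = .severity_levels))
  c(MD = unname(n["MD"]), MNM = unname(n["MNM"]),
    SMO = unname(n["MD"] + n["MNM"]),
    PLTC = unname(n["PLTC"]), LSMM = unname(n["LSMM"]),
    AMM = unname(n["MD"] + n["MNM"] + n["PLTC"] + n["LSMM"]),
    NONE = unname(n["NONE"]), TOTAL = length(classified$severity))
}
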
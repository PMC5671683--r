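# Rule-based criteria engine. Each severity level below maternal death is
# defined by a CriteriaSet: a list of single rules (any one suffices) plus
# optional combined-rule groups (all members of a group must hold jointly).
# Unrecorded (missing) values never satisfy a rule.

.comparators <- c("is_present", "greater_than", "equals")

#' Build a single criterion rule
#'
#' @param field A schema field name.
#' @param comparator One of \code{"is_present"} (tri-state flag recorded as
#'   present), \code{"greater_than"} (numeric strictly above
#'   \code{value}), \code{"equals"} (category equal to \code{value}).
#' @param value Threshold or category value; ignored for
#'   \code{"is_present"}.
#' @return A \code{criterion_rule} object.
#' @export
#' @examples
#' criterion_rule("hospital_stay_days", "greater_than", 7)
criterion_rule <- function(field, comparator = "is_present", value = NULL) {
  comparator <- match.arg(comparator, .comparators)
  schema <- cohort_schema()
  if (!field %in% schema$field)
    stop("criterion references unknown schema field '", field, "'")
  type <- schema$type[schema$field == field]
  if (comparator == "greater_than" && !type %in% c("integer", "numeric"))
    stop("greater_than only applies to numeric fields; '", field,
         "' is ", type)
  if (comparator == "is_present" && type != "flag")
    stop("is_present only applies to tri-state flags; '", field,
         "' is ", type)
  if (comparator != "is_present" && is.null(value))
    stop("comparator '", comparator, "' needs a value")
  structure(list(field = field, comparator = comparator, value = value),
            class = "criterion_rule")
}

#' Build a criteria set for one severity level
#'
#' @param level Severity level the set defines: \code{"MNM"}, \code{"PLTC"}
#'   or \code{"LSMM"} (maternal death is defined by vital status, not rules).
#' @param rules List of \code{\link{criterion_rule}}s; a record meets the
#'   set if any single rule holds.
#' @param combined List of rule lists; a record also meets the set if every
#'   rule of any one group holds jointly.
#' @return A \code{criteria_set} object.
#' @export
criteria_set <- function(level, rules = list(), combined = list()) {
  level <- match.arg(level, c("MNM", "PLTC", "LSMM"))
  stopifnot(all(vapply(rules, inherits, logical(1), "criterion_rule")))
  for (grp in combined)
    stopifnot(length(grp) >= 1L,
              all(vapply(grp, inherits, logical(1), "criterion_rule")))
  if (length(rules) + length(combined) == 0L)
    stop("criteria set for ", level, " must contain at least one rule")
  structure(list(level = level, rules = rules, combined = combined),
            class = "criteria_set")
}

#' @export
print.criteria_set <- function(x, ...) {
  rule_txt <- function(r) {
    if (r$comparator == "is_present") paste0(r$field, " present")
    else paste(r$field, sub("_", " ", r$comparator), r$value)
  }
  cat("Criteria set for", x$level, "\n")
  for (r in x$rules) cat("  -", rule_txt(r), "\n")
  for (g in x$combined)
    cat("  -", paste(vapply(g, rule_txt, character(1)), collapse = " AND "),
        "\n")
  invisible(x)
}

#' Default severity criteria
#'
#' The pragmatic criteria recordable in a routine birth registry:
#' \describe{
#'   \item{MNM}{blood transfusion together with haemorrhage (any trimester or
#'     postpartum) as a joint rule; eclampsia or magnesium sulfate for
#'     eclampsia; cardiac disease; renal disease; prolonged hospital stay
#'     (> 7 days).}
#'   \item{PLTC}{abruptio placentae; ectopic pregnancy; ruptured uterus;
#'     postpartum haemorrhage; puerperal sepsis; puerperal infection; severe
#'     preeclampsia without magnesium sulfate; severe hypertension; any blood
#'     transfusion; placenta previa with haemorrhage; other severe
#'     condition.}
#'   \item{LSMM}{anaemia; HIV+; diabetes; antenatal admission; ovular
#'     infection; urinary tract infection; other maternal condition; retained
#'     placenta; referral.}
#' }
#' Transfusion and haemorrhage are combined jointly for MNM so that
#' transfusion alone (a PLTC criterion in its own right) grades as PLTC, not
#' MNM; set \code{mnm_transfusion_joint = FALSE} for the alternative reading
#' in which either alone qualifies as MNM.
#'
#' @param mnm_transfusion_joint Require transfusion AND haemorrhage jointly
#'   for MNM (default) or let each alone qualify.
#' @return Named list of \code{\link{criteria_set}}s for \code{MNM},
#'   \code{PLTC} and \code{LSMM}.
#' @export
default_criteria <- function(mnm_transfusion_joint = TRUE) {
  p <- function(f) criterion_rule(f, "is_present")
  mnm_single <- lapply(c("eclampsia_or_mgso4", "cardiac_disease",
                         "renal_disease"), p)
  mnm_single <- c(mnm_single,
                  list(criterion_rule("hospital_stay_days", "greater_than", 7)))
  if (mnm_transfusion_joint) {
    mnm <- criteria_set("MNM", rules = mnm_single,
                        combined = list(list(p("blood_transfusion"),
                                             p("haemorrhage_any"))))
  } else {
    mnm <- criteria_set("MNM",
                        rules = c(list(p("blood_transfusion"),
                                       p("haemorrhage_any")), mnm_single))
  }
  list(
    MNM  = mnm,
    PLTC = criteria_set("PLTC",
                        rules = lapply(c(.pltc_flags, "blood_transfusion"), p)),
    LSMM = criteria_set("LSMM", rules = lapply(.lsmm_flags, p))
  )
}

.eval_rule <- function(rule, cohort) {
  if (!rule$field %in% names(cohort))
    stop("criterion references unknown schema field '", rule$field, "'")
  x <- cohort[[rule$field]]
  switch(rule$comparator,
         is_present   = flag_present(x),
         greater_than = !is.na(x) & as.numeric(x) > as.numeric(rule$value),
         equals       = !is.na(x) & x == rule$value)
}

#' Does each record meet a criteria set?
#'
#' A record meets the set if any single rule holds, or all rules of any
#' combined group hold jointly. Unrecorded values never satisfy a rule.
#'
#' @param cohort A cohort data frame (one record or many).
#' @param criteria A \code{\link{criteria_set}}.
#' @return Logical vector, one element per record.
#' @export
meets_criteria <- function(cohort, criteria) {
  stopifnot(inherits(criteria, "criteria_set"), is.data.frame(cohort))
  hit <- rep(FALSE, nrow(cohort))
  for (r in criteria$rules) hit <- hit | .eval_rule(r, cohort)
  for (grp in criteria$combined)
    hit <- hit | Reduce(`&`, lapply(grp, .eval_rule, cohort = cohort))
  hit
}

# ---------------------------------------------------------------------------
# YAML (de)serialisation so criteria ship as an editable structured config.
# ---------------------------------------------------------------------------

.rule_to_list <- function(r) {
  out <- list(field = r$field, comparator = r$comparator)
  if (!is.null(r$value)) out$value <- r$value
  out
}

.rule_from_list <- function(l)
  criterion_rule(l$field, l$comparator, l$value)

#' Read or write a criteria configuration file
#'
#' The configuration is YAML with one block per severity level; each block
#' has a \code{rules} list (any one suffices) and an optional
#' \code{combined} list of rule groups (all members jointly). Every rule is
#' validated against the schema on read.
#'
#' @param path File path.
#' @param criteria Named list of \code{\link{criteria_set}}s (for writing).
#' @return \code{read_criteria()} returns the named list of criteria sets;
#'   \code{write_criteria()} returns \code{path} invisibly.
#' @export
read_criteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("MNM", "PLTC", "LSMM")
  if (!all(need %in% names(cfg)))
    stop("criteria config must define MNM, PLTC and LSMM blocks")
  out <- lapply(need, function(lv) {
    blk <- cfg[[lv]]
    criteria_set(lv,
                 rules = lapply(blk$rules, .rule_from_list),
                 combined = lapply(blk$combined, function(grp)
                   lapply(grp, .rule_from_list)))
  })
  names(out) <- need
  out
}

#' @rdname read_criteria
#' @export
write_criteria <- function(criteria, path) {
  cfg <- lapply(criteria, function(cs) list(
    rules = lapply(cs$rules, .rule_to_list),
    combined = lapply(cs$combined, function(grp)
      lapply(grp, .rule_to_list))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
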
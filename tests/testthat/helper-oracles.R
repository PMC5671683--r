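# Independent oracles, deliberately written record-by-record and rule-by-rule
# (no vectorisation shared with the implementation).

oracle_classify <- function(cohort, criteria = default_criteria()) {
  vapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, , drop = FALSE]
    holds <- function(r) {
      v <- rec[[r$field]]
      if (is.na(v)) return(FALSE)
      if (r$comparator == "is_present") return(v == "present")
      if (r$comparator == "greater_than") return(as.numeric(v) > r$value)
      v == r$value
    }
    meets <- function(cs) {
      single <- any(vapply(cs$rules, holds, logical(1)))
      joint <- any(vapply(cs$combined,
                          function(g) all(vapply(g, holds, logical(1))),
                          logical(1)))
      single || joint
    }
    ds <- rec$death_status
    if (!is.na(ds) &&
        ds %in% c("died_at_facility", "died_in_transport_or_referral"))
      return("MD")
    if (meets(criteria$MNM)) return("MNM")
    if (meets(criteria$PLTC)) return("PLTC")
    if (meets(criteria$LSMM)) return("LSMM")
    "NONE"
  }, character(1))
}

# closed-form Pearson chi-square for a 2x2 table of counts
pearson_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, c, b, d), 2)
  sum((o - e)^2 / e)
}
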
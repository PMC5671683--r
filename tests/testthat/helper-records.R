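# Build well-formed records in code; every test fixture is generated here.

flag_fields <- function() {
  s <- cohort_schema()
  s$field[s$type == "flag"]
}

# n records with every condition absent and benign defaults
blank_cohort <- function(n = 1) {
  df <- data.frame(record_id = sprintf("R%03d", seq_len(n)),
                   cluster_id = "C01",
                   maternal_age = 25L,
                   ethnicity = "white",
                   literacy = "secondary_or_university",
                   marital_status = "married_or_stable",
                   parity = "multipara",
                   prenatal_visits = 5L,
                   labour_onset = "spontaneous",
                   delivery_mode = "vaginal",
                   death_status = "alive",
                   hospital_stay_days = 2L,
                   gestational_age_weeks = 39,
                   birthweight_g = 3300,
                   apgar5 = 9L,
                   vital_status_at_birth = "live",
                   child_discharge_status = "alive")
  for (f in flag_fields()) df[[f]] <- "absent"
  df[cohort_schema()$field]
}

# random records exercising all tri-state combinations
random_cohort <- function(n, seed) {
  set.seed(seed)
  df <- blank_cohort(n)
  for (f in flag_fields())
    df[[f]] <- sample(c("present", "absent", NA), n, replace = TRUE,
                      prob = c(.25, .6, .15))
  # keep the prev_any invariant out of the way: derive it where recorded
  comp <- sapply(setdiff(grep("^prev_", names(df), value = TRUE), "prev_any"),
                 function(f) df[[f]])
  df$prev_any <- ifelse(rowSums(comp == "present", na.rm = TRUE) > 0,
                        "present", "absent")
  df$hospital_stay_days <- sample(0:15, n, replace = TRUE)
  df$death_status <- sample(c("alive", "died_at_facility",
                              "died_in_transport_or_referral", NA),
                            n, replace = TRUE, prob = c(.85, .06, .04, .05))
  df$cluster_id <- sample(sprintf("C%02d", 1:5), n, replace = TRUE)
  df
}
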
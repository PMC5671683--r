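crit <- default_criteria()

test_that("maternal death is defined by vital status alone", {
  coh <- blank_cohort(4)
  coh$death_status <- c("died_at_facility", "alive",
                        "died_in_transport_or_referral", NA)
  expect_identical(is_md(coh), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("single rules, combined rules, and the missing-never-qualifies convention", {
  coh <- blank_cohort(6)
  coh$eclampsia_or_mgso4[1] <- "present"
  coh$blood_transfusion[2] <- "present"       # transfusion alone
  coh$blood_transfusion[3] <- "present"       # transfusion + haemorrhage jointly
  coh$haemorrhage_any[3] <- "present"
  coh$hospital_stay_days[4] <- 8L             # prolonged stay > 7
  coh$eclampsia_or_mgso4[5] <- NA             # missing, must not qualify
  expect_identical(meets_criteria(coh, crit$MNM),
                   c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # transfusion alone is still "any blood transfusion" for PLTC
  expect_true(meets_criteria(coh[2, ], crit$PLTC))
  expect_identical(unname(as.character(classify_cohort(coh, crit)$severity)),
                   c("MNM", "PLTC", "MNM", "MNM", "NONE", "NONE"))
})

test_that("the alternative single-criterion transfusion reading is selectable", {
  loose <- default_criteria(mnm_transfusion_joint = FALSE)
  coh <- blank_cohort(1)
  coh$blood_transfusion <- "present"
  expect_true(meets_criteria(coh, loose$MNM))
  expect_false(meets_criteria(coh, crit$MNM))
})

test_that("precedence MD > MNM > PLTC > LSMM is deterministic and never lowered", {
  coh <- blank_cohort(3)
  # everything at once -> MD
  for (f in flag_fields()) coh[[f]][1] <- "present"
  coh$prev_any[1] <- "present"
  coh$death_status[1] <- "died_at_facility"
  # MNM + LSMM criteria -> MNM
  coh$eclampsia_or_mgso4[2] <- "present"
  coh$anaemia[2] <- "present"
  # LSMM only
  coh$anaemia[3] <- "present"
  got <- as.character(classify_cohort(coh, crit)$severity)
  expect_identical(got, c("MD", "MNM", "LSMM"))

  # monotone: adding a higher-severity flag never lowers the class
  rank <- function(x) match(x, c("NONE", "LSMM", "PLTC", "MNM", "MD"))
  base <- random_cohort(60, seed = 11)
  before <- rank(oracle_classify(base))
  worse <- base
  worse$severe_hypertension <- "present"   # a PLTC criterion
  after <- rank(as.character(classify_cohort(worse, crit)$severity))
  expect_identical(after, pmax(before, rank("PLTC")))
})

test_that("classifier agrees with the brute-force rule evaluator on random records", {
  for (seed in c(1, 2, 3)) {
    coh <- random_cohort(150, seed = seed)
    expect_identical(as.character(classify_cohort(coh, crit)$severity),
                     oracle_classify(coh, crit))
  }
  # and under the alternative criteria reading
  loose <- default_criteria(mnm_transfusion_joint = FALSE)
  coh <- random_cohort(150, seed = 4)
  expect_identical(as.character(classify_cohort(coh, loose)$severity),
                   oracle_classify(coh, loose))
})

test_that("classes partition every cohort", {
  coh <- random_cohort(500, seed = 9)
  sc <- severity_counts(classify_cohort(coh, crit))
  expect_equal(unname(sc["MD"] + sc["MNM"] + sc["PLTC"] + sc["LSMM"] +
                        sc["NONE"]), 500)
  expect_equal(unname(sc["SMO"]), unname(sc["MD"] + sc["MNM"]))
  expect_equal(unname(sc["AMM"]), unname(sc["TOTAL"] - sc["NONE"]))
})

test_that("rules referencing unknown fields are a configuration error", {
  expect_error(criterion_rule("no_such_field"), "unknown schema field")
  expect_error(criterion_rule("ethnicity", "greater_than", 2), "numeric")
  expect_error(criterion_rule("maternal_age", "is_present"), "tri-state")
  expect_error(criteria_set("MNM"), "at least one rule")
})

test_that("criteria sets round-trip through the YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_criteria(crit, path)
  back <- read_criteria(path)
  coh <- random_cohort(100, seed = 21)
  expect_identical(classify_cohort(coh, back)$severity,
                   classify_cohort(coh, crit)$severity)
})

test_that("neonatal near miss follows the strict thresholds and applicability rules", {
  coh <- blank_cohort(7)
  coh$birthweight_g  <- c(1749, 1750, 3300, NA, 3300, NA, 1000)
  coh$apgar5         <- c(9L, 7L, 6L, 6L, 9L, NA, 9L)
  coh$gestational_age_weeks <- c(39, 33, 39, NA, 32.9, NA, 39)
  coh$vital_status_at_birth[7] <- "fetal_death"
  expect_identical(neonatal_near_miss(coh),
                   c(TRUE,   # 1749 g: boundary, strict <1750
                     FALSE,  # 1750 g / Apgar 7 / 33 wk: none qualifies
                     TRUE,   # Apgar 6
                     TRUE,   # Apgar 6 alone, others unrecorded
                     TRUE,   # 32.9 weeks
                     NA,     # nothing assessable
                     NA))    # fetal death: not applicable
})
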
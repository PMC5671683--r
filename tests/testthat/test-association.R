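test_that("crude PR basics: symmetry, interval shape, zero-cell flag", {
  r <- crude_pr(25, 75, 25, 75)
  expect_equal(r$pr, 1)
  expect_lte(r$ci_low, r$pr); expect_gte(r$ci_high, r$pr)
  expect_true(r$pr > 0)

  r0 <- crude_pr(0, 50, 10, 40)
  expect_true(is.na(r0$ci_low))
  expect_match(r0$note, "CI not defined")
  expect_error(crude_pr(0, 0, 5, 5))
})

test_that("crude PR equals the one-covariate log-binomial coefficient (oracle equivalence)", {
  cfg <- sim_config(n = 8000, seed = 31,
                    class_mixture = c(MD = 0, MNM = .08, PLTC = 0, LSMM = 0,
                                      NONE = .92),
                    covariate_effects = list(
                      MNM = list(parity = c(nullipara = log(1.8)))),
                    missingness_rates = c(maternal_age = 0))
  coh <- classify_cohort(generate_cohort(cfg))
  yy <- coh$severity == "MNM"
  ex <- coh$parity == "nullipara"
  manual <- crude_pr(sum(yy & ex), sum(!yy & ex), sum(yy & !ex), sum(!yy & !ex))
  fit <- adjusted_pr(coh, "MNM", covariates = "parity", cluster = NULL)
  expect_equal(fit$adjusted_pr, manual$pr, tolerance = 1e-6)
  expect_equal(fit$crude_pr, manual$pr, tolerance = 1e-12)
})

test_that("reference categories give PR 1 implicitly and effects are recovered", {
  cfg <- sim_config(n = 20000, seed = 32,
                    class_mixture = c(MD = 0, MNM = .06, PLTC = 0, LSMM = 0,
                                      NONE = .94),
                    covariate_effects = list(
                      MNM = list(risk_exposure = c(present = log(2)),
                                 parity = c(nullipara = log(1.3)))),
                    missingness_rates = c(maternal_age = 0))
  coh <- classify_cohort(generate_cohort(cfg))
  res <- adjusted_pr(coh, "MNM", c("risk_exposure", "parity"))
  expect_identical(res$reference, c("absent", "multipara"))
  expect_true(all(res$adjusted_low <= res$adjusted_pr &
                    res$adjusted_pr <= res$adjusted_high))
  got <- res$adjusted_pr[match(c("present", "nullipara"), res$category)]
  expect_equal(got, c(2, 1.3), tolerance = 0.18)
  expect_equal(attr(res, "n_clusters"), 12L)
})

test_that("cluster-robust intervals widen under positive intra-cluster correlation", {
  cfg <- sim_config(n = 12000, seed = 33, cluster_sd = 0.6,
                    class_mixture = c(MD = 0, MNM = .07, PLTC = 0, LSMM = 0,
                                      NONE = .93),
                    missingness_rates = c(maternal_age = 0))
  coh <- classify_cohort(generate_cohort(cfg))
  clustered <- adjusted_pr(coh, "MNM", "parity", cluster = "cluster_id")
  expect_warning(
    plain <- adjusted_pr(transform(coh, cluster_id = "C01"), "MNM", "parity"),
    "fewer than 2 clusters")
  width <- function(x) log(x$adjusted_high) - log(x$adjusted_low)
  # the outcome rate varies strongly by cluster; the intercept picks that
  # up, and for the covariate the clustered interval must not be narrower
  # by more than the t-vs-z critical-value ratio
  expect_gte(width(clustered), width(plain) * 0.9)
})

test_that("complete-case restriction and outcome subsetting are applied", {
  coh <- classify_cohort(generate_cohort(sim_config(n = 6000, seed = 34)))
  res <- adjusted_pr(coh, "MNM", c("risk_exposure"))
  n_cc <- sum(coh$severity %in% c("MNM", "NONE") & !is.na(coh$risk_exposure))
  expect_equal(sum(res$n[res$variable == "risk_exposure"]),
               sum(coh$severity %in% c("MNM", "NONE") &
                     coh$risk_exposure == "present", na.rm = TRUE))
  expect_lt(n_cc, sum(coh$severity %in% c("MNM", "NONE")))  # missingness real
  expect_error(adjusted_pr(coh, "MNM", "nonexistent_covariate"), "unknown")
})
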
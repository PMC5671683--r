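test_that("with a single cluster the corrected test is the Pearson test", {
  var <- rep(c("a", "a", "b", "b"), c(10, 20, 30, 40))
  by <- rep(c("x", "y", "x", "y"), c(10, 20, 30, 40))
  expect_warning(res <- rao_scott_chi2(var, by, rep("only", 100)),
                 "fewer than 2 clusters")
  expect_equal(res$deff, 1)
  expect_equal(res$chi2_corrected, res$chi2_uncorrected)
  expect_equal(res$chi2_uncorrected, pearson_2x2(10, 20, 30, 40))
  expect_equal(res$p_corrected,
               pchisq(pearson_2x2(10, 20, 30, 40), 1, lower.tail = FALSE))
})

test_that("degenerate tables give a not-defined result with an explanation", {
  res <- rao_scott_chi2(rep("a", 50), rep(c("x", "y"), 25),
                        rep(c("C1", "C2"), 25))
  expect_true(is.na(res$chi2_corrected))
  expect_match(res$note, "degenerate")
})

test_that("crosstab partitions non-missing records and reports missingness", {
  # every record NONE with the flag absent: a single occupied cell
  coh <- classify_cohort(blank_cohort(40))
  tab <- crosstab(coh, "prev_any", cluster = NULL)
  expect_equal(sum(tab$counts), 40)
  expect_equal(tab$counts["absent", "NONE"], 40)
  expect_equal(tab$missing_pct, 0)

  # balanced two-class, two-category cohort: all cells n/4
  coh <- blank_cohort(80)
  coh$anaemia[41:80] <- "present"              # half LSMM, half NONE
  coh$prev_any <- rep(c("present", "absent"), 40)
  coh$prev_hypertension <- coh$prev_any
  coh <- classify_cohort(coh)
  tab <- crosstab(coh, "prev_any", cluster = NULL)
  expect_true(all(tab$counts[, c("LSMM", "NONE")] == 20))
  expect_true(all(tab$col_pct[, c("LSMM", "NONE")] == 50))

  # missing variable values leave cells but enter the missing fraction
  coh$prev_any[1:8] <- NA
  tab <- crosstab(coh, "prev_any", cluster = NULL)
  expect_equal(tab$missing_pct, 10)
  expect_equal(sum(tab$counts), 72)
  expect_error(crosstab(coh, "no_such_var"), "unknown variable")
})

test_that("a seeded neonatal near-miss gradient is recovered in the crosstab", {
  cfg <- sim_config(n = 60000, seed = 13)
  coh <- classify_cohort(generate_cohort(cfg))
  tab <- crosstab(coh, "neonatal_near_miss")
  p_hat <- tab$col_pct["yes", ] / 100
  n_col <- colSums(tab$counts)
  truth <- cfg$neonatal_gradient[colnames(tab$counts)]
  # masked neonatal fields shift observed rates slightly below truth;
  # allow binomial error on top of that small bias
  for (k in c("MNM", "PLTC", "LSMM", "NONE")) {
    se <- sqrt(truth[[k]] * (1 - truth[[k]]) / n_col[[k]])
    expect_lt(abs(p_hat[[k]] - truth[[k]]), 3 * se + 0.01)
  }
  # and the gradient ordering itself is reproduced
  expect_true(p_hat[["MNM"]] > p_hat[["PLTC"]])
  expect_true(p_hat[["LSMM"]] > p_hat[["NONE"]])
})

test_that("under between-cluster heterogeneity the corrected test is the less anticonservative", {
  set.seed(4021)
  n_k <- 60; K <- 12; reps <- 2000
  # the compared factor is cluster-level, the trait probability varies by
  # cluster: the naive Pearson test then badly overstates the evidence
  p_base <- stats::rbeta(reps * K, 8, 8)
  cl <- rep(sprintf("C%02d", 1:K), each = n_k)
  by <- rep(rep(c("x", "y"), each = K / 2), each = n_k)
  rej_u <- rej_c <- logical(reps)
  for (r in seq_len(reps)) {
    pk <- rep(p_base[(r - 1) * K + 1:K], each = n_k)
    var <- ifelse(stats::runif(K * n_k) < pk, "a", "b")
    res <- rao_scott_chi2(var, by, cl)
    rej_u[r] <- res$p_uncorrected < 0.05
    rej_c[r] <- res$p_corrected < 0.05
  }
  expect_lte(mean(rej_c), mean(rej_u))
  expect_gt(mean(rej_u), 0.3)   # the naive test really is broken here
  expect_lt(mean(rej_c), 0.3)
})
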
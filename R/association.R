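# Prevalence ratios of each adverse-outcome class versus the no-morbidity
# reference group. Crude PRs come straight from the 2x2 counts with the Katz
# log-normal confidence interval. Adjusted PRs come from a log-link binomial
# model (modified Poisson fallback on non-convergence) with a PSU-clustered
# sandwich covariance; cluster-robust intervals use t critical values on
# K - 1 degrees of freedom.

#' Reference levels for the standard analysis covariates
#'
#' @return Named list mapping covariate to its reference category.
#' @export
reference_levels <- function() {
  list(maternal_age_group = "20-24",
       ethnicity = "white",
       literacy = "secondary_or_university",
       marital_status = "married_or_stable",
       parity = "multipara",
       prev_any = "absent",
       prenatal_visits_group = ">4",
       risk_exposure = "absent",
       previous_csection = "absent",
       labour_onset = "spontaneous",
       delivery_mode = "vaginal")
}

#' Crude prevalence ratio from 2x2 counts
#'
#' For an analysis population restricted to one outcome class plus the
#' no-morbidity reference group: \code{a} outcome & exposed, \code{b}
#' no-morbidity & exposed, \code{c} outcome & unexposed, \code{d}
#' no-morbidity & unexposed. PR = (a/(a+b)) / (c/(c+d)), with the Katz
#' log-normal 95\% interval exp(log PR +/- z * sqrt(1/a - 1/(a+b) + 1/c -
#' 1/(c+d))).
#'
#' @param a,b,c,d Cell counts (see above).
#' @param conf_level Confidence level, default 0.95.
#' @return A \code{pr_result} data frame row: \code{pr}, \code{ci_low},
#'   \code{ci_high}, \code{n_exposed}, \code{n_unexposed}. With a zero
#'   outcome count in either arm the interval is \code{NA} and the estimate
#'   is flagged in \code{note}.
#' @export
#' @examples
#' crude_pr(90, 14493, 897, 398396)  # maternal death vs any previous condition
crude_pr <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a + b > 0, c + d > 0)
  p1 <- a / (a + b)
  p0 <- c / (c + d)
  pr <- p1 / p0
  note <- NA_character_
  if (a == 0 || c == 0) {
    lo <- hi <- NA_real_
    note <- "zero outcome count: CI not defined"
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
    lo <- exp(log(pr) - z * se)
    hi <- exp(log(pr) + z * se)
  }
  structure(data.frame(pr = pr, ci_low = lo, ci_high = hi,
                       n_exposed = a + b, n_unexposed = c + d,
                       note = note),
            class = c("pr_result", "data.frame"))
}

.fit_log_binomial <- function(formula, data) {
  # log-binomial first; modified Poisson (log-link, robust variance) when the
  # log-binomial fails to converge or steps outside the parameter space
  y <- stats::model.response(stats::model.frame(formula, data))
  start <- c(log(max(mean(y), 1e-6)),
             rep(0, ncol(stats::model.matrix(formula, data)) - 1L))
  fit <- tryCatch(
    suppressWarnings(stats::glm(formula, data = data,
                                family = stats::binomial(link = "log"),
                                start = start,
                                control = stats::glm.control(
                                  epsilon = 1e-8, maxit = 100))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && !fit$boundary)
    return(list(fit = fit, family = "log-binomial"))
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::poisson(link = "log"),
                                     control = stats::glm.control(
                                       epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("neither log-binomial nor modified-Poisson fit converged")
  list(fit = fit, family = "modified-poisson")
}

#' Adjusted prevalence ratios for one outcome class
#'
#' Restricts the cohort to the records in the requested severity class plus
#' the no-morbidity group, drops records with any model variable unrecorded
#' (complete case), and fits a log-link binomial model of class membership
#' on all covariates simultaneously (modified Poisson on non-convergence).
#' Exponentiated coefficients are the adjusted PRs. Confidence intervals use
#' a cluster-robust (PSU-grouped) sandwich covariance with t critical values
#' on K - 1 degrees of freedom; with fewer than 2 clusters an unclustered
#' robust covariance is used with a warning. Crude PRs per covariate are
#' computed from the corresponding 2x2 (complete case per covariate) via
#' \code{\link{crude_pr}}.
#'
#' @param classified A cohort with a \code{severity} column.
#' @param outcome Severity class: \code{"MD"}, \code{"MNM"}, \code{"PLTC"}
#'   or \code{"LSMM"}.
#' @param covariates Character vector of categorical/flag columns (derived
#'   strata are added automatically).
#' @param cluster Name of the PSU column, or \code{NULL} for unclustered.
#' @param conf_level Confidence level, default 0.95.
#' @return A data frame, one row per non-reference covariate category:
#'   \code{outcome}, \code{variable}, \code{category}, \code{reference},
#'   \code{crude_pr}, \code{crude_low}, \code{crude_high},
#'   \code{adjusted_pr}, \code{adjusted_low}, \code{adjusted_high},
#'   \code{n}, plus attributes \code{family} and \code{n_clusters}.
#' @export
adjusted_pr <- function(classified, outcome, covariates,
                        cluster = "cluster_id", conf_level = 0.95) {
  outcome <- match.arg(outcome, c("MD", "MNM", "PLTC", "LSMM"))
  if (is.null(classified$severity))
    stop("cohort has no severity column; run classify_cohort() first")
  classified <- derive_strata(classified)
  miss <- setdiff(covariates, names(classified))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))

  dat <- classified[classified$severity %in% c(outcome, "NONE"), , drop = FALSE]
  keep_cols <- c("severity", covariates, cluster)
  dat <- dat[stats::complete.cases(dat[keep_cols]), , drop = FALSE]
  if (!nrow(dat)) stop("no complete-case records for this model")
  dat$.y <- as.integer(dat$severity == outcome)

  refs <- reference_levels()
  for (v in covariates) {
    f <- factor(dat[[v]])
    if (!is.null(refs[[v]]) && refs[[v]] %in% levels(f))
      f <- stats::relevel(f, ref = refs[[v]])
    dat[[v]] <- f
  }

  form <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fitted <- .fit_log_binomial(form, dat)
  fit <- fitted$fit

  n_clusters <- 0L
  if (!is.null(cluster)) {
    cl <- factor(dat[[cluster]])
    n_clusters <- nlevels(cl)
  }
  if (!is.null(cluster) && n_clusters >= 2L) {
    V <- sandwich::vcovCL(fit, cluster = cl)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df = n_clusters - 1L)
  } else {
    if (!is.null(cluster))
      warning("fewer than 2 clusters: using unclustered robust variance")
    V <- sandwich::vcovHC(fit, type = "HC0")
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(V))

  rows <- list()
  for (v in covariates) {
    lv <- levels(dat[[v]])
    for (cat in lv[-1L]) {
      term <- paste0(v, cat)
      if (!term %in% names(beta) || is.na(beta[term])) {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outcome, variable = v, category = cat,
          reference = lv[1L], crude_pr = NA_real_, crude_low = NA_real_,
          crude_high = NA_real_, adjusted_pr = NA_real_,
          adjusted_low = NA_real_, adjusted_high = NA_real_,
          n = NA_integer_)
        next
      }
      # crude 2x2, complete case on this covariate only
      cc <- classified[classified$severity %in% c(outcome, "NONE") &
                         !is.na(classified[[v]]), , drop = FALSE]
      expd <- as.character(cc[[v]]) == cat
      refd <- as.character(cc[[v]]) == lv[1L]
      yy <- cc$severity == outcome
      cr <- crude_pr(sum(expd & yy), sum(expd & !yy),
                     sum(refd & yy), sum(refd & !yy),
                     conf_level = conf_level)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = outcome, variable = v, category = cat, reference = lv[1L],
        crude_pr = cr$pr, crude_low = cr$ci_low, crude_high = cr$ci_high,
        adjusted_pr = exp(beta[[term]]),
        adjusted_low = exp(beta[[term]] - crit * se[[term]]),
        adjusted_high = exp(beta[[term]] + crit * se[[term]]),
        n = sum(dat[[v]] == cat))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family") <- fitted$family
  attr(out, "n_clusters") <- n_clusters
  out
}
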
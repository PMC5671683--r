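# Severity-stratified contingency tables with chi-square tests corrected for
# the cluster design effect (each cluster/country is one primary sampling
# unit). The correction is the first-order Rao-Scott adjustment: the Pearson
# statistic is divided by an average design effect estimated from the
# between-PSU variance of the cell proportions, and referred to the same
# degrees of freedom.

.table_var <- function(classified, variable) {
  if (!variable %in% names(classified)) {
    classified <- derive_strata(classified)
    if (!variable %in% names(classified))
      stop("unknown variable '", variable, "'")
  }
  x <- classified[[variable]]
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  as.character(x)
}

#' First-order design-effect-corrected chi-square test
#'
#' Computes the Pearson chi-square for \code{table(var, by)} and corrects it
#' for clustered sampling: for each cell, the design effect is the ratio of
#' the cluster-sample variance of the cell proportion (clusters as PSUs,
#' with-replacement approximation) to its simple-random-sampling variance;
#' the Pearson statistic is divided by the unweighted mean of the cell
#' design effects and compared to a chi-square on the same degrees of
#' freedom. With a single cluster the design effect is 1 by construction and
#' the test reduces exactly to the uncorrected Pearson test (a warning is
#' issued).
#'
#' @param var,by Vectors defining the two-way table (records with \code{NA}
#'   in either are dropped).
#' @param cluster Per-record PSU labels.
#' @return List with \code{chi2_uncorrected}, \code{deff},
#'   \code{chi2_corrected}, \code{df}, \code{p_uncorrected},
#'   \code{p_corrected}, \code{n}, \code{n_clusters}. Degenerate tables
#'   (any zero margin, or fewer than 2 levels either way) give \code{NA}
#'   statistics with a \code{note}.
#' @export
rao_scott_chi2 <- function(var, by, cluster) {
  keep <- !is.na(var) & !is.na(by) & !is.na(cluster)
  var <- as.character(var)[keep]
  by <- as.character(by)[keep]
  cluster <- as.character(cluster)[keep]
  n <- length(var)
  tab <- table(var, by)
  out <- list(chi2_uncorrected = NA_real_, deff = NA_real_,
              chi2_corrected = NA_real_,
              df = NA_real_, p_uncorrected = NA_real_,
              p_corrected = NA_real_, n = n,
              n_clusters = length(unique(cluster)), note = NULL)
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    out$note <- "degenerate table: need two non-empty levels on both margins"
    return(out)
  }
  X2 <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  out$chi2_uncorrected <- unname(X2)
  out$df <- df
  out$p_uncorrected <- stats::pchisq(X2, df, lower.tail = FALSE)

  K <- out$n_clusters
  if (K < 2L) {
    warning("fewer than 2 clusters: falling back to the uncorrected test")
    out$deff <- 1
    out$chi2_corrected <- out$chi2_uncorrected
    out$p_corrected <- out$p_uncorrected
    return(out)
  }
  cl <- factor(cluster)
  n_k <- tabulate(cl, nbins = K)
  deffs <- numeric(0)
  for (r in rownames(tab)) for (c in colnames(tab)) {
    p_hat <- tab[r, c] / n
    if (p_hat <= 0 || p_hat >= 1) next
    t_k <- tabulate(cl[var == r & by == c], nbins = K)
    # with-replacement PSU variance of the estimated cell proportion
    v_clu <- K / (K - 1) * sum((t_k - n_k * p_hat)^2) / n^2
    v_srs <- p_hat * (1 - p_hat) / n
    deffs <- c(deffs, v_clu / v_srs)
  }
  deff <- if (length(deffs)) mean(deffs) else 1
  out$deff <- deff
  out$chi2_corrected <- unname(X2) / deff
  out$p_corrected <- stats::pchisq(out$chi2_corrected, df, lower.tail = FALSE)
  out
}

#' Cross-tabulate a variable against the severity classes
#'
#' Builds the severity-stratified table for one characteristic or outcome:
#' cell counts and within-class column percentages over the records with the
#' variable recorded, the fraction unrecorded, and (when cluster labels are
#' available) the design-effect-corrected chi-square test.
#'
#' @param classified A cohort with a \code{severity} column.
#' @param variable A categorical/flag schema field, a derived stratum (see
#'   \code{\link{derive_strata}}), or \code{"neonatal_near_miss"}.
#' @param cluster Name of the cluster (PSU) column; \code{NULL} skips the
#'   corrected test.
#' @return A \code{strat_table} object: list with \code{variable},
#'   \code{counts} (categories x classes), \code{col_pct},
#'   \code{missing_pct}, and the \code{\link{rao_scott_chi2}} fields.
#' @export
#' @examples
#' coh <- classify_cohort(generate_cohort(sim_config(n = 2000, seed = 7)))
#' crosstab(coh, "neonatal_near_miss")
crosstab <- function(classified, variable, cluster = "cluster_id") {
  if (is.null(classified$severity))
    stop("cohort has no severity column; run classify_cohort() first")
  x <- .table_var(classified, variable)
  sev <- factor(classified$severity, levels = .severity_levels)
  counts <- table(category = x, severity = sev)
  col_pct <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/") * 100
  out <- list(variable = variable,
              counts = unclass(counts),
              col_pct = unclass(col_pct),
              missing_pct = 100 * mean(is.na(x)))
  if (!is.null(cluster)) {
    cl <- classified[[cluster]]
    if (is.null(cl)) stop("unknown cluster column '", cluster, "'")
    out <- c(out, rao_scott_chi2(x, as.character(sev), cl))
  }
  structure(out, class = "strat_table")
}

#' @export
print.strat_table <- function(x, ...) {
  cat("Stratified table:", x$variable,
      sprintf("(missing %.1f%%)\n", x$missing_pct))
  disp <- matrix(sprintf("%d (%.1f)", x$counts, x$col_pct),
                 nrow = nrow(x$counts),
                 dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  if (!is.null(x$p_corrected) && !is.na(x$p_corrected))
    cat(sprintf("Chi2 = %.2f, deff = %.2f, corrected Chi2 = %.2f on %d df, p = %.4g (%d clusters)\n",
                x$chi2_uncorrected, x$deff, x$chi2_corrected, x$df,
                x$p_corrected, x$n_clusters))
  invisible(x)
}

#' Derive the conventional analysis strata
#'
#' Adds the grouped covariates used in stratified and regression analyses:
#' \code{maternal_age_group} (10-19, 20-24, 25-29, 30-34, 35-55) and
#' \code{prenatal_visits_group} (0, 1-4, >4).
#'
#' @param cohort A cohort data frame.
#' @return The cohort with the two derived columns appended.
#' @export
derive_strata <- function(cohort) {
  age <- cohort$maternal_age
  cohort$maternal_age_group <- as.character(
    cut(age, breaks = c(10, 19, 24, 29, 34, 55),
        labels = c("10-19", "20-24", "25-29", "30-34", "35-55"),
        include.lowest = TRUE))
  v <- cohort$prenatal_visits
  cohort$prenatal_visits_group <-
    ifelse(is.na(v), NA_character_,
           ifelse(v == 0, "0", ifelse(v <= 4, "1-4", ">4")))
  cohort
}
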
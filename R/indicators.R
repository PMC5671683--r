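# The surveillance indicator panel. Percentages are over all women in the
# cohort; ratios are per live births: MMR per 100,000, the morbidity ratios
# (MNMR, SMOR, PLTCR, LSMMR, AMMR) per 1,000. The morbidity-to-death ratio
# counts survivors with any morbidity per maternal death.

#' Count live births in a cohort
#'
#' Records with \code{vital_status_at_birth == "live"}; unrecorded vital
#' status is counted as non-live (and reported via \code{\link{missingness}}).
#'
#' @param cohort A cohort data frame.
#' @return Integer count.
#' @export
count_live_births <- function(cohort) {
  vs <- cohort$vital_status_at_birth
  sum(!is.na(vs) & vs == "live")
}

#' Surveillance indicator panel
#'
#' Computes, from a classified cohort or from explicit class counts, the
#' panel of maternal-health surveillance indicators: per-class counts,
#' percentages of all women, and live-birth-denominated ratios --
#' MMR (maternal deaths per 100,000 live births) and MNMR, SMOR, PLTCR,
#' LSMMR, AMMR (per 1,000 live births) -- plus the morbidity-to-death ratio
#' (AMM - MD)/MD, the number of women surviving any morbidity per maternal
#' death.
#'
#' All values are kept unrounded; the print method applies the conventional
#' display rounding (ratios to 1 decimal, MD percentage to 2 decimals,
#' other percentages to 1, morbidity-to-death ratio to the nearest
#' integer).
#'
#' @param classified A cohort with a \code{severity} column (ignored when
#'   \code{counts} is given).
#' @param counts Optional named vector of class counts (\code{MD},
#'   \code{MNM}, \code{PLTC}, \code{LSMM}, \code{NONE}) to use instead of a
#'   cohort, e.g. counts transcribed from a published table.
#' @param n_live_births Live-birth denominator; required with \code{counts},
#'   otherwise computed by \code{\link{count_live_births}}.
#' @return An \code{indicator_panel} object: list with \code{n_women},
#'   \code{n_live_births}, \code{counts} (incl. SMO and AMM),
#'   \code{percent}, \code{ratios} (MMR, MNMR, SMOR, PLTCR, LSMMR, AMMR),
#'   and \code{morbidity_to_death_ratio} (\code{NA} if no deaths).
#' @export
#' @examples
#' panel <- indicator_panel(counts = c(MD = 1028, MNM = 21985, PLTC = 110038,
#'                                     LSMM = 137589, NONE = 441441),
#'                          n_live_births = 697820)
#' panel
indicator_panel <- function(classified = NULL, counts = NULL,
                            n_live_births = NULL) {
  if (is.null(counts)) {
    if (is.null(classified))
      stop("supply a classified cohort or explicit class counts")
    if (any(is.na(classified$severity)))
      stop("every record must be classified")
    sc <- severity_counts(classified)
    counts <- sc[c("MD", "MNM", "PLTC", "LSMM", "NONE")]
    if (is.null(n_live_births)) n_live_births <- count_live_births(classified)
  } else {
    need <- c("MD", "MNM", "PLTC", "LSMM", "NONE")
    if (!all(need %in% names(counts)))
      stop("counts must name ", paste(need, collapse = ", "))
    counts <- counts[need]
    if (is.null(n_live_births))
      stop("n_live_births is required with explicit counts")
  }
  if (n_live_births <= 0) stop("live-birth denominator must be positive")
  n_women <- sum(counts)
  if (n_live_births > n_women)
    warning("more live births than women; check for multiple gestation")

  full <- c(counts["MD"], counts["MNM"], SMO = unname(counts["MD"] + counts["MNM"]),
            counts["PLTC"], counts["LSMM"],
            AMM = unname(sum(counts[c("MD", "MNM", "PLTC", "LSMM")])),
            counts["NONE"])
  percent <- 100 * full / n_women
  per_lb <- function(k, scale) scale * full[[k]] / n_live_births
  ratios <- c(MMR = per_lb("MD", 1e5), MNMR = per_lb("MNM", 1e3),
              SMOR = per_lb("SMO", 1e3), PLTCR = per_lb("PLTC", 1e3),
              LSMMR = per_lb("LSMM", 1e3), AMMR = per_lb("AMM", 1e3))
  mdr <- if (full[["MD"]] > 0)
    (full[["AMM"]] - full[["MD"]]) / full[["MD"]] else NA_real_

  structure(list(n_women = n_women, n_live_births = n_live_births,
                 counts = full, percent = percent, ratios = ratios,
                 morbidity_to_death_ratio = mdr),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat("Maternal morbidity indicator panel\n")
  cat(sprintf("  Women: %s   Live births: %s\n",
              format(x$n_women, big.mark = ","),
              format(x$n_live_births, big.mark = ",")))
  pct <- ifelse(names(x$percent) == "MD", sprintf("%.2f", x$percent),
                sprintf("%.1f", x$percent))
  ratio_name <- c(MD = "MMR", MNM = "MNMR", SMO = "SMOR", PLTC = "PLTCR",
                  LSMM = "LSMMR", AMM = "AMMR")
  scale_txt <- c(MMR = "/100,000 LB", MNMR = "/1000 LB", SMOR = "/1000 LB",
                 PLTCR = "/1000 LB", LSMMR = "/1000 LB", AMMR = "/1000 LB")
  for (k in names(x$counts)) {
    line <- sprintf("  %-5s %10s  %5s%%", k,
                    format(x$counts[[k]], big.mark = ","), pct[[match(k, names(x$percent))]])
    if (k %in% names(ratio_name)) {
      rn <- ratio_name[[k]]
      line <- paste0(line, sprintf("   %s = %.1f%s", rn, x$ratios[[rn]],
                                   scale_txt[[rn]]))
    }
    cat(line, "\n")
  }
  if (!is.na(x$morbidity_to_death_ratio))
    cat(sprintf("  Survivors with any morbidity per maternal death: %d\n",
                round(x$morbidity_to_death_ratio)))
  invisible(x)
}

#' Flatten an indicator panel for export
#'
#' @param x An \code{indicator_panel}.
#' @return A named list of bare numbers suitable for JSON export.
#' @export
panel_as_list <- function(x) {
  stopifnot(inherits(x, "indicator_panel"))
  out <- c(list(n_women = x$n_women, n_live_births = x$n_live_births),
           as.list(x$counts), stats::setNames(as.list(x$percent),
                                              paste0("pct_", names(x$percent))),
           as.list(x$ratios),
           list(morbidity_to_death_ratio = x$morbidity_to_death_ratio))
  lapply(out, unname)
}
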
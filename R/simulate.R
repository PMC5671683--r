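# Synthetic registry generator. Emulates a multi-country perinatal registry:
# records are drawn cluster by cluster with a known severity mixture,
# covariate-dependent class probabilities (log-linear tilts), a
# class-conditional neonatal gradient, and MCAR missingness at per-field
# rates. Criterion flags are set so that the classifier recovers the
# intended class exactly, which is what makes every downstream stage
# testable against known truth.

.default_mixture <- c(MD = 1028, MNM = 21985, PLTC = 110038,
                      LSMM = 137589, NONE = 441441) / 712081

.default_nnm_gradient <- c(MD = 0.131, MNM = 0.145, PLTC = 0.052,
                           LSMM = 0.064, NONE = 0.049)

.default_stillbirth <- c(MD = 0.049, MNM = 0.025, PLTC = 0.020,
                         LSMM = 0.022, NONE = 0.019)

.default_missingness <- c(
  maternal_age = 0.004, ethnicity = 0.069, literacy = 0.041,
  marital_status = 0.042, parity = 0.076, prenatal_visits = 0.076,
  risk_exposure = 0.311, previous_csection = 0.168, labour_onset = 0.054,
  delivery_mode = 0.012, previous_conditions = 0.124,
  gestational_age_weeks = 0.061, birthweight_g = 0.020, apgar5 = 0.030,
  child_discharge_status = 0.155)

.default_prevalences <- list(
  maternal_age_group = c("10-19" = 0.248, "20-24" = 0.293, "25-29" = 0.219,
                         "30-34" = 0.147, "35-55" = 0.093),
  ethnicity = c(white = 0.223, mixed = 0.730, other = 0.047),
  literacy = c(none_or_primary = 0.483, secondary_or_university = 0.517),
  marital_status = c(married_or_stable = 0.867, single_or_other = 0.133),
  parity = c(nullipara = 0.380, multipara = 0.620),
  prenatal_visits_group = c("0" = 0.077, "1-4" = 0.289, ">4" = 0.634),
  risk_exposure = c(present = 0.096, absent = 0.904),
  previous_csection = c(present = 0.143, absent = 0.857),
  labour_onset = c(spontaneous = 0.827, induced = 0.050,
                   elective_csection = 0.123),
  prev_conditions = c(prev_diabetes = 0.002, prev_hypertension = 0.011,
                      prev_preeclampsia = 0.009, prev_eclampsia = 0.001,
                      prev_cardiac_disease = 0.001, prev_renal_disease = 0.001,
                      prev_other_severe = 0.013))

#' Configuration for the synthetic registry generator
#'
#' Defaults emulate a 12-country registry: the severity mixture is the
#' observed class distribution of a large Latin American/Caribbean birth
#' registry (MD 0.14\%, MNM 3.1\%, PLTC 15.5\%, LSMM 19.3\%, none 62\%),
#' the neonatal near-miss gradient rises with maternal severity
#' (4.9\%/6.4\%/5.2\%/14.5\%/13.1\% for none/LSMM/PLTC/MNM/MD), and
#' per-field missingness matches routinely observed registry completeness
#' (0.4\% for age up to 31.1\% for the risk-exposure composite; previous
#' conditions are masked jointly so the derived any-previous flag stays
#' consistent with its components).
#'
#' @param n Total number of records (ignored when \code{cluster_sizes} is
#'   given).
#' @param seed Integer seed; fully determines the cohort.
#' @param n_clusters Number of clusters (PSUs/countries), default 12.
#' @param cluster_sizes Optional explicit per-cluster record counts.
#' @param class_mixture Probabilities over \code{MD, MNM, PLTC, LSMM, NONE};
#'   must sum to 1.
#' @param covariate_effects Per-class log-linear tilts: a named list
#'   \code{list(MNM = list(risk_exposure = c(present = log(2))), ...)}
#'   multiplying that class's probability by \code{exp(effect)} for records
#'   in the named category. Effects that push any probability past 1 (or
#'   the no-morbidity remainder below 0) are a configuration error.
#' @param covariate_prevalences Baseline category probabilities (see
#'   defaults).
#' @param missingness_rates Named per-field MCAR masking probabilities;
#'   \code{previous_conditions} masks the previous-condition block jointly.
#' @param neonatal_gradient Neonatal near-miss probability per severity
#'   class (live births).
#' @param stillbirth_rate Fetal-death probability per severity class.
#' @param cluster_sd Standard deviation of a log-normal per-cluster tilt on
#'   the morbidity-class probabilities (0 = homogeneous clusters).
#' @param mask_criteria Also mask condition flags (including the flags that
#'   carry each record's class) at 3\%; intended for robustness
#'   experiments -- label fidelity is then no longer guaranteed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n = 10000, seed = 1, n_clusters = 12,
                       cluster_sizes = NULL,
                       class_mixture = .default_mixture,
                       covariate_effects = list(),
                       covariate_prevalences = .default_prevalences,
                       missingness_rates = .default_missingness,
                       neonatal_gradient = .default_nnm_gradient,
                       stillbirth_rate = .default_stillbirth,
                       cluster_sd = 0,
                       mask_criteria = FALSE) {
  if (!is.null(cluster_sizes)) {
    n_clusters <- length(cluster_sizes)
    n <- sum(cluster_sizes)
  }
  stopifnot(n >= 1, n_clusters >= 1, seed == round(seed))
  need <- c("MD", "MNM", "PLTC", "LSMM", "NONE")
  if (!all(need %in% names(class_mixture)))
    stop("class_mixture must name ", paste(need, collapse = ", "))
  class_mixture <- class_mixture[need]
  if (abs(sum(class_mixture) - 1) > 1e-8)
    stop("class_mixture must sum to 1")
  if (any(class_mixture < 0 | class_mixture > 1))
    stop("class_mixture entries must be probabilities")
  for (p in missingness_rates)
    if (p < 0 || p > 1) stop("missingness rates must be in [0, 1]")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 n_clusters = as.integer(n_clusters),
                 cluster_sizes = cluster_sizes,
                 class_mixture = class_mixture,
                 covariate_effects = covariate_effects,
                 covariate_prevalences = covariate_prevalences,
                 missingness_rates = missingness_rates,
                 neonatal_gradient = neonatal_gradient[need],
                 stillbirth_rate = stillbirth_rate[need],
                 cluster_sd = cluster_sd,
                 mask_criteria = isTRUE(mask_criteria)),
            class = "sim_config")
}

.sample_cat <- function(n, probs)
  names(probs)[1L + findInterval(stats::runif(n), cumsum(probs) / sum(probs))]

#' Generate a synthetic cohort
#'
#' Draws a cohort under a \code{\link{sim_config}}: cluster assignment,
#' covariates, a covariate- and cluster-tilted severity class per record,
#' then the condition flags that realise that class under the default
#' criteria (one criterion per record, chosen at random within the class's
#' rule list; maternal deaths additionally carry a severe condition),
#' class-conditional neonatal outcomes, and finally MCAR missingness on the
#' non-criterion fields. The generative truth (intended class, realised
#' criterion, neonatal near-miss state before masking) is attached for
#' \code{\link{truth_table}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A cohort data frame with attributes \code{"truth"} and
#'   \code{"sim_config"}.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n = 1000, seed = 42))
#' table(classify_cohort(coh)$severity)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  K <- config$n_clusters
  prev <- config$covariate_prevalences

  sizes <- config$cluster_sizes
  if (is.null(sizes))
    sizes <- as.vector(stats::rmultinom(1, n, rep(1 / K, K)))
  cluster_id <- rep(sprintf("C%02d", seq_len(K)), sizes)

  df <- data.frame(record_id = sprintf("R%07d", seq_len(n)),
                   cluster_id = cluster_id)

  age_grp <- .sample_cat(n, prev$maternal_age_group)
  age_lo <- c("10-19" = 14, "20-24" = 20, "25-29" = 25, "30-34" = 30,
              "35-55" = 35)
  age_hi <- c("10-19" = 19, "20-24" = 24, "25-29" = 29, "30-34" = 34,
              "35-55" = 45)
  df$maternal_age <- as.integer(age_lo[age_grp] + floor(
    stats::runif(n) * (age_hi[age_grp] - age_lo[age_grp] + 1L)))
  df$ethnicity <- .sample_cat(n, prev$ethnicity)
  df$literacy <- .sample_cat(n, prev$literacy)
  df$marital_status <- .sample_cat(n, prev$marital_status)
  df$parity <- .sample_cat(n, prev$parity)
  visit_grp <- .sample_cat(n, prev$prenatal_visits_group)
  df$prenatal_visits <- as.integer(ifelse(visit_grp == "0", 0L,
    ifelse(visit_grp == "1-4", sample(1:4, n, replace = TRUE),
           sample(5:12, n, replace = TRUE))))
  df$risk_exposure <- .sample_cat(n, prev$risk_exposure)
  df$previous_csection <- .sample_cat(n, prev$previous_csection)
  df$labour_onset <- .sample_cat(n, prev$labour_onset)
  df$delivery_mode <- ifelse(df$labour_onset == "elective_csection", "csection",
    ifelse(stats::runif(n) < 0.19, "csection", "vaginal"))

  for (f in names(prev$prev_conditions))
    df[[f]] <- ifelse(stats::runif(n) < prev$prev_conditions[[f]],
                      "present", "absent")
  comp <- sapply(names(prev$prev_conditions), function(f) df[[f]] == "present")
  df$prev_any <- ifelse(rowSums(comp) > 0L, "present", "absent")

  # --- severity class: tilted multinomial --------------------------------
  morb <- c("MD", "MNM", "PLTC", "LSMM")
  p <- matrix(rep(config$class_mixture[morb], each = n), nrow = n,
              dimnames = list(NULL, morb))
  for (cls in names(config$covariate_effects)) {
    if (!cls %in% morb) stop("effects may only target morbidity classes")
    for (v in names(config$covariate_effects[[cls]])) {
      if (!v %in% names(df)) stop("effect references unknown field '", v, "'")
      eff <- config$covariate_effects[[cls]][[v]]
      for (cat in names(eff))
        p[df[[v]] == cat, cls] <- p[df[[v]] == cat, cls] * exp(eff[[cat]])
    }
  }
  if (config$cluster_sd > 0) {
    u <- matrix(exp(stats::rnorm(K * length(morb), 0, config$cluster_sd)),
                nrow = K, dimnames = list(NULL, morb))
    k_idx <- rep(seq_len(K), sizes)
    p <- p * u[k_idx, , drop = FALSE]
  }
  p_none <- 1 - rowSums(p)
  if (any(p > 1) || any(p_none < 0))
    stop("infeasible config: covariate/cluster effects push class ",
         "probabilities outside [0, 1]")
  cum <- cbind(t(apply(p, 1L, cumsum)), 1)
  cls <- c(morb, "NONE")[max.col(stats::runif(n) <= cum, ties.method = "first")]

  # --- condition flags realising the class -------------------------------
  all_flags <- c(.mnm_flags, .pltc_flags, .lsmm_flags)
  for (f in all_flags) df[[f]] <- "absent"
  df$death_status <- "alive"
  df$hospital_stay_days <- as.integer(sample(1:6, n, replace = TRUE,
                                             prob = c(.35, .3, .15, .1, .06, .04)))
  crit <- rep(NA_character_, n)

  mnm_opts <- c("eclampsia_or_mgso4", "cardiac_disease", "renal_disease",
                "transfusion_haemorrhage", "prolonged_stay")
  mnm_probs <- c(.35, .15, .10, .25, .15)
  set_mnm_condition <- function(idx) {
    choice <- mnm_opts[.bincode(stats::runif(length(idx)),
                                c(0, cumsum(mnm_probs)))]
    plain <- choice %in% .mnm_flags
    for (f in unique(choice[plain]))
      df[idx[choice == f], f] <<- "present"
    th <- idx[choice == "transfusion_haemorrhage"]
    df[th, "blood_transfusion"] <<- "present"
    df[th, "haemorrhage_any"] <<- "present"
    ps <- idx[choice == "prolonged_stay"]
    df[ps, "hospital_stay_days"] <<- as.integer(sample(8:21, length(ps),
                                                       replace = TRUE))
    choice
  }

  idx <- which(cls == "MD")
  if (length(idx)) {
    df$death_status[idx] <- ifelse(stats::runif(length(idx)) < 0.9,
                                   "died_at_facility",
                                   "died_in_transport_or_referral")
    crit[idx] <- paste0("death+", set_mnm_condition(idx))
  }
  idx <- which(cls == "MNM")
  if (length(idx)) crit[idx] <- set_mnm_condition(idx)
  idx <- which(cls == "PLTC")
  if (length(idx)) {
    opts <- c(.pltc_flags, "blood_transfusion")
    choice <- opts[sample.int(length(opts), length(idx), replace = TRUE)]
    for (f in unique(choice)) df[idx[choice == f], f] <- "present"
    crit[idx] <- choice
  }
  idx <- which(cls == "LSMM")
  if (length(idx)) {
    choice <- .lsmm_flags[sample.int(length(.lsmm_flags), length(idx),
                                     replace = TRUE)]
    for (f in unique(choice)) df[idx[choice == f], f] <- "present"
    crit[idx] <- choice
  }

  # --- neonatal outcomes --------------------------------------------------
  sb <- stats::runif(n) < config$stillbirth_rate[cls]
  df$vital_status_at_birth <- ifelse(sb, "fetal_death", "live")
  nnm <- ifelse(sb, NA, stats::runif(n) < config$neonatal_gradient[cls])

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  bw <- round(clamp(stats::rnorm(n, 3250, 450), 1750, 4800))
  ap <- sample(7:10, n, replace = TRUE, prob = c(.02, .08, .30, .60))
  ga <- round(clamp(stats::rnorm(n, 39, 1.3), 33, 42), 1)
  hit <- which(!is.na(nnm) & nnm)
  if (length(hit)) {
    mode <- sample(c("bw", "apgar", "ga"), length(hit), replace = TRUE)
    i <- hit[mode == "bw"]
    bw[i] <- round(stats::runif(length(i), 600, 1749))
    i <- hit[mode == "apgar"]
    ap[i] <- sample(0:6, length(i), replace = TRUE)
    i <- hit[mode == "ga"]
    ga[i] <- round(stats::runif(length(i), 26, 32.9), 1)
    bw[i] <- round(clamp(stats::rnorm(length(i), 1900, 350), 1750, 2600))
  }
  i <- which(sb)
  if (length(i)) {
    ap[i] <- 0L
    bw[i] <- round(clamp(stats::rnorm(length(i), 2400, 800), 300, 4500))
    ga[i] <- round(clamp(stats::rnorm(length(i), 34, 4), 20, 42), 1)
  }
  df$gestational_age_weeks <- ga
  df$birthweight_g <- bw
  df$apgar5 <- as.integer(ap)

  nd_rate <- c(MD = .036, MNM = .020, PLTC = .008, LSMM = .008, NONE = .006)
  rf_rate <- c(MD = .005, MNM = .013, PLTC = .008, LSMM = .010, NONE = .005)
  u <- stats::runif(n)
  df$child_discharge_status <- ifelse(sb, NA_character_,
    ifelse(u < nd_rate[cls], "neonatal_death",
           ifelse(u < nd_rate[cls] + rf_rate[cls], "referred", "alive")))

  # --- MCAR missingness ---------------------------------------------------
  rates <- config$missingness_rates
  prev_block <- .prev_flags
  for (f in names(rates)) {
    r <- rates[[f]]
    if (r <= 0) next
    if (f == "previous_conditions") {
      mask <- stats::runif(n) < r
      for (g in prev_block) df[[g]][mask] <- NA
    } else if (f %in% names(df)) {
      df[[f]][stats::runif(n) < r] <- NA
    } else {
      stop("missingness rate names unknown field '", f, "'")
    }
  }
  if (config$mask_criteria)
    for (f in c(all_flags, "hospital_stay_days"))
      df[[f]][stats::runif(n) < 0.03] <- NA

  df <- df[.schema_fields()]
  attr(df, "truth") <- data.frame(record_id = df$record_id,
                                  cluster_id = df$cluster_id,
                                  true_class = cls, criterion = crit,
                                  nnm_true = nnm)
  attr(df, "sim_config") <- config
  df
}

#' Generative ground truth of a synthetic cohort
#'
#' @param cohort A cohort produced by \code{\link{generate_cohort}}.
#' @param config Optional \code{\link{sim_config}}; when supplied it must be
#'   the configuration the cohort was generated under.
#' @return Data frame with \code{record_id}, \code{cluster_id},
#'   \code{true_class}, \code{criterion} (which rule realises the class) and
#'   \code{nnm_true} (pre-masking neonatal near-miss state).
#' @export
truth_table <- function(cohort, config = NULL) {
  tt <- attr(cohort, "truth")
  if (is.null(tt))
    stop("cohort carries no generative truth (not from generate_cohort?)")
  if (!is.null(config) && !identical(unclass(config),
                                     unclass(attr(cohort, "sim_config"))))
    stop("config does not match the one the cohort was generated under")
  tt
}
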
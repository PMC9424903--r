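#' Parameters for simulating a patient cohort with survival outcomes
#'
#' The cohort emulates a stage III colorectal cancer biomarker study: each
#' patient carries two latent binary biomarkers — a high/low MMP14-positive
#' CAF fraction and a high/low stromal TIL density (the driver of the
#' stroma-restricted Immunoscore) — plus six dichotomized clinical covariates.
#' Relapse-free survival is exponential under a proportional-hazards model on
#' the two biomarker indicators, with independent exponential censoring.
#'
#' @param n_patients Cohort size (default 86).
#' @param fields_min,fields_max Range of fields of view per patient (2-5).
#' @param hr_ratio_high Hazard ratio for a high MMP14+ CAF/CAF ratio
#'   (default 2.926, the adverse effect size the pipeline is designed to
#'   detect).
#' @param hr_is_high Hazard ratio for a high stroma-restricted Immunoscore
#'   (default 0.277, protective).
#' @param baseline_hazard Events per month in the double-reference group.
#' @param censor_rate Censoring events per month.
#' @param prob_ratio_high,prob_is_high Prevalence of the two high classes.
#' @param caf_mmp14_beta_high,caf_mmp14_beta_low Beta shape pairs for the true
#'   per-patient MMP14+ CAF fraction in the high and low classes.
#' @param til_multiplier_high,til_multiplier_low Multipliers applied to the
#'   stromal TIL density for patients with high / low TIL level.
#' @param covariate_frequencies Named prevalences of the binary clinical
#'   covariates; defaults follow the frequencies of an 86-patient stage III
#'   cohort (age >= 67 years, female sex, left-sided/rectal location, stage
#'   IIIC, unfavorable histology, 5-FU monotherapy).
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 86L,
                              fields_min = 2L, fields_max = 5L,
                              hr_ratio_high = 2.926,
                              hr_is_high = 0.277,
                              baseline_hazard = 0.006,
                              censor_rate = 0.015,
                              prob_ratio_high = 0.5,
                              prob_is_high = 0.5,
                              caf_mmp14_beta_high = c(12, 6),
                              caf_mmp14_beta_low = c(4, 12),
                              til_multiplier_high = 2,
                              til_multiplier_low = 0.6,
                              covariate_frequencies = c(age_ge67 = 0.5,
                                                        female = 0.488,
                                                        left_or_rectum = 0.651,
                                                        stage_iiic = 0.174,
                                                        unfavorable_histology = 0.151,
                                                        fu_monotherapy = 0.523)) {
  if (n_patients < 2) abort("`n_patients` must be at least 2.")
  if (hr_ratio_high <= 0 || hr_is_high <= 0) abort("hazard ratios must be positive.")
  if (baseline_hazard <= 0 || censor_rate < 0) abort("rates must be positive.")
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate a patient cohort (and optionally its mIHC fields)
#'
#' Draws per-patient biomarker ground truth, clinical covariates and
#' relapse-free survival from the proportional-hazards model configured in
#' [cohort_sim_params()], and labels each patient with its true risk group:
#' A (high Immunoscore / high ratio), B (high/low), C (low Immunoscore / high
#' ratio — the adverse combination), D (low/low). With `fields = TRUE` every
#' patient additionally receives its fields of single cells, simulated with
#' the patient's true MMP14+ CAF fraction and TIL density level.
#'
#' @param cohort A [cohort_sim_params()] object.
#' @param tissue A [tissue_sim_params()] object used when `fields = TRUE`.
#' @param seed Integer seed governing the whole cohort.
#' @param fields Simulate per-field cell tables? (slower; default FALSE).
#' @return A list of class `sim_cohort` with `patients` (one row per patient:
#'   ground truth, covariates, `rfs_months`, `event`, `n_fields`) and, when
#'   requested, `cells` (all fields stacked, keyed by `patient_id`,
#'   `field_id`).
#' @examples
#' coh <- simulate_cohort(cohort_sim_params(n_patients = 40), seed = 7)
#' dplyr::count(coh$patients, group_true, event)
#' @export
simulate_cohort <- function(cohort = cohort_sim_params(),
                            tissue = tissue_sim_params(),
                            seed = 1L, fields = FALSE) {
  stopifnot(inherits(cohort, "cohort_sim_params"),
            inherits(tissue, "tissue_sim_params"))
  set.seed(seed)
  n <- cohort$n_patients

  ratio_high <- runif(n) < cohort$prob_ratio_high
  is_high <- runif(n) < cohort$prob_is_high
  frac <- ifelse(ratio_high,
    rbeta(n, cohort$caf_mmp14_beta_high[1], cohort$caf_mmp14_beta_high[2]),
    rbeta(n, cohort$caf_mmp14_beta_low[1], cohort$caf_mmp14_beta_low[2]))

  covs <- imap(as.list(cohort$covariate_frequencies),
               function(p, nm) runif(n) < p) |> as_tibble()

  hazard <- cohort$baseline_hazard *
    cohort$hr_ratio_high^ratio_high * cohort$hr_is_high^is_high
  t_event <- rexp(n, hazard)
  t_cens <- if (cohort$censor_rate > 0) rexp(n, cohort$censor_rate) else rep(Inf, n)

  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    true_ratio_high = ratio_high,
    true_is_high = is_high,
    true_caf_mmp14_fraction = frac,
    group_true = risk_groups(ifelse(is_high, "high", "low"),
                             ifelse(ratio_high, "high", "low")),
    n_fields = sample(seq(cohort$fields_min, cohort$fields_max), n, replace = TRUE),
    rfs_months = pmin(t_event, t_cens),
    event = t_event <= t_cens) |>
    bind_cols(covs)

  out <- list(patients = patients)
  if (fields) {
    field_seeds <- sample.int(.Machine$integer.max, sum(patients$n_fields))
    k <- 0L
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      p_tissue <- tissue
      p_tissue$mmp14_prevalence["caf"] <- frac[i]
      p_tissue$stroma_densities["til"] <- tissue$stroma_densities["til"] *
        if (is_high[i]) cohort$til_multiplier_high else cohort$til_multiplier_low
      flds <- vector("list", patients$n_fields[i])
      for (j in seq_len(patients$n_fields[i])) {
        k <- k + 1L
        f <- simulate_field(p_tissue, seed = field_seeds[k])
        f$cells$patient_id <- patients$patient_id[i]
        f$cells$field_id <- j
        flds[[j]] <- f$cells
      }
      cells[[i]] <- bind_rows(flds)
    }
    out$cells <- bind_rows(cells) |>
      select("patient_id", "field_id", dplyr::everything())
  }
  structure(out, class = "sim_cohort")
}
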
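#' Profile a multi-patient mIHC cohort end to end
#'
#' Runs the full single-cell pipeline on a stacked cell table: gate lineages,
#' segment every field into IF / TN / ISA, label cells with their region,
#' compute field-averaged patient densities, both Immunoscore variants, the
#' MMP14+ CAF/CAF ratio (intratumoral regions only), the median-split classes
#' and the A-D risk groups.
#'
#' @param cells Tibble of cells across patients and fields: `patient_id`,
#'   `field_id`, `x_um`, `y_um` and one intensity column per marker.
#' @param config A [gating_config()].
#' @param field_size_um,grid_resolution_um,dilation_radius_um,closing_radius_um,band_width_um
#'   Segmentation parameters, see [segment_field()].
#' @param ratio_regions Regions whose CAFs enter the ratio denominator;
#'   default `c("TN", "ISA")` — the invasive front is excluded because
#'   peritumoral aSMA also marks smooth muscle.
#' @return List of class `cohort_profile`: `patients` (per patient: ratio,
#'   ratio class, both Immunoscore totals/classes, risk group), `densities`
#'   (patient-level [density_table()]), `cells` (gated, region-labelled) and
#'   `areas` (per-field region areas).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_sim_params(n_patients = 6), seed = 1, fields = TRUE)
#' thr <- derive_threshold_fmo(simulate_fmo_null(seed = 2))
#' prof <- profile_cohort(coh$cells, default_gating_config(thr))
#' prof$patients
#' }
#' @export
profile_cohort <- function(cells, config,
                           field_size_um = 1884, grid_resolution_um = 4,
                           dilation_radius_um = 10, closing_radius_um = 20,
                           band_width_um = 300,
                           ratio_regions = c("TN", "ISA")) {
  gated <- gate_lineages(cells, config)
  keys <- distinct(gated, .data$patient_id, .data$field_id)

  labelled <- vector("list", nrow(keys))
  area_rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- gated |>
      filter(.data$patient_id == keys$patient_id[i],
             .data$field_id == keys$field_id[i])
    seg <- segment_field(sub, field_size_um, grid_resolution_um,
                         dilation_radius_um, closing_radius_um, band_width_um,
                         tumor_col = "lineage")
    labelled[[i]] <- assign_regions(sub, seg)
    area_rows[[i]] <- seg$areas |>
      mutate(patient_id = keys$patient_id[i], field_id = keys$field_id[i])
  }
  gated <- bind_rows(labelled)
  areas <- bind_rows(area_rows) |>
    select("patient_id", "field_id", "region", "area_mm2")

  dens <- density_table(gated, areas)
  is_mod <- immunoscore(dens, "is")
  is_conv <- immunoscore(dens, "conventional")
  ratio <- positive_fraction(gated, "caf", "mmp14", regions = ratio_regions)

  patients <- ratio |>
    rename(mmp14_caf_ratio = "ratio") |>
    mutate(ratio_klass = dichotomize_by_median(.data$mmp14_caf_ratio)) |>
    left_join(is_mod |> select("patient_id", is_total = "total", is_klass = "klass"),
              by = "patient_id") |>
    left_join(is_conv |> select("patient_id", conv_total = "total",
                                conv_klass = "klass"),
              by = "patient_id") |>
    mutate(group = risk_groups(.data$is_klass, .data$ratio_klass))

  structure(list(patients = patients, densities = dens,
                 cells = gated, areas = areas,
                 immunoscore_is = is_mod, immunoscore_conventional = is_conv),
            class = "cohort_profile")
}

#' Export simulated cohort tables as CSV
#'
#' Writes `cells.csv` (per-cell coordinates, intensities and ground truth)
#' and `clinical.csv` (per-patient covariates, biomarker truth and survival)
#' into a directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$patients, file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(cohort$cells)) {
    write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  }
  invisible(dir)
}
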
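standard_populations <- function(cells) {
  # population membership from gated lineage + sub-flags
  list(
    tumor   = cells$lineage == "tumor",
    caf     = cells$lineage == "caf",
    tam     = cells$lineage == "tam",
    tam_m1  = cells$lineage == "tam" & !is.na(cells$tam_subtype) & cells$tam_subtype == "m1",
    tam_m2  = cells$lineage == "tam" & !is.na(cells$tam_subtype) & cells$tam_subtype == "m2",
    cd3     = cells$lineage == "til",
    cd8     = cells$lineage == "til" & isTRUE_vec(cells$cd8_pos),
    mdsc    = cells$lineage == "mdsc")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Cell density of one lineage in one region
#'
#' @param cells Tibble of cells with `lineage` and `region` columns.
#' @param lineage Lineage label to count.
#' @param region Region label (`"IF"`, `"TN"`, `"ISA"`, or `"CT"` for the
#'   combined TN+ISA centre).
#' @param region_area_mm2 Area of the region in mm^2; `NA` (missing region)
#'   propagates to a missing density.
#' @return Density in cells/mm^2 (scalar).
#' @examples
#' df <- tibble::tibble(lineage = rep("til", 10), region = "TN")
#' compute_density(df, "til", "TN", 1)
#' @export
compute_density <- function(cells, lineage, region, region_area_mm2) {
  if (is.na(region_area_mm2)) return(NA_real_)
  if (region_area_mm2 <= 0) abort("`region_area_mm2` must be positive.")
  in_region <- if (region == "CT") cells$region %in% c("TN", "ISA")
    else cells$region == region
  sum(cells$lineage == lineage & in_region) / region_area_mm2
}

#' Per-field densities of the standard cell populations
#'
#' Counts each population (tumor, CAF, TAM and M1/M2 subtypes, CD3+ TILs,
#' CD8+ TILs, MDSCs) in each region of each field and divides by the region
#' area. Regions with zero area are missing for that field, not zero. The
#' combined centre-of-tumor (CT = TN + ISA) is included as its own region.
#'
#' @param cells Gated, region-labelled cells with `patient_id`, `field_id`,
#'   `lineage`, `region` (plus `tam_subtype`, `cd8_pos` when available).
#' @param areas Tibble `patient_id`, `field_id`, `region`, `area_mm2` (as
#'   assembled from [segment_field()]'s `areas` per field).
#' @return Long tibble: `patient_id`, `field_id`, `region`, `population`,
#'   `density` (cells/mm^2).
#' @export
field_densities <- function(cells, areas) {
  pops <- standard_populations(cells)
  counts <- imap(pops, function(sel, nm) {
    sub <- cells[sel, c("patient_id", "field_id", "region")]
    ct <- sub |> filter(.data$region %in% c("TN", "ISA")) |> mutate(region = "CT")
    bind_rows(sub, ct) |>
      count(.data$patient_id, .data$field_id, .data$region, name = "n") |>
      mutate(population = nm)
  }) |> list_rbind()

  areas |>
    tidyr::crossing(population = names(pops)) |>
    left_join(counts, by = c("patient_id", "field_id", "region", "population")) |>
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)),
           density = if_else(.data$area_mm2 > 0, .data$n / .data$area_mm2, NA_real_)) |>
    select("patient_id", "field_id", "region", "population", "density")
}

#' Patient-level density table (field-averaged)
#'
#' The patient value for every population/region is the arithmetic mean of
#' that patient's per-field densities, ignoring fields where the region is
#' missing; if the region is missing in every field the patient value is
#' missing.
#'
#' @param fields Output of [field_densities()] (or `cells` + `areas` to
#'   compute it first).
#' @param areas Optional; when supplied, `fields` is taken to be raw cells.
#' @return Tibble `patient_id`, `region`, `population`, `density`, with the
#'   per-field table attached as attribute `"fields"`.
#' @export
density_table <- function(fields, areas = NULL) {
  if (!is.null(areas)) fields <- field_densities(fields, areas)
  pat <- fields |>
    group_by(.data$patient_id, .data$region, .data$population) |>
    summarise(density = mean(.data$density, na.rm = TRUE), .groups = "drop") |>
    mutate(density = if_else(is.nan(.data$density), NA_real_, .data$density))
  attr(pat, "fields") <- fields
  pat
}

#' Median-split dichotomization
#'
#' Values at or below the cohort median are `"low"`, values strictly above
#' are `"high"`; the convention matches the Immunoscore component scoring
#' (ties at the median score 0).
#'
#' @param values Numeric vector (one value per patient); `NA` allowed.
#' @return Character vector of `"high"` / `"low"` (`NA` preserved).
#' @examples
#' dichotomize_by_median(c(1, 2, 3, 4))
#' @export
dichotomize_by_median <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("need at least two non-missing values to median-split.")
  med <- median(values[ok])
  out <- if_else(values > med, "high", "low")
  out
}

#' Immunoscore (conventional or stroma-restricted variant)
#'
#' Four binary components — CD3+ and CD8+ T-cell density in two regions —
#' are scored 1 when the patient's density is strictly above the cohort
#' median for that component and 0 when at or below it. The conventional
#' variant uses the centre of tumor (CT) and the invasive front (IF); the
#' `"is"` variant replaces CT with the intratumoral stromal area (ISA),
#' restricting the score to peritumoral and intratumoral stroma. The total
#' (0-4) classifies patients as `"high"` (>= 2) or `"low"` (< 2). Missing
#' region densities leave the component missing; the total is the sum of the
#' available components against the unchanged >= 2 cut.
#'
#' @param densities Patient-level [density_table()].
#' @param variant `"is"` (default) or `"conventional"`.
#' @param medians Optional named numeric of component medians (names
#'   `cd3_center`, `cd8_center`, `cd3_front`, `cd8_front`); computed from the
#'   cohort when omitted.
#' @return Tibble: `patient_id`, the four component scores, `n_missing`,
#'   `total`, `klass`, `variant`.
#' @export
immunoscore <- function(densities, variant = c("is", "conventional"),
                        medians = NULL) {
  variant <- match.arg(variant)
  center_region <- if (variant == "is") "ISA" else "CT"
  comp_def <- tibble(
    component = c("cd3_center", "cd8_center", "cd3_front", "cd8_front"),
    population = c("cd3", "cd8", "cd3", "cd8"),
    region = c(center_region, center_region, "IF", "IF"))

  comp <- comp_def |>
    left_join(densities, by = c("population", "region"),
              relationship = "many-to-many") |>
    select("patient_id", "component", "density")
  if (any(is.na(comp$patient_id))) abort("density table lacks the required regions.")

  comp <- comp |>
    group_by(.data$component) |>
    mutate(median_density = if (is.null(medians)) median(.data$density, na.rm = TRUE)
           else medians[[.data$component[1]]]) |>
    ungroup() |>
    mutate(score = dplyr::case_when(
      is.na(.data$density) ~ NA_integer_,
      .data$density > .data$median_density ~ 1L,
      TRUE ~ 0L))

  comp |>
    select("patient_id", "component", "score") |>
    pivot_wider(names_from = "component", values_from = "score") |>
    mutate(n_missing = rowSums(is.na(dplyr::pick(dplyr::starts_with("cd")))),
           total = rowSums(dplyr::pick(dplyr::starts_with("cd")), na.rm = TRUE),
           klass = if_else(.data$total >= 2, "high", "low"),
           variant = variant)
}

#' Marker-positive fraction of a lineage within selected regions
#'
#' Computes, per patient, the fraction of lineage cells (restricted to the
#' given regions) that are positive for a marker — e.g. the MMP14+ CAF/CAF
#' ratio over the intratumoral regions TN and ISA, the invasive front being
#' excluded from CAF analyses because peritumoral aSMA also stains smooth
#' muscle. By default the patient value is the mean of per-field fractions
#' (fields with no lineage cell in the regions are missing and ignored);
#' `pooled = TRUE` instead pools counts across fields.
#'
#' @param cells Gated, region-labelled cells with `patient_id`, `field_id`,
#'   `lineage`, `region` and a `<marker>_pos` flag column.
#' @param lineage Lineage forming the denominator.
#' @param marker Marker name (its `_pos` flag must exist).
#' @param regions Regions restricting the denominator; default `c("TN","ISA")`.
#' @param pooled Pool counts across fields instead of averaging per-field
#'   fractions.
#' @return Tibble `patient_id`, `n_pos`, `n_total`, `ratio` (fraction in
#'   [0, 1]; missing when the patient has no lineage cell in the regions).
#' @export
positive_fraction <- function(cells, lineage, marker,
                              regions = c("TN", "ISA"), pooled = FALSE) {
  flag <- paste0(marker, "_pos")
  if (!flag %in% names(cells)) {
    abort(paste0("no positivity flag `", flag, "`; run mark_positive() or gate_lineages()."))
  }
  sub <- cells |>
    filter(.data$lineage == !!lineage, .data$region %in% regions)
  per_field <- sub |>
    group_by(.data$patient_id, .data$field_id) |>
    summarise(n_pos = sum(.data[[flag]]), n_total = n(), .groups = "drop") |>
    mutate(ratio = .data$n_pos / .data$n_total)

  out <- if (pooled) {
    per_field |>
      group_by(.data$patient_id) |>
      summarise(n_pos = sum(.data$n_pos), n_total = sum(.data$n_total),
                ratio = sum(.data$n_pos) / sum(.data$n_total), .groups = "drop")
  } else {
    per_field |>
      group_by(.data$patient_id) |>
      summarise(n_pos = sum(.data$n_pos), n_total = sum(.data$n_total),
                ratio = mean(.data$ratio), .groups = "drop")
  }
  absent <- setdiff(unique(cells$patient_id), out$patient_id)
  if (length(absent) > 0) {
    warn(sprintf("%d patient(s) have no %s cell in regions %s; ratio is missing.",
                 length(absent), lineage, paste(regions, collapse = "/")))
    out <- bind_rows(out, tibble(patient_id = absent, n_pos = NA_integer_,
                                 n_total = 0L, ratio = NA_real_))
  }
  arrange(out, .data$patient_id)
}

#' Four-group risk stratification
#'
#' Combines the Immunoscore class with the MMP14+ CAF/CAF ratio class:
#' group A = high score / high ratio, B = high/low, C = low/high (the
#' adverse combination), D = low/low.
#'
#' @param is_klass,ratio_klass Character vectors of `"high"` / `"low"`.
#' @return Character vector of `"A"`-`"D"` (`NA` when either class is
#'   missing).
#' @examples
#' risk_groups(c("high", "low"), c("high", "high"))
#' @export
risk_groups <- function(is_klass, ratio_klass) {
  dplyr::case_when(
    is_klass == "high" & ratio_klass == "high" ~ "A",
    is_klass == "high" & ratio_klass == "low" ~ "B",
    is_klass == "low" & ratio_klass == "high" ~ "C",
    is_klass == "low" & ratio_klass == "low" ~ "D",
    TRUE ~ NA_character_)
}

#' Percentages from printed cohort characteristic counts
#'
#' Recomputes the percentage column of a clinicopathologic characteristics
#' table from its raw counts (each characteristic's levels summing to the
#' cohort size).
#'
#' @param counts Tibble with columns `characteristic`, `level`, `n`.
#' @return `counts` with an added `pct` column (0-100 scale).
#' @export
characteristic_percentages <- function(counts) {
  counts |>
    group_by(.data$characteristic) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Printed characteristics of the reference 86-patient stage III cohort
#'
#' Counts transcribed from the published clinicopathologic table of the
#' 86-patient stage III colorectal cancer cohort the pipeline was designed
#' around; used for worked-example arithmetic and as the source of the
#' simulator's default covariate frequencies.
#'
#' @return Tibble `characteristic`, `level`, `n`.
#' @export
stage3_cohort_counts <- function() {
  path <- system.file("extdata", "stage3_cohort_counts.csv",
                      package = "stromascore", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
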
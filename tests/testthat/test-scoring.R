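test_that("densities are counts over area with missing regions propagated", {
  cells <- tibble::tibble(lineage = c(rep("til", 10), rep("caf", 3)),
                          region = c(rep("TN", 10), rep("ISA", 3)))
  expect_equal(compute_density(cells, "til", "TN", 1), 10)
  expect_equal(compute_density(cells, "caf", "TN", 1), 0)
  expect_equal(compute_density(cells, "til", "CT", 2), 5)  # TN+ISA pooled
  # 100 cells over a full 1884x1884 um field: 100 / 3.549456 mm^2
  full <- tibble::tibble(lineage = rep("til", 100), region = "IF")
  expect_equal(compute_density(full, "til", "IF", 1.884^2), 28.17334,
               tolerance = 1e-6)
  expect_true(is.na(compute_density(cells, "til", "TN", NA)))
  expect_error(compute_density(cells, "til", "TN", 0), "positive")
})

test_that("patient densities are field averages, invariant to field order", {
  cells <- tibble::tibble(
    patient_id = "P1",
    field_id = c(1L, 1L, 2L),
    lineage = "til", cd8_pos = FALSE, tam_subtype = NA_character_,
    region = "TN")
  areas <- tibble::tibble(patient_id = "P1", field_id = c(1L, 2L),
                          region = "TN", area_mm2 = c(1, 0.5))
  d <- density_table(cells, areas)
  # field 1: 2 cells/mm2; field 2: 1/0.5 = 2 -> mean 2
  expect_equal(d$density[d$population == "cd3" & d$region == "TN"], 2)

  perm <- density_table(cells[c(3, 1, 2), ], areas[c(2, 1), ])
  expect_equal(dplyr::arrange(perm, region, population),
               dplyr::arrange(d, region, population))

  # a region with zero area in one field is missing there, not zero
  areas2 <- tibble::tibble(patient_id = "P1", field_id = c(1L, 2L),
                           region = "ISA", area_mm2 = c(0, 0.5))
  cells2 <- dplyr::mutate(cells, region = "ISA")
  d2 <- density_table(cells2, areas2)
  expect_equal(d2$density[d2$population == "cd3" & d2$region == "ISA"], 2)
  # missing in all fields -> missing patient value
  areas3 <- dplyr::mutate(areas2, area_mm2 = 0)
  d3 <- density_table(cells2, areas3)
  expect_true(is.na(d3$density[d3$population == "cd3" & d3$region == "ISA"]))
})

# density table with the four Immunoscore components set to median +/- delta
pattern_densities <- function(pattern, medians = c(10, 10, 10, 10)) {
  # pattern: logical length 4 (cd3_center, cd8_center, cd3_front, cd8_front)
  tibble::tibble(
    patient_id = "P1",
    region = c("ISA", "ISA", "IF", "IF"),
    population = c("cd3", "cd8", "cd3", "cd8"),
    density = medians + ifelse(pattern, 1, 0))
}

test_that("all 16 component patterns score by the >=2 rule with ties scoring 0", {
  med <- c(cd3_center = 10, cd8_center = 10, cd3_front = 10, cd8_front = 10)
  for (k in 0:15) {
    pattern <- as.logical(bitwAnd(k, c(1L, 2L, 4L, 8L)))
    sc <- immunoscore(pattern_densities(pattern), "is", medians = med)
    expect_equal(sc$total, sum(pattern))
    expect_equal(sc$klass, if (sum(pattern) >= 2) "high" else "low")
  }
  # density exactly at the median scores 0 (the all-tie pattern is total 0, low)
  tie <- immunoscore(pattern_densities(rep(FALSE, 4)), "is", medians = med)
  expect_equal(tie$total, 0L)
  expect_equal(tie$klass, "low")
})

test_that("immunoscore medians are cohort medians and variants pick their regions", {
  dens <- tidyr::crossing(patient_id = sprintf("P%d", 1:4),
                          region = c("TN", "ISA", "IF", "CT"),
                          population = c("cd3", "cd8")) |>
    dplyr::mutate(density = dplyr::case_when(
      patient_id %in% c("P1", "P2") ~ 5,
      TRUE ~ 20))
  # median 12.5: P1/P2 below on all four components, P3/P4 above
  sc <- immunoscore(dens, "is")
  expect_equal(sc$total[sc$patient_id %in% c("P1", "P2")], c(0L, 0L))
  expect_equal(sc$total[sc$patient_id %in% c("P3", "P4")], c(4L, 4L))
  expect_equal(sort(unique(sc$klass)), c("high", "low"))

  # conventional variant reads CT, not ISA: make them disagree for P1
  dens2 <- dens |>
    dplyr::mutate(density = ifelse(patient_id == "P1" & region == "CT",
                                   50, density))
  conv <- immunoscore(dens2, "conventional")
  isv <- immunoscore(dens2, "is")
  expect_gt(conv$total[conv$patient_id == "P1"], isv$total[isv$patient_id == "P1"])

  # a missing component leaves the total over the remaining components
  dens3 <- dens |>
    dplyr::mutate(density = ifelse(patient_id == "P3" & region == "ISA",
                                   NA_real_, density))
  sc3 <- immunoscore(dens3, "is")
  expect_equal(sc3$n_missing[sc3$patient_id == "P3"], 2)
  expect_equal(sc3$total[sc3$patient_id == "P3"], 2L)
  expect_equal(sc3$klass[sc3$patient_id == "P3"], "high")
})

test_that("increasing a density never decreases the Immunoscore total", {
  med <- c(cd3_center = 10, cd8_center = 10, cd3_front = 10, cd8_front = 10)
  base <- pattern_densities(c(FALSE, TRUE, FALSE, TRUE))
  t0 <- immunoscore(base, "is", medians = med)$total
  bumped <- base |> dplyr::mutate(density = density + 5)
  expect_gte(immunoscore(bumped, "is", medians = med)$total, t0)
})

test_that("median dichotomization uses the <=median->low convention", {
  expect_equal(dichotomize_by_median(c(1, 2, 3, 4)),
               c("low", "low", "high", "high"))
  expect_equal(dichotomize_by_median(rep(2, 5)), rep("low", 5))
  expect_equal(dichotomize_by_median(c(0.1, 0.2, 0.2, 0.9)),
               c("low", "low", "low", "high"))
  # even count of distinct values: exactly half high
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(sum(dichotomize_by_median(x) == "high"), 4)
  expect_error(dichotomize_by_median(c(NA_real_, NA_real_)), "non-missing")
})

test_that("risk groups combine the two classes per the A-D definitions", {
  expect_equal(risk_groups("high", "high"), "A")
  expect_equal(risk_groups("high", "low"), "B")
  expect_equal(risk_groups("low", "high"), "C")
  expect_equal(risk_groups("low", "low"), "D")
  expect_true(is.na(risk_groups(NA, "high")))
})

ratio_cells <- function(n_pos, n_tot, patient = "P1", field = 1L,
                        region = "ISA", lineage = "caf") {
  tibble::tibble(patient_id = patient, field_id = field,
                 lineage = lineage, region = region,
                 mmp14_pos = c(rep(TRUE, n_pos), rep(FALSE, n_tot - n_pos)))
}

test_that("positive fractions are counts over lineage cells in region", {
  expect_equal(positive_fraction(ratio_cells(0, 40), "caf", "mmp14")$ratio, 0)
  expect_equal(positive_fraction(ratio_cells(5, 20), "caf", "mmp14")$ratio, 0.25)
  # fraction unchanged when unrelated cells are added
  mixed <- dplyr::bind_rows(ratio_cells(5, 20),
                            ratio_cells(7, 9, lineage = "til"),
                            ratio_cells(3, 11, region = "IF"))
  expect_equal(positive_fraction(mixed, "caf", "mmp14")$ratio, 0.25)
  # empty denominator is missing, with a warning
  expect_warning(
    r <- positive_fraction(ratio_cells(2, 5, lineage = "til"), "caf", "mmp14"),
    "missing")
  expect_true(is.na(r$ratio))
})

test_that("patient ratios average per-field fractions; pooled mode pools counts", {
  cells <- dplyr::bind_rows(ratio_cells(1, 10, field = 1L),
                            ratio_cells(30, 60, field = 2L))
  avg <- positive_fraction(cells, "caf", "mmp14")
  expect_equal(avg$ratio, (0.1 + 0.5) / 2)
  pooled <- positive_fraction(cells, "caf", "mmp14", pooled = TRUE)
  expect_equal(pooled$ratio, 31 / 70)
  # permuting fields leaves the patient value unchanged
  perm <- positive_fraction(cells[sample(nrow(cells)), ], "caf", "mmp14")
  expect_equal(perm$ratio, avg$ratio)
})

test_that("printed cohort counts reproduce their published percentages", {
  counts <- stage3_cohort_counts()
  expect_true(all(tapply(counts$n, counts$characteristic, sum) == 86))
  pct <- characteristic_percentages(counts)
  expect_equal(pct$pct[pct$level == "male"], 100 * 44 / 86)
  expect_equal(round(pct$pct[pct$level == "yes"]), 29)
})
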
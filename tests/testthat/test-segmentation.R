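cells_at <- function(x, y, lineage = "tumor") {
  tibble::tibble(x_um = x, y_um = y, lineage = lineage)
}

test_that("rasterization handles empty, single-cell and saturated fields", {
  empty <- cells_at(numeric(), numeric())
  m <- rasterize_tumor_mask(empty, field_size_um = 200, grid_resolution_um = 4)
  expect_false(any(m))

  # single cell, fine grid: dilated area close to the analytic disc
  one <- cells_at(500, 500)
  m1 <- rasterize_tumor_mask(one, field_size_um = 1000, grid_resolution_um = 1,
                             dilation_radius_um = 50)
  expect_lt(abs(raster_area_um2(m1) - pi * 50^2) / (pi * 50^2), 0.02)

  # dense grid of tumor cells saturates the field
  g <- seq(2, 198, by = 4)
  dense <- cells_at(rep(g, each = length(g)), rep(g, length(g)))
  m2 <- rasterize_tumor_mask(dense, field_size_um = 200, grid_resolution_um = 4,
                             dilation_radius_um = 10)
  expect_true(all(m2))
})

test_that("invalid raster parameters error", {
  expect_error(rasterize_tumor_mask(cells_at(1, 1), grid_resolution_um = 0),
               "positive")
  expect_error(extract_invasive_front(square_raster(100, 4, 40), band_width_um = 0),
               "positive")
  expect_error(extract_invasive_front(matrix(TRUE, 2, 2)), "resolution")
})

test_that("invasive front band matches analytic areas on square and disc tumors", {
  # 600x600 um square, 300 um band, 4 um grid, fully interior to a 3000 um
  # field: Euclidean band area = 4*s*w + pi*w^2 (rounded corners)
  sq <- square_raster(3000, 4, 600)
  band <- extract_invasive_front(sq, 300)
  analytic_sq <- 4 * 600 * 300 + pi * 300^2
  expect_lt(abs(raster_area_um2(band) - analytic_sq) / analytic_sq, 0.02)

  # disc radius 200 um, band 300 um: annulus pi*(500^2 - 200^2)
  dc <- disc_raster(3000, 4, 200)
  band2 <- extract_invasive_front(dc, 300)
  analytic_dc <- pi * (500^2 - 200^2)
  expect_lt(abs(raster_area_um2(band2) - analytic_dc) / analytic_dc, 0.02)

  # empty mask -> empty band
  expect_false(any(extract_invasive_front(
    make_raster(matrix(FALSE, 10, 10), 4, 40), 300)))
})

test_that("widening the band never shrinks the invasive front", {
  dc <- disc_raster(2000, 4, 150)
  b200 <- extract_invasive_front(dc, 200)
  b300 <- extract_invasive_front(dc, 300)
  expect_true(all(b300[b200]))
  expect_gt(sum(b300), sum(b200))
})

test_that("morphological closing bridges narrow gaps and leaves wide ones open", {
  # two 150 um-radius nests separated by a 10 um gap: closing radius 20 um
  # bridges the gap into a single connected nest
  npx <- 500; res <- 2
  ctr <- (seq_len(npx) - 0.5) * res
  two_nests <- function(gap) {
    c1 <- 500 - gap / 2 - 150; c2 <- 500 + gap / 2 + 150
    d1 <- outer((ctr - 500)^2, (ctr - c1)^2, `+`) <= 150^2
    d2 <- outer((ctr - 500)^2, (ctr - c2)^2, `+`) <= 150^2
    make_raster(d1 | d2, res, npx * res)
  }
  parts_narrow <- partition_center(two_nests(10), closing_radius_um = 20)
  expect_equal(max(EBImage::bwlabel(parts_narrow$tn + 0)), 1)

  parts_wide <- partition_center(two_nests(100), closing_radius_um = 20)
  expect_equal(max(EBImage::bwlabel(parts_wide$tn + 0)), 2)
  # the wide gap is not absorbed into the nest mask
  gap_px <- abs(ctr - 500) < 40
  expect_false(any(parts_wide$tn[outer(gap_px, gap_px, `&`)]))
})

test_that("stroma enclosed by tumor becomes ISA; all-tumor centre has none", {
  # annular tumor: enclosed core is ISA after hole filling
  npx <- 400; res <- 4
  ctr <- (seq_len(npx) - 0.5) * res
  d2 <- outer((ctr - 800)^2, (ctr - 800)^2, `+`)
  ring <- make_raster(d2 <= 500^2 & d2 >= 300^2, res, npx * res)
  parts <- partition_center(ring, closing_radius_um = 20)
  expect_gt(sum(parts$isa), 0)
  core <- d2 <= 250^2
  expect_true(all(parts$isa[core]))

  solid <- make_raster(d2 <= 500^2, res, npx * res)
  parts2 <- partition_center(solid, closing_radius_um = 20)
  expect_equal(sum(parts2$isa), 0)
})

test_that("TN and ISA partition the centre exactly", {
  for (s in 1:5) {
    fld <- simulate_field(small_tissue_params(), seed = s)
    seg <- segment_field(fld$cells, field_size_um = 900, tumor_col = "true_lineage")
    expect_true(all((seg$tn_mask | seg$isa_mask) == seg$ct_mask))
    expect_false(any(seg$tn_mask & seg$isa_mask))
    expect_false(any(seg$if_mask & seg$ct_mask))
    # areas add up to machine precision of the raster
    a <- seg$areas
    expect_equal(a$area_mm2[a$region == "TN"] + a$area_mm2[a$region == "ISA"],
                 a$area_mm2[a$region == "CT"])
  }
})

test_that("region areas converge as the grid is refined on fixture geometry", {
  for (res in list(c(4, 2), c(2, 1))) {
    band_a <- raster_area_mm2(extract_invasive_front(disc_raster(2400, res[1], 250), 300))
    band_b <- raster_area_mm2(extract_invasive_front(disc_raster(2400, res[2], 250), 300))
    expect_lt(abs(band_a - band_b) / band_b, 0.02)
  }
  ring <- function(res) {
    npx <- as.integer(2000 / res)
    ctr <- (seq_len(npx) - 0.5) * res
    d2 <- outer((ctr - 1000)^2, (ctr - 1000)^2, `+`)
    make_raster(d2 <= 450^2 & d2 >= 250^2, res, 2000)
  }
  p4 <- partition_center(ring(4), 20)
  p2 <- partition_center(ring(2), 20)
  expect_lt(abs(raster_area_mm2(p4$isa) - raster_area_mm2(p2$isa)) /
            raster_area_mm2(p2$isa), 0.02)
  expect_lt(abs(raster_area_mm2(p4$tn) - raster_area_mm2(p2$tn)) /
            raster_area_mm2(p2$tn), 0.02)
})

test_that("cells are assigned exactly one region, idempotently", {
  fld <- simulate_field(small_tissue_params(), seed = 3)
  seg <- segment_field(fld$cells, field_size_um = 900, tumor_col = "true_lineage")
  lab1 <- assign_regions(fld$cells, seg)
  expect_equal(nrow(lab1), nrow(fld$cells))
  expect_true(all(lab1$region %in% c("IF", "TN", "ISA", "OUTSIDE")))
  lab2 <- assign_regions(lab1, seg)
  expect_identical(lab1$region, lab2$region)

  # label agrees with a direct pixel lookup under the half-open convention
  res <- seg$grid_resolution_um
  ix <- pmin(floor(lab1$x_um / res) + 1L, ncol(seg$labels))
  iy <- pmin(floor(lab1$y_um / res) + 1L, nrow(seg$labels))
  oracle <- c("OUTSIDE", "IF", "TN", "ISA")[seg$labels[cbind(iy, ix)] + 1L]
  expect_identical(lab1$region, oracle)
})

test_that("a cell on the tumor boundary (distance zero outside the mask) is IF", {
  sq <- square_raster(1000, 4, 400)  # mask covers [300, 700) in each axis
  masks <- structure(list(
    labels = matrix(0L, nrow(sq), ncol(sq)), tumor_mask = sq,
    grid_resolution_um = 4, field_size_um = 1000), class = "region_masks")
  band <- extract_invasive_front(sq, 300)
  masks$labels[band] <- 1L
  masks$labels[sq] <- 2L
  on_boundary <- tibble::tibble(x_um = 700, y_um = 500)  # first pixel outside
  expect_equal(assign_regions(on_boundary, masks)$region, "IF")
})

test_that("out-of-field cells are excluded with a warning", {
  fld <- simulate_field(small_tissue_params(), seed = 3)
  seg <- segment_field(fld$cells, field_size_um = 900, tumor_col = "true_lineage")
  bad <- dplyr::bind_rows(fld$cells[1:5, ],
                          tibble::tibble(x_um = c(-1, 950), y_um = c(10, 10)))
  expect_warning(out <- assign_regions(bad, seg), "excluded")
  expect_equal(nrow(out), 5L)
})

test_that("label masks survive a TIFF round trip", {
  fld <- simulate_field(small_tissue_params(), seed = 2)
  seg <- segment_field(fld$cells, field_size_um = 900, tumor_col = "true_lineage")
  path <- withr::local_tempfile(fileext = ".tiff")
  write_region_masks(seg, path)
  back <- read_region_masks(path)
  expect_identical(back$labels, seg$labels)
  expect_equal(back$grid_resolution_um, seg$grid_resolution_um)
  expect_equal(back$areas, seg$areas)
})
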
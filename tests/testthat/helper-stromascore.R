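# Shared fixtures built in code.

# Small, fast tissue field: quarter-size field, fewer cells.
small_tissue_params <- function(...) {
  tissue_sim_params(field_size_um = 900, n_nests = 9,
                    nest_radius_meanlog = log(110), nest_radius_sdlog = 0.12,
                    tumor_cell_density = 1200,
                    stroma_densities = c(caf = 250, tam = 150, til = 300, mdsc = 40),
                    ...)
}

# Gating configuration used for fidelity checks: thresholds from a large FMO
# null at the 0.999 quantile (10-marker panel; see the methods vignette for
# why fidelity checks use the higher quantile).
fidelity_gating <- function(params = tissue_sim_params(), seed = 4242) {
  thr <- derive_threshold_fmo(simulate_fmo_null(params, n = 1e5, seed = seed),
                              positivity_quantile = 0.999)
  default_gating_config(thr, positivity_quantile = 0.999)
}

# Build a logical raster directly (internal convention: rows = y, cols = x).
make_raster <- function(mat, resolution_um, field_size_um) {
  structure(mat, resolution_um = resolution_um, field_size_um = field_size_um)
}

# Raster of a centred axis-aligned square of side `side_um`.
square_raster <- function(field_um, res_um, side_um) {
  npx <- as.integer(ceiling(field_um / res_um))
  ctr <- (seq_len(npx) - 0.5) * res_um
  inx <- abs(ctr - field_um / 2) < side_um / 2
  make_raster(outer(inx, inx, `&`), res_um, field_um)
}

# Raster of a centred disc of radius `r_um` (pixel-centre test).
disc_raster <- function(field_um, res_um, r_um) {
  npx <- as.integer(ceiling(field_um / res_um))
  ctr <- (seq_len(npx) - 0.5) * res_um
  d2 <- outer((ctr - field_um / 2)^2, (ctr - field_um / 2)^2, `+`)
  make_raster(d2 <= r_um^2, res_um, field_um)
}

raster_area_um2 <- function(mask) raster_area_mm2(mask) * 1e6
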
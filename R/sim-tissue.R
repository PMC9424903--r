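#' Parameters for simulating one mIHC tissue field
#'
#' Defines the geometry and intensity model of a synthetic multiplex-IHC
#' field: tumor-cell nests as random-radius discs, stromal lineages placed as
#' homogeneous Poisson processes outside the nests, and per-marker intensities
#' drawn from a log-normal positive model over a common log-normal background
#' (the background doubles as the fluorescence-minus-one null used to derive
#' gating thresholds).
#'
#' @param field_size_um Side length of the square field in micrometres.
#'   Default 1884, the field-of-view size used throughout the pipeline.
#' @param n_nests Number of tumor-cell nests (discs) dropped into the field.
#' @param nest_radius_meanlog,nest_radius_sdlog Log-normal parameters of the
#'   nest radius in micrometres.
#' @param nest_layout `"grid"` (default) packs nest centres on a jittered
#'   square grid, emulating a centre-of-tumor field whose nests abut and
#'   enclose interstitial stromal corridors; `"uniform"` scatters centres
#'   uniformly, emulating sparser tumor areas.
#' @param nest_jitter_um Centre jitter (standard deviation, µm) in the grid
#'   layout.
#' @param tumor_cell_density Tumor cells per mm^2 inside the nest union.
#' @param stroma_densities Named numeric vector of cells per mm^2 outside the
#'   nests for lineages `caf`, `tam`, `til`, `mdsc`.
#' @param tam_m2_fraction Fraction of TAMs that are CD163-positive (M2).
#' @param til_cd8_fraction Fraction of TILs that are CD8-positive.
#' @param mmp14_prevalence Named vector: probability that a cell of each
#'   lineage expresses MMP14. The `caf` entry is the patient-level biomarker
#'   and is overridden per patient by [simulate_cohort()].
#' @param positive_meanlog,positive_sdlog Log-normal parameters of positive
#'   marker intensities (arbitrary units).
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   background (FMO-style null) intensities.
#' @return A list of class `tissue_sim_params`.
#' @export
tissue_sim_params <- function(field_size_um = 1884,
                              n_nests = 25,
                              nest_radius_meanlog = log(185),
                              nest_radius_sdlog = 0.15,
                              nest_layout = c("grid", "uniform"),
                              nest_jitter_um = 25,
                              tumor_cell_density = 2500,
                              stroma_densities = c(caf = 400, tam = 220, til = 500, mdsc = 60),
                              tam_m2_fraction = 0.55,
                              til_cd8_fraction = 0.4,
                              mmp14_prevalence = c(tumor = 0.35, caf = 0.3, tam = 0.15,
                                                   til = 0.05, mdsc = 0.1),
                              positive_meanlog = log(10),
                              positive_sdlog = 0.4,
                              background_meanlog = log(0.5),
                              background_sdlog = 0.6) {
  if (!is.numeric(field_size_um) || field_size_um <= 0) {
    abort("`field_size_um` must be a positive length in micrometres.")
  }
  if (tumor_cell_density < 0 || any(stroma_densities < 0)) {
    abort("densities must be non-negative (cells/mm^2).")
  }
  if (n_nests < 0) abort("`n_nests` must be a non-negative count.")
  nest_layout <- match.arg(nest_layout)
  structure(
    list(field_size_um = field_size_um, n_nests = n_nests,
         nest_radius_meanlog = nest_radius_meanlog,
         nest_radius_sdlog = nest_radius_sdlog,
         nest_layout = nest_layout, nest_jitter_um = nest_jitter_um,
         tumor_cell_density = tumor_cell_density,
         stroma_densities = stroma_densities,
         tam_m2_fraction = tam_m2_fraction,
         til_cd8_fraction = til_cd8_fraction,
         mmp14_prevalence = mmp14_prevalence,
         positive_meanlog = positive_meanlog, positive_sdlog = positive_sdlog,
         background_meanlog = background_meanlog,
         background_sdlog = background_sdlog),
    class = "tissue_sim_params")
}

#' Marker panel used by the simulator and the default gating configuration
#' @return Character vector of marker column names.
#' @export
panel_markers <- function() {
  c("panck", "asma", "cd45", "cd31", "cd68", "cd163", "cd3", "cd8", "cd33", "mmp14")
}

# positive-marker set per ground-truth lineage (before subtype flags)
lineage_positive_markers <- function(lineage, tam_m2, til_cd8) {
  base <- switch(lineage,
    tumor = "panck",
    caf   = "asma",
    tam   = c("cd45", "cd68"),
    til   = c("cd45", "cd3"),
    mdsc  = c("cd45", "cd33"))
  if (lineage == "tam" && isTRUE(tam_m2)) base <- c(base, "cd163")
  if (lineage == "til" && isTRUE(til_cd8)) base <- c(base, "cd8")
  base
}

point_in_nests <- function(x, y, nests) {
  if (nrow(nests) == 0L || length(x) == 0L) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(nests))) {
    inside <- inside |
      ((x - nests$cx_um[i])^2 + (y - nests$cy_um[i])^2 <= nests$r_um[i]^2)
  }
  inside
}

# homogeneous Poisson points on the field, thinned to inside/outside the nest union
poisson_points <- function(density_mm2, field, nests, inside) {
  n <- rpois(1L, density_mm2 * (field / 1000)^2)
  x <- runif(n, 0, field)
  y <- runif(n, 0, field)
  keep <- point_in_nests(x, y, nests)
  if (!inside) keep <- !keep
  tibble(x_um = x[keep], y_um = y[keep])
}

#' Simulate one tissue field of single cells
#'
#' Generates tumor-cell nests (discs with log-normal radii, centres uniform in
#' the field), fills them with tumor cells and the surrounding stroma with
#' CAFs, TAMs, TILs and MDSCs as independent homogeneous Poisson processes,
#' then draws a marker-intensity vector for every cell: log-normal positive
#' intensities for the lineage's markers, background draws for all others.
#' Ground-truth lineage, subtype flags and MMP14 status are attached so that
#' downstream gating and scoring can be validated against them.
#'
#' @param params A [tissue_sim_params()] object.
#' @param seed Integer seed; the same seed and parameters reproduce the field
#'   exactly.
#' @return A list of class `tissue_field` with elements `cells` (tibble:
#'   `cell_id`, `x_um`, `y_um`, `true_lineage`, `true_tam_subtype`,
#'   `true_cd8`, `true_mmp14`, one intensity column per marker) and `nests`
#'   (tibble: `nest_id`, `cx_um`, `cy_um`, `r_um`).
#' @examples
#' fld <- simulate_field(tissue_sim_params(n_nests = 2), seed = 1)
#' dplyr::count(fld$cells, true_lineage)
#' @export
simulate_field <- function(params = tissue_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "tissue_sim_params"))
  set.seed(seed)
  field <- params$field_size_um

  nn <- params$n_nests
  if (identical(params$nest_layout, "grid") && nn > 0) {
    k <- ceiling(sqrt(nn))
    spacing <- field / k
    grid <- expand.grid(gx = seq_len(k), gy = seq_len(k))[seq_len(nn), ]
    cx <- (grid$gx - 0.5) * spacing + rnorm(nn, 0, params$nest_jitter_um)
    cy <- (grid$gy - 0.5) * spacing + rnorm(nn, 0, params$nest_jitter_um)
  } else {
    cx <- runif(nn, 0, field)
    cy <- runif(nn, 0, field)
  }
  nests <- tibble(
    nest_id = seq_len(nn),
    cx_um = cx, cy_um = cy,
    r_um  = rlnorm(nn, params$nest_radius_meanlog, params$nest_radius_sdlog))

  tumor <- poisson_points(params$tumor_cell_density, field, nests, inside = TRUE)
  if (params$n_nests == 0L) tumor <- tumor[0, ]
  tumor$true_lineage <- rep("tumor", nrow(tumor))

  stroma <- imap(params$stroma_densities, function(dens, lin) {
    pts <- poisson_points(dens, field, nests, inside = FALSE)
    pts$true_lineage <- rep(lin, nrow(pts))
    pts
  }) |> list_rbind()

  cells <- bind_rows(tumor, stroma)
  n <- nrow(cells)
  cells$cell_id <- seq_len(n)
  cells$true_tam_subtype <- ifelse(cells$true_lineage == "tam",
    ifelse(runif(n) < params$tam_m2_fraction, "m2", "m1"), NA_character_)
  cells$true_cd8 <- ifelse(cells$true_lineage == "til",
    runif(n) < params$til_cd8_fraction, NA)
  prev <- params$mmp14_prevalence[cells$true_lineage]
  prev[is.na(prev)] <- 0
  cells$true_mmp14 <- runif(n) < prev

  intens <- matrix(rlnorm(n * length(panel_markers()),
                          params$background_meanlog, params$background_sdlog),
                   nrow = n, ncol = length(panel_markers()),
                   dimnames = list(NULL, panel_markers()))
  if (n > 0) {
    pos_sets <- pmap(list(cells$true_lineage,
                          cells$true_tam_subtype == "m2", cells$true_cd8),
                     lineage_positive_markers)
    for (i in seq_len(n)) {
      mk <- pos_sets[[i]]
      if (cells$true_mmp14[i]) mk <- c(mk, "mmp14")
      intens[i, mk] <- rlnorm(length(mk), params$positive_meanlog, params$positive_sdlog)
    }
  }
  cells <- bind_cols(cells, as_tibble(intens))
  cells <- select(cells, "cell_id", "x_um", "y_um", "true_lineage",
                  "true_tam_subtype", "true_cd8", "true_mmp14",
                  all_of(panel_markers()))
  structure(list(cells = cells, nests = nests), class = "tissue_field")
}

#' Sample the background (FMO-style) intensity null
#'
#' Draws from the same background intensity model the field simulator uses for
#' negative markers, emulating a fluorescence-minus-one control sample from
#' which positivity thresholds are derived.
#'
#' @param params A [tissue_sim_params()] object.
#' @param n Number of null intensities.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_fmo_null <- function(params = tissue_sim_params(), n = 10000L, seed = 1L) {
  set.seed(seed)
  rlnorm(n, params$background_meanlog, params$background_sdlog)
}
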
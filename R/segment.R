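#' @title Raster conventions
#' @description Rasters are logical matrices with rows indexing y (down) and
#'   columns indexing x (right), origin at the top-left of the field, pixel
#'   size `grid_resolution_um` micrometres and half-open pixel intervals: the
#'   pixel in row i, column j covers x in [(j-1)r, jr), y in [(i-1)r, ir).
#' @name raster-conventions
#' @keywords internal
NULL

new_raster <- function(mat, resolution_um, field_size_um) {
  structure(mat, resolution_um = resolution_um, field_size_um = field_size_um)
}

raster_dim <- function(field_size_um, resolution_um) {
  as.integer(ceiling(field_size_um / resolution_um))
}

#' Area of a binary raster in mm^2
#' @param mask Logical raster produced by [rasterize_tumor_mask()] and friends.
#' @return Area in mm^2 (pixel count times pixel area).
#' @export
raster_area_mm2 <- function(mask) {
  res <- attr(mask, "resolution_um")
  sum(mask) * (res / 1000)^2
}

tumor_flags <- function(cells, tumor_col = NULL) {
  if (is.null(tumor_col)) {
    tumor_col <- if ("lineage" %in% names(cells)) "lineage"
      else if ("true_lineage" %in% names(cells)) "true_lineage"
      else abort("no `lineage` or `true_lineage` column; supply `tumor_col`.")
  }
  cells[[tumor_col]] == "tumor"
}

# Euclidean distance (in pixels, centre-to-centre) from every pixel to the
# nearest TRUE pixel of `mask`; Inf when the mask is empty.
dist_to_mask_px <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::distmap(1 - mask)
}

#' Rasterize point tumor cells into a tumor-area mask
#'
#' Marks every pixel whose centre lies within `dilation_radius_um` of a tumor
#' cell, turning the point pattern into the contiguous "tumor cell area" that
#' the invasive-front and nest/stroma partitions are derived from.
#'
#' @param cells Tibble with `x_um`, `y_um` and a lineage column (`lineage`, or
#'   ground-truth `true_lineage`); rows with value `"tumor"` seed the mask.
#' @param field_size_um Side of the square field (µm).
#' @param grid_resolution_um Pixel size (µm); default 4, roughly a cell radius.
#' @param dilation_radius_um Radius of the disc grown around every tumor cell
#'   (µm); default 10.
#' @param tumor_col Optional name of the column identifying tumor cells.
#' @return Logical raster with resolution metadata attached.
#' @export
rasterize_tumor_mask <- function(cells, field_size_um = 1884,
                                 grid_resolution_um = 4,
                                 dilation_radius_um = 10,
                                 tumor_col = NULL) {
  if (grid_resolution_um <= 0) abort("`grid_resolution_um` must be positive.")
  if (dilation_radius_um < 0) abort("`dilation_radius_um` must be non-negative.")
  npx <- raster_dim(field_size_um, grid_resolution_um)
  seedmat <- matrix(FALSE, npx, npx)
  tum <- cells[tumor_flags(cells, tumor_col), , drop = FALSE]
  if (nrow(tum) > 0) {
    ix <- pmin(floor(tum$x_um / grid_resolution_um) + 1L, npx)
    iy <- pmin(floor(tum$y_um / grid_resolution_um) + 1L, npx)
    ok <- tum$x_um >= 0 & tum$y_um >= 0 & tum$x_um < field_size_um & tum$y_um < field_size_um
    seedmat[cbind(iy[ok], ix[ok])] <- TRUE
  }
  d <- dist_to_mask_px(seedmat)
  new_raster(d * grid_resolution_um <= dilation_radius_um,
             grid_resolution_um, field_size_um)
}

#' Extract the invasive-front band around a tumor mask
#'
#' The invasive front is the band of tissue external to the tumor area:
#' pixels outside the mask whose Euclidean distance to the mask is smaller
#' than `band_width_um` (half-open, so the boundary itself counts as front).
#' An empty mask yields an empty front.
#'
#' @param tumor_mask Logical raster from [rasterize_tumor_mask()] (or any
#'   raster carrying resolution metadata).
#' @param band_width_um Band width in µm; default 300.
#' @return Logical raster of the band, clipped to the field.
#' @export
extract_invasive_front <- function(tumor_mask, band_width_um = 300) {
  if (band_width_um <= 0) abort("`band_width_um` must be positive.")
  res <- attr(tumor_mask, "resolution_um")
  if (is.null(res) || res <= 0) abort("tumor mask lacks a valid resolution.")
  d <- dist_to_mask_px(tumor_mask)
  new_raster(!tumor_mask & (d * res < band_width_um),
             res, attr(tumor_mask, "field_size_um"))
}

#' Partition the tumor centre into nest (TN) and intratumoral stroma (ISA)
#'
#' Applies a morphological closing (disc structuring element of radius
#' `closing_radius_um`) to the tumor mask: the closed area is the tumor cell
#' nest (TN), the holes it encloses after filling are the intratumoral
#' stromal area (ISA), and their union is the centre of tumor (CT). Closing
#' bridges nests separated by gaps narrower than twice the radius; wider
#' stromal corridors remain ISA.
#'
#' @param tumor_mask Logical raster.
#' @param closing_radius_um Structuring-element radius in µm; default 20.
#' @return List with logical rasters `tn`, `isa`, `ct` (TN and ISA disjoint,
#'   their union exactly CT).
#' @export
partition_center <- function(tumor_mask, closing_radius_um = 20) {
  res <- attr(tumor_mask, "resolution_um")
  if (is.null(res) || res <= 0) abort("tumor mask lacks a valid resolution.")
  fs <- attr(tumor_mask, "field_size_um")
  if (!any(tumor_mask)) {
    empty <- new_raster(tumor_mask & FALSE, res, fs)
    return(list(tn = empty, isa = empty, ct = empty))
  }
  r_px <- max(1L, round(closing_radius_um / res))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  tn <- EBImage::closing(matrix(as.numeric(tumor_mask), nrow(tumor_mask)), brush)
  ct <- EBImage::fillHull(tn)
  tn <- tn > 0.5
  ct <- ct > 0.5
  list(tn = new_raster(tn, res, fs),
       isa = new_raster(ct & !tn, res, fs),
       ct = new_raster(ct, res, fs))
}

#' Segment a field into invasive front, tumor nest and intratumoral stroma
#'
#' Full single-field segmentation: rasterize tumor cells, close the mask into
#' the TN, fill to obtain the CT, take CT's enclosed holes as ISA, and grow
#' the invasive-front band external to the CT so the band and the centre are
#' disjoint by construction. Every pixel receives exactly one label.
#'
#' @inheritParams rasterize_tumor_mask
#' @param closing_radius_um Radius for the TN closing (µm).
#' @param band_width_um Invasive-front band width (µm); default 300.
#' @return Object of class `region_masks`: integer label matrix (0 OUTSIDE,
#'   1 IF, 2 TN, 3 ISA), the component rasters, the grid metadata and a
#'   region-area table (`areas`, mm^2, including the combined CT region).
#' @examples
#' fld <- simulate_field(tissue_sim_params(n_nests = 3), seed = 2)
#' seg <- segment_field(fld$cells)
#' seg$areas
#' @export
segment_field <- function(cells, field_size_um = 1884,
                          grid_resolution_um = 4,
                          dilation_radius_um = 10,
                          closing_radius_um = 20,
                          band_width_um = 300,
                          tumor_col = NULL) {
  mask <- rasterize_tumor_mask(cells, field_size_um, grid_resolution_um,
                               dilation_radius_um, tumor_col)
  parts <- partition_center(mask, closing_radius_um)
  front <- extract_invasive_front(parts$ct, band_width_um)

  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[front] <- 1L
  labels[parts$tn] <- 2L
  labels[parts$isa] <- 3L

  px_mm2 <- (grid_resolution_um / 1000)^2
  areas <- tibble(
    region = c("IF", "TN", "ISA", "CT"),
    area_mm2 = c(sum(labels == 1L), sum(labels == 2L), sum(labels == 3L),
                 sum(labels == 2L | labels == 3L)) * px_mm2)

  structure(list(labels = labels, tumor_mask = mask, if_mask = front,
                 tn_mask = parts$tn, isa_mask = parts$isa, ct_mask = parts$ct,
                 grid_resolution_um = grid_resolution_um,
                 field_size_um = field_size_um,
                 band_width_um = band_width_um, areas = areas),
            class = "region_masks")
}

#' Label each cell with its tissue region
#'
#' Looks up the region label of the pixel containing every cell (half-open
#' pixel intervals, so a cell exactly on a pixel edge belongs to the pixel on
#' its lower-coordinate side). Cells outside the field bounds are dropped
#' with a warning.
#'
#' @param cells Tibble with `x_um`, `y_um`.
#' @param masks A `region_masks` object from [segment_field()].
#' @return `cells` with a `region` column (`"TN"`, `"ISA"`, `"IF"`,
#'   `"OUTSIDE"`); out-of-field rows removed.
#' @export
assign_regions <- function(cells, masks) {
  stopifnot(inherits(masks, "region_masks"))
  res <- masks$grid_resolution_um
  fs <- masks$field_size_um
  inside <- cells$x_um >= 0 & cells$y_um >= 0 & cells$x_um < fs & cells$y_um < fs
  if (any(!inside)) {
    warn(sprintf("%d cell(s) outside the %g um field were excluded.",
                 sum(!inside), fs))
    cells <- cells[inside, , drop = FALSE]
  }
  npx <- nrow(masks$labels)
  ix <- pmin(floor(cells$x_um / res) + 1L, npx)
  iy <- pmin(floor(cells$y_um / res) + 1L, npx)
  lab <- masks$labels[cbind(iy, ix)]
  cells$region <- c("OUTSIDE", "IF", "TN", "ISA")[lab + 1L]
  cells
}

#' Plot a segmented field
#'
#' @param object A `region_masks` object.
#' @param cells Optional cell tibble overlaid as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_masks <- function(object, cells = NULL, ...) {
  res <- object$grid_resolution_um
  df <- expand.grid(iy = seq_len(nrow(object$labels)),
                    ix = seq_len(ncol(object$labels)))
  df$region <- factor(c("OUTSIDE", "IF", "TN", "ISA")[object$labels + 1L],
                      levels = c("OUTSIDE", "IF", "TN", "ISA"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$ix - 0.5) * res,
                                        y = (.data$iy - 0.5) * res,
                                        fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(OUTSIDE = "grey90", IF = "#80b1d3",
                                          TN = "#fb8072", ISA = "#fdb462")) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "region")
  if (!is.null(cells)) {
    p <- p + ggplot2::geom_point(data = cells,
      ggplot2::aes(x = .data$x_um, y = .data$y_um), inherit.aes = FALSE,
      size = 0.2, alpha = 0.4)
  }
  p
}

#' Write / read region label masks as single-channel TIFF
#'
#' Labels are stored as 8-bit grey values 0 (OUTSIDE), 1 (IF), 2 (TN),
#' 3 (ISA); the µm-per-pixel calibration and band width are written to a
#' YAML sidecar (`<path>.yml`) read back by `read_region_masks()`.
#'
#' @param masks A `region_masks` object.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_masks <- function(masks, path) {
  stopifnot(inherits(masks, "region_masks"))
  tiff::writeTIFF(masks$labels / 255, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(um_per_px = masks$grid_resolution_um,
                        field_um = masks$field_size_um,
                        band_um = masks$band_width_um),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_region_masks
#' @export
read_region_masks <- function(path) {
  img <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(img * 255)), nrow(img))
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  res <- meta$um_per_px; fs <- meta$field_um; band <- meta$band_um
  px_mm2 <- (res / 1000)^2
  areas <- tibble(
    region = c("IF", "TN", "ISA", "CT"),
    area_mm2 = c(sum(labels == 1L), sum(labels == 2L), sum(labels == 3L),
                 sum(labels == 2L | labels == 3L)) * px_mm2)
  structure(list(labels = labels,
                 tumor_mask = NULL,
                 if_mask = new_raster(labels == 1L, res, fs),
                 tn_mask = new_raster(labels == 2L, res, fs),
                 isa_mask = new_raster(labels == 3L, res, fs),
                 ct_mask = new_raster(labels == 2L | labels == 3L, res, fs),
                 grid_resolution_um = res, field_size_um = fs,
                 band_width_um = band, areas = areas),
            class = "region_masks")
}
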
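#' Derive a marker-positivity threshold from an FMO null sample
#'
#' Fluorescence-minus-one (FMO) controls provide the null distribution of a
#' marker's intensity in the absence of the specific stain. The threshold is
#' the nearest-rank empirical quantile of that null — the ceiling(q*n)-th
#' order statistic — and a cell is called positive only when its intensity is
#' strictly greater than the threshold, so ties with the null quantile are
#' negative.
#'
#' @param null_intensities Numeric vector of null (FMO) intensities.
#' @param positivity_quantile Quantile in (0, 1); default 0.99.
#' @return The intensity threshold (scalar).
#' @examples
#' derive_threshold_fmo(1:100, 0.99)  # 99th order statistic
#' @export
derive_threshold_fmo <- function(null_intensities, positivity_quantile = 0.99) {
  if (length(null_intensities) == 0 || all(is.na(null_intensities))) {
    abort("FMO null sample is empty.")
  }
  if (positivity_quantile <= 0 || positivity_quantile >= 1) {
    abort("`positivity_quantile` must lie strictly between 0 and 1.")
  }
  x <- sort(null_intensities[!is.na(null_intensities)])
  x[ceiling(positivity_quantile * length(x))]
}

#' Declarative gating configuration
#'
#' A gating configuration couples per-marker intensity thresholds with an
#' ordered list of lineage rules. Rules are evaluated in declared order and
#' the first rule whose required-positive markers are all above threshold and
#' required-negative markers all at-or-below threshold wins; cells matching
#' no rule are `UNCLASSIFIED`.
#'
#' @param thresholds Named numeric vector, one threshold per marker, or a
#'   single unnamed value applied to every marker a rule references.
#' @param rules List of rules, each `list(lineage =, positive =, negative =)`
#'   with `positive` / `negative` character vectors of marker names.
#' @param positivity_quantile The FMO quantile the thresholds were derived at
#'   (metadata; default 0.99).
#' @return Object of class `gating_config`.
#' @export
gating_config <- function(thresholds, rules, positivity_quantile = 0.99) {
  referenced <- unique(unlist(map(rules, function(r) c(r$positive, r$negative))))
  if (is.null(names(thresholds))) {
    if (length(thresholds) != 1L) {
      abort("`thresholds` must be named per marker, or a single value.")
    }
    thresholds <- setNames(rep(thresholds, length(referenced)), referenced)
  }
  missing <- setdiff(referenced, names(thresholds))
  if (length(missing) > 0) {
    abort(paste0("no threshold for marker(s): ", paste(missing, collapse = ", ")))
  }
  structure(list(thresholds = thresholds, rules = rules,
                 positivity_quantile = positivity_quantile),
            class = "gating_config")
}

#' Default lineage gating rules for the 10-marker panel
#'
#' Tumor cells are panCK+; CAFs are aSMA+ panCK- CD45- CD31-; TAMs are
#' CD45+ CD68+ (M2 if additionally CD163+, else M1); TILs are CD45+ CD3+
#' (with CD8 recorded as a sub-flag); MDSCs are CD45+ myeloid-marker+ CD68-
#' (myeloid marker configurable, default CD33). The tumor rule is evaluated
#' first so double positives (e.g. panCK+ aSMA+) resolve to tumor.
#'
#' @param thresholds Named thresholds (or single value) as in
#'   [gating_config()].
#' @param mdsc_marker Name of the myeloid marker column; default `"cd33"`.
#' @inheritParams gating_config
#' @return A `gating_config`.
#' @export
default_gating_config <- function(thresholds, mdsc_marker = "cd33",
                                  positivity_quantile = 0.99) {
  rules <- list(
    list(lineage = "tumor", positive = "panck", negative = character()),
    list(lineage = "caf", positive = "asma",
         negative = c("panck", "cd45", "cd31")),
    list(lineage = "tam", positive = c("cd45", "cd68"), negative = character()),
    list(lineage = "til", positive = c("cd45", "cd3"), negative = character()),
    list(lineage = "mdsc", positive = c("cd45", mdsc_marker), negative = "cd68"))
  if (is.null(names(thresholds)) && length(thresholds) == 1L) {
    # also threshold the sub-flag markers (CD163, CD8) and MMP14
    all_markers <- unique(c(unlist(map(rules, function(r) c(r$positive, r$negative))),
                            "cd163", "cd8", "mmp14"))
    thresholds <- setNames(rep(thresholds, length(all_markers)), all_markers)
  }
  gating_config(thresholds, rules, positivity_quantile)
}

#' Flag marker-positive cells
#'
#' A cell is positive for a marker when its intensity is strictly greater
#' than the threshold, independent of its lineage.
#'
#' @param cells Tibble with one intensity column per marker.
#' @param marker Marker column name.
#' @param threshold Intensity threshold (e.g. from [derive_threshold_fmo()]).
#' @return `cells` with an added logical column `<marker>_pos`.
#' @export
mark_positive <- function(cells, marker, threshold) {
  if (!marker %in% names(cells)) {
    abort(paste0("marker column `", marker, "` not found."))
  }
  cells[[paste0(marker, "_pos")]] <- cells[[marker]] > threshold
  cells
}

#' Gate cells into lineages
#'
#' Applies the configuration's thresholds to every referenced marker, then
#' assigns each cell the first matching lineage rule (or `UNCLASSIFIED`).
#' TAMs additionally get `tam_subtype` (`"m2"` when CD163-positive, else
#' `"m1"`) and TILs a logical `cd8_pos` sub-flag when those markers carry
#' thresholds.
#'
#' @param cells Tibble with one intensity column per marker.
#' @param config A [gating_config()].
#' @return `cells` with `lineage`, per-marker `<marker>_pos` flags,
#'   `tam_subtype` and (if CD8 is thresholded) `cd8_pos`.
#' @examples
#' fld <- simulate_field(seed = 1)
#' thr <- derive_threshold_fmo(simulate_fmo_null(seed = 2))
#' gated <- gate_lineages(fld$cells, default_gating_config(thr))
#' mean(gated$lineage == fld$cells$true_lineage)
#' @export
gate_lineages <- function(cells, config) {
  stopifnot(inherits(config, "gating_config"))
  markers <- names(config$thresholds)
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("gating rules reference missing marker column(s): ",
                 paste(missing, collapse = ", ")))
  }
  pos <- map(setNames(markers, markers),
             function(m) cells[[m]] > config$thresholds[[m]])

  lineage <- rep("UNCLASSIFIED", nrow(cells))
  unset <- rep(TRUE, nrow(cells))
  for (rule in config$rules) {
    match <- unset
    for (m in rule$positive) match <- match & pos[[m]]
    for (m in rule$negative) match <- match & !pos[[m]]
    lineage[match] <- rule$lineage
    unset <- unset & !match
  }
  cells$lineage <- lineage
  for (m in markers) cells[[paste0(m, "_pos")]] <- pos[[m]]
  if ("cd163" %in% markers) {
    cells$tam_subtype <- ifelse(cells$lineage == "tam",
                                ifelse(pos[["cd163"]], "m2", "m1"),
                                NA_character_)
  }
  cells
}

#' Read / write a gating configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_gating_config()` returns a `gating_config`;
#'   `write_gating_config()` returns `path` invisibly.
#' @export
read_gating_config <- function(path) {
  y <- yaml::read_yaml(path)
  gating_config(unlist(y$thresholds), y$rules,
                positivity_quantile = y$positivity_quantile %||% 0.99)
}

#' @rdname read_gating_config
#' @param config A `gating_config`.
#' @export
write_gating_config <- function(config, path) {
  stopifnot(inherits(config, "gating_config"))
  yaml::write_yaml(list(thresholds = as.list(config$thresholds),
                        positivity_quantile = config$positivity_quantile,
                        rules = config$rules), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
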
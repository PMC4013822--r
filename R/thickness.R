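#' Enamel thickness map from a boundary set
#'
#' Thickness is the difference between the smoothed inner boundary and the
#' outer boundary, per (column, B-scan). Cells where either boundary is
#' undefined are `NA`; negative differences (local segmentation failures)
#' are also set to `NA` — zero is a meaningful physical thickness, so
#' failures are marked undefined rather than clipped.
#'
#' @param bounds A `boundary_set` from [segment_enamel()].
#' @param stage_label Optional treatment-stage label (`"a"`..`"g"`).
#' @return Object of class `thickness_map`: list with `values` (N x I, axial
#'   pixels), `unit`, `stage_label` and `spacing_axial`.
#' @export
thickness_map <- function(bounds, stage_label = NULL) {
  vals <- bounds$L_in - bounds$L_en
  neg <- which(!is.na(vals) & vals < 0)
  if (length(neg)) {
    warning(sprintf("thickness_map: %d negative cell(s) marked undefined", length(neg)))
    vals[neg] <- NA_real_
  }
  if (all(is.na(vals))) stop("thickness map is fully undefined")
  structure(list(values = vals, unit = "px", stage_label = stage_label,
                 spacing_axial = unname(bounds$spacing[["axial"]])),
            class = "thickness_map")
}

#' Convert a thickness map from pixels to micrometres
#'
#' @param map A `thickness_map` in pixel units.
#' @param spacing_axial Micrometres per axial pixel; defaults to the spacing
#'   recorded in the map.
#' @return The map with `values` in micrometres and `unit = "um"`.
#' @export
to_micrometers <- function(map, spacing_axial = map$spacing_axial) {
  stopifnot(inherits(map, "thickness_map"))
  if (map$unit == "um") stop("map is already in micrometres")
  map$values <- map$values * spacing_axial
  map$unit <- "um"
  map
}

#' @export
print.thickness_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<thickness_map>%s %d x %d, unit %s, %d defined cells\n",
              if (is.null(x$stage_label)) "" else paste0(" stage ", x$stage_label),
              d[1], d[2], x$unit, sum(!is.na(x$values))))
  if (any(!is.na(x$values)))
    cat(sprintf("  mean %.1f  range [%.1f, %.1f]\n",
                mean(x$values, na.rm = TRUE), min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Defined-cell mask of a thickness map
#' @param map A `thickness_map`.
#' @return Logical N x I matrix.
#' @export
defined_mask <- function(map) !is.na(map$values)

#' Write a thickness map as CSV plus a PGM preview
#'
#' @param map A `thickness_map`.
#' @param path CSV output path; the preview gets the same path with a `.pgm`
#'   extension.
#' @param preview Write the PGM preview image too?
#' @return `path`, invisibly.
#' @export
write_thickness_csv <- function(map, path, preview = FALSE) {
  write_matrix_csv(map$values, path)
  if (preview) write_pgm(map$values, sub("\\.csv$", ".pgm", path))
  invisible(path)
}
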
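#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one place; the
#' defaults are the values used throughout the method's description
#' (acquisition spacings, filter mask sizes, morphological structuring
#' element, registration search ranges, the 70-pixel boundary-disambiguation
#' limit and the active-contour parameters). All are overridable, e.g. a
#' smaller `h3` for volumes with few B-scans.
#'
#' @param spacing_axial Axial pixel size, micrometres per pixel.
#' @param spacing_lateral Lateral pixel size, micrometres per pixel.
#' @param spacing_slice Inter-B-scan distance, micrometres.
#' @param h1 Grey-volume median mask (pre-processing).
#' @param h2 Binary-volume median mask.
#' @param se Structuring-element size for the in-plane closing.
#' @param h3 Projection median mask for ROI extraction.
#' @param shift_range Registration shift search limit, px (each axis).
#' @param zoom_levels Registration zoom candidates, percent.
#' @param limit_shift_px Boundary disagreement limit for the p_r2/p_r3
#'   disambiguation (70 px, i.e. 350 um at 5 um/px).
#' @param contour A [contour_params()].
#' @param seed Integer seed recorded with reports.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing_axial = 5, spacing_lateral = 11.7,
                            spacing_slice = 47,
                            h1 = c(3, 3, 3), h2 = c(3, 3, 3), se = c(3, 3),
                            h3 = c(31, 31),
                            shift_range = 40, zoom_levels = seq(-20, 20, 10),
                            limit_shift_px = 70,
                            contour = contour_params(),
                            seed = 1L) {
  cfg <- list(spacing_axial = spacing_axial, spacing_lateral = spacing_lateral,
              spacing_slice = spacing_slice, h1 = h1, h2 = h2, se = se, h3 = h3,
              shift_range = shift_range, zoom_levels = zoom_levels,
              limit_shift_px = limit_shift_px, contour = contour,
              seed = as.integer(seed))
  if (any(c(spacing_axial, spacing_lateral, spacing_slice) <= 0))
    stop("spacings must be positive")
  if (shift_range < 1) stop("shift_range must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  spacing: %g x %g um/px, %g um/slice\n",
              x$spacing_axial, x$spacing_lateral, x$spacing_slice))
  cat(sprintf("  masks: h1 %s, h2 %s, SE %s, h3 %s\n",
              paste(x$h1, collapse = "x"), paste(x$h2, collapse = "x"),
              paste(x$se, collapse = "x"), paste(x$h3, collapse = "x")))
  cat(sprintf("  search: shifts +/-%d px, zoom {%s}%%, limit %d px\n",
              x$shift_range, paste(x$zoom_levels, collapse = ","),
              x$limit_shift_px))
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()] (the `contour` entry is
#' a nested mapping of [contour_params()] arguments); missing keys keep
#' their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$contour)) vals$contour <- do.call(contour_params, vals$contour)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$contour <- unclass(x$contour)
  yaml::write_yaml(x, path)
  invisible(path)
}
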
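#' Per-stage thickness statistics inside the ROI
#'
#' @param map A `thickness_map` (conventionally in micrometres), aligned to
#'   the reference grid.
#' @param mask Optional `roi_mask`; when omitted, statistics cover all
#'   defined cells.
#' @return Object of class `stage_stats`: `stage_label`, `mean`, `std`,
#'   `min`, `max`, `n_defined` (units follow the map).
#' @export
stage_statistics <- function(map, mask = NULL) {
  stopifnot(inherits(map, "thickness_map"))
  vals <- map$values
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "roi_mask"))
    if (!all(dim(vals) == dim(mask$mask))) stop("mask/map shape mismatch")
    vals[!mask$mask] <- NA_real_
  }
  v <- vals[!is.na(vals)]
  if (!length(v)) stop("no defined cells inside the ROI")
  structure(list(stage_label = map$stage_label, mean = mean(v),
                 std = stats::sd(v), min = min(v), max = max(v),
                 n_defined = length(v), unit = map$unit),
            class = "stage_stats")
}

#' @export
print.stage_stats <- function(x, ...) {
  cat(sprintf("<stage_stats>%s mean %.1f +/- %.1f %s  [%.1f, %.1f]  n = %d\n",
              if (is.null(x$stage_label)) "" else paste0(" stage ", x$stage_label),
              x$mean, if (is.na(x$std)) 0 else x$std, x$unit, x$min, x$max,
              x$n_defined))
  invisible(x)
}

#' Pairwise stage-difference matrix of mean enamel thickness
#'
#' Entry `D[r, c]` is `mean_c - mean_r`: the row stage is the baseline, so a
#' negative value in row 1 means thickness loss relative to the untreated
#' tooth. The matrix is antisymmetric by construction.
#'
#' @param stats List of 7 `stage_stats` (stages a..g, in order) or a numeric
#'   vector of 7 stage means.
#' @return 7 x 7 numeric matrix with stage-labelled dimnames.
#' @export
difference_matrix <- function(stats) {
  means <- if (is.numeric(stats)) stats
           else vapply(stats, function(s) s$mean, 0)
  if (length(means) != 7L) stop("exactly 7 stages (a..g) are required")
  lab <- paste0("L_ROI", letters[1:7])
  D <- matrix(means, 7, 7, byrow = TRUE) - matrix(means, 7, 7)
  dimnames(D) <- list(lab, lab)
  D
}

#' Relative thickness-measurement error against a reference profile
#'
#' Mean absolute relative difference, in percent, between an automatically
#' measured thickness profile and a reference (expert or ground-truth)
#' profile over their common defined support. Columns where the reference is
#' zero are excluded with a warning.
#'
#' @param L_d Numeric vector/matrix: automatic thickness.
#' @param L_d_ref Numeric vector/matrix of the same shape: reference
#'   thickness.
#' @return Scalar error in percent.
#' @export
measurement_error <- function(L_d, L_d_ref) {
  a <- as.vector(L_d); e <- as.vector(L_d_ref)
  if (length(a) != length(e)) stop("profiles must have equal length")
  ok <- !is.na(a) & !is.na(e)
  zero <- ok & e == 0
  if (any(zero)) {
    warning(sprintf("measurement_error: %d zero-reference column(s) excluded",
                    sum(zero)))
    ok <- ok & !zero
  }
  if (!any(ok)) stop("no comparable columns")
  mean(abs(a[ok] - e[ok]) / e[ok]) * 100
}

#' Linearly interpolate sparse expert boundary points
#'
#' Experts mark a boundary at scattered columns; consecutive marks are
#' connected with straight segments (no extrapolation beyond the first and
#' last mark).
#'
#' @param n Columns of the marked points.
#' @param row Boundary rows at those columns.
#' @param N Total number of columns of the B-scan.
#' @return Length-N vector, `NA` outside the marked span.
#' @export
interpolate_expert_points <- function(n, row, N) {
  ok <- !is.na(row)
  n <- n[ok]; row <- row[ok]
  if (length(n) < 2L) stop("need at least two expert points")
  out <- rep(NA_real_, N)
  sp <- seq(min(n), max(n))
  out[sp] <- stats::approx(n, row, xout = sp, method = "linear", ties = "ordered")$y
  out
}

#' Read expert boundary annotations from CSV
#'
#' Expected columns: `i` (B-scan), `n` (column), `outer_row`, `inner_row`
#' (either may be `NA` at a given point). Points are interpolated per B-scan
#' with [interpolate_expert_points()] and the expert thickness profile is
#' `inner - outer`.
#'
#' @param path CSV path.
#' @param N Number of columns of the underlying B-scans.
#' @return Named list (by B-scan index) of lists `L_en_E`, `L_in_E`, `L_d_E`.
#' @export
read_expert_boundaries <- function(path, N) {
  df <- utils::read.csv(path)
  need <- c("i", "n", "outer_row", "inner_row")
  if (!all(need %in% names(df))) stop("expert CSV must have columns i, n, outer_row, inner_row")
  out <- list()
  for (i in sort(unique(df$i))) {
    sub <- df[df$i == i, ]
    en <- interpolate_expert_points(sub$n, sub$outer_row, N)
    inn <- interpolate_expert_points(sub$n, sub$inner_row, N)
    bad <- which(!is.na(en) & !is.na(inn) & inn < en)
    if (length(bad)) stop("expert inner boundary above outer boundary")
    out[[as.character(i)]] <- list(L_en_E = en, L_in_E = inn, L_d_E = inn - en)
  }
  out
}

#' Write the analysis report (CSV tables + JSON metadata)
#'
#' Writes `stage_stats.csv` (stage, mean, std, min, max, n),
#' `difference_matrix.csv` (7 x 7 with stage labels) and `run_meta.json`
#' (configuration echo). Output is deterministic: no timestamps.
#'
#' @param stats List of `stage_stats`.
#' @param matrix Difference matrix from [difference_matrix()].
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if missing).
#' @param extra Optional named list merged into the JSON metadata
#'   (e.g. registration transforms).
#' @return `dir`, invisibly.
#' @export
export_report <- function(stats, matrix, config, dir, extra = list()) {
  if (!length(stats)) stop("empty statistics list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(stage = vapply(stats, function(s) s$stage_label %||% NA_character_, ""),
                   mean = vapply(stats, function(s) s$mean, 0),
                   std = vapply(stats, function(s) s$std, 0),
                   min = vapply(stats, function(s) s$min, 0),
                   max = vapply(stats, function(s) s$max, 0),
                   n = vapply(stats, function(s) s$n_defined, 0L))
  utils::write.csv(df, file.path(dir, "stage_stats.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(matrix), file.path(dir, "difference_matrix.csv"),
                   row.names = TRUE)
  meta <- c(list(package = "enameloct",
                 config = unclass(config)), extra)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(dir)
}

#' Read back a report written by [export_report()]
#' @param dir Report directory.
#' @return List with `stats` (data frame), `matrix` and `meta`.
#' @export
read_report <- function(dir) {
  stats <- utils::read.csv(file.path(dir, "stage_stats.csv"))
  m <- utils::read.csv(file.path(dir, "difference_matrix.csv"), row.names = 1)
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"))
  list(stats = stats, matrix = as.matrix(m), meta = meta)
}
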
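#' Parameters for the synthetic OCT tooth phantom
#'
#' The phantom emulates the appearance of a dental OCT volume: above a bright,
#' curved outer tooth surface there is dark background; below it an enamel
#' band whose brightness decays linearly with depth (the characteristic
#' falling part of a dental A-scan) sits on top of a dimmer, constant-level
#' dentine plateau. The tooth occupies an elliptical footprint of the en-face
#' (n, i) plane; outside the footprint the column is pure background.
#' Multiplicative Rayleigh-like speckle is added on top, clipped to
#' `[0, 255]`.
#'
#' Boundary convention: the outer boundary is the first enamel row; the inner
#' boundary is the first row *below* the enamel (exclusive convention), so
#' `inner - outer` equals the number of enamel rows, i.e. the thickness in
#' axial pixels.
#'
#' @param shape `c(M, N, I)`: depth rows, lateral columns, B-scans.
#' @param spacing `c(axial, lateral, slice)` in micrometres (per pixel for
#'   the first two).
#' @param levels List with `background`, `enamel` (length 2: brightness at
#'   the surface and at the inner boundary; a scalar gives a constant band)
#'   and `dentine`, all in `[0, 255]`. Enamel must be brighter than dentine,
#'   dentine brighter than background.
#' @param surface_fun `function(n, i, shape)` returning the outer-surface row
#'   for vectors `n`, `i` (recycled); `NULL` for the built-in curved default.
#' @param thickness_fun `function(n, i, shape)` returning the enamel
#'   thickness in axial pixels (0 outside the tooth); `NULL` for the default
#'   tapered field over an elliptical footprint.
#' @param footprint Semi-axes of the default elliptical tooth footprint as
#'   fractions of `N/2` and `I/2`; ignored when `thickness_fun` is given.
#' @param speckle List with `model` (only `"rayleigh"`) and `strength`
#'   (0 disables noise).
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(884, 512, 128),
                           spacing = c(axial = 5, lateral = 11.7, slice = 47),
                           levels = list(background = 10, enamel = c(220, 110),
                                         dentine = 80),
                           surface_fun = NULL,
                           thickness_fun = NULL,
                           footprint = c(0.45, 0.45),
                           speckle = list(model = "rayleigh", strength = 0.15),
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive sizes")
  en <- levels$enamel
  if (length(en) == 1L) en <- c(en, en)
  if (any(c(levels$background, en, levels$dentine) < 0) ||
      any(c(levels$background, en, levels$dentine) > 255))
    stop("intensity levels must lie in [0, 255]")
  if (!(min(en) > levels$dentine && levels$dentine > levels$background))
    stop("need enamel > dentine > background brightness")
  if (speckle$strength < 0) stop("speckle strength must be >= 0")
  p <- list(shape = shape, spacing = spacing,
            levels = list(background = levels$background, enamel = en,
                          dentine = levels$dentine),
            surface_fun = surface_fun, thickness_fun = thickness_fun,
            footprint = footprint, speckle = speckle, seed = as.integer(seed))
  class(p) <- "phantom_params"
  p
}

# Default geometry scales with the volume so phantoms of any size stay
# valid; at the native 884-row depth this gives a surface around row 120
# with +/-50 px curvature and a 146-px (730 um) central enamel thickness.
.default_surface <- function(n, i, shape) {
  M <- shape[1]; N <- shape[2]; I <- shape[3]
  cn <- (N + 1) / 2; ci <- (I + 1) / 2
  M * (0.135 + 0.057 * ((n - cn) / (N / 2))^2 + 0.017 * ((i - ci) / (I / 2))^2 +
         0.014 * n / N + 0.007 * i / I)
}

.default_thickness <- function(n, i, shape, footprint, base_px = 0.165 * shape[1]) {
  N <- shape[2]; I <- shape[3]
  cn <- (N + 1) / 2; ci <- (I + 1) / 2
  e2 <- ((n - cn) / (footprint[1] * N))^2 + ((i - ci) / (footprint[2] * I))^2
  ifelse(e2 <= 1, base_px * (0.6 + 0.4 * sqrt(pmax(0, 1 - e2))), 0)
}

.phantom_fields <- function(params) {
  shape <- params$shape
  N <- shape[2]; I <- shape[3]
  nn <- matrix(seq_len(N), N, I)
  ii <- matrix(rep(seq_len(I), each = N), N, I)
  sf <- params$surface_fun %||% .default_surface
  tf <- params$thickness_fun %||%
    function(n, i, shape) .default_thickness(n, i, shape, params$footprint)
  f <- matrix(round(sf(as.vector(nn), as.vector(ii), shape)), N, I)
  g <- matrix(round(tf(as.vector(nn), as.vector(ii), shape)), N, I)
  if (any(g < 0)) stop("thickness field must be >= 0")
  if (any(f[g > 0] < 1) || any((f + g)[g > 0] > shape[1]))
    stop("surface + thickness must stay within [1, M]")
  list(f = f, g = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic OCT volume with known ground truth
#'
#' @param params A [phantom_params()] object.
#' @return A list with `volume` (an [oct_volume()]) and `truth`, a list of
#'   `outer_boundary`, `inner_boundary` (N x I row indices, `NA` outside the
#'   tooth), `thickness_px`, `tooth_mask` and `applied_transform`
#'   `c(dn, di, dz)`.
#' @examples
#' p <- phantom_params(shape = c(60, 24, 2), speckle = list(strength = 0))
#' ph <- generate_volume(p)
#' range(ph$truth$thickness_px[ph$truth$tooth_mask])
#' @export
generate_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  shape <- params$shape
  M <- shape[1]; N <- shape[2]; I <- shape[3]
  fg <- .phantom_fields(params)
  f <- fg$f; g <- fg$g
  lv <- params$levels
  nc <- N * I
  rowm <- matrix(seq_len(M), M, nc)
  F <- matrix(rep(as.vector(f), each = M), M, nc)
  G <- matrix(rep(as.vector(g), each = M), M, nc)
  vol <- matrix(lv$background, M, nc)
  in_en <- rowm >= F & rowm < F + G & G > 0
  in_de <- rowm >= F + G & G > 0
  # linear decay over the band: brightness enamel[1] at the surface row,
  # enamel[2] at the last enamel row
  depth_frac <- (rowm - F) / pmax(G - 1, 1)
  en_val <- lv$enamel[1] + depth_frac * (lv$enamel[2] - lv$enamel[1])
  vol[in_en] <- en_val[in_en]
  vol[in_de] <- lv$dentine
  if (params$speckle$strength > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(params$seed)
    # Rayleigh with unit mean, mixed towards 1 by `strength`
    ray <- stats::rweibull(length(vol), shape = 2, scale = 2 / sqrt(pi))
    vol <- vol * (1 + params$speckle$strength * (ray - 1))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  vol <- pmin(pmax(round(vol), 0), 255)
  arr <- array(as.integer(vol), c(M, N, I))
  truth <- list(
    outer_boundary = ifelse(g > 0, f, NA_integer_),
    inner_boundary = ifelse(g > 0, f + g, NA_integer_),
    thickness_px = g,
    tooth_mask = g > 0,
    applied_transform = c(dn = 0, di = 0, dz = 0)
  )
  list(volume = oct_volume(arr, params$spacing[[1]], params$spacing[[2]],
                           params$spacing[[3]]),
       truth = truth)
}

# Separable source-index maps realising the registration warp used by the
# match criterion: aligned(n) = moving(round(c + (n + dn - c) * s)) with
# s = 1 + dz/100. The stage volume is built by scattering reference columns
# to those target indices (later writes win), so that sampling the stage at
# the planted parameters reproduces the reference exactly wherever the map
# is injective. Interior gaps (|s| > 1 strides) are filled from the nearest
# assigned neighbour; targets outside the grid are dropped (zero-fill).
.scatter_map <- function(len, dshift, dz) {
  s <- 1 + dz / 100
  cc <- (len + 1) / 2
  tgt <- round(cc + (seq_len(len) + dshift - cc) * s)
  src <- rep(NA_integer_, len)
  keep <- tgt >= 1 & tgt <= len
  src[tgt[keep]] <- seq_len(len)[keep]
  if (any(!is.na(src))) {
    idx <- which(!is.na(src))
    lo <- min(idx); hi <- max(idx)
    for (p in seq(lo, hi)) {
      if (is.na(src[p])) {
        below <- max(idx[idx < p]); above <- min(idx[idx > p])
        src[p] <- if (p - below <= above - p) src[below] else src[above]
      }
    }
  }
  src
}

.warp_volume <- function(arr, dn, di, dz, fill = 0L) {
  d <- dim(arr)
  nsrc <- .scatter_map(d[2], dn, dz)
  isrc <- .scatter_map(d[3], di, dz)
  out <- array(fill, d)
  nok <- which(!is.na(nsrc)); iok <- which(!is.na(isrc))
  out[, nok, iok] <- arr[, nsrc[nok], isrc[iok], drop = FALSE]
  out
}

.warp_matrix <- function(m, dn, di, dz, fill = NA) {
  d <- dim(m)
  nsrc <- .scatter_map(d[1], dn, dz)
  isrc <- .scatter_map(d[2], di, dz)
  out <- matrix(fill, d[1], d[2])
  nok <- which(!is.na(nsrc)); iok <- which(!is.na(isrc))
  out[nok, iok] <- m[nsrc[nok], isrc[iok]]
  out
}

#' Generate a series of treatment-stage phantoms
#'
#' Stage `k` shares the base geometry but its enamel thickness field is
#' offset by `stage_deltas[k]` (micrometres, converted to axial pixels and
#' clipped at zero), and the whole volume is displaced by the planted
#' transform `(dn, di, dz)` — lateral/slice shifts in pixels plus a
#' centre-anchored nearest-neighbour zoom in percent, the same motion model
#' the registration stage searches over. Uncovered cells are filled with the
#' background level (a displaced acquisition images background there).
#'
#' @param base A [phantom_params()] object (stage 1 uses it unchanged).
#' @param stage_deltas Numeric vector of per-stage mean-thickness offsets in
#'   micrometres relative to stage 1 (first entry must be 0).
#' @param stage_transforms List of `c(dn, di, dz)` per stage (first must be
#'   the identity). Shifts are limited to `[-40, 40]` px and zoom to
#'   `[-20, 20]` percent, the search range of the registration stage.
#' @param stage_labels Stage labels, default `letters[1:k]`.
#' @return A list of per-stage lists as returned by [generate_volume()], with
#'   `truth$applied_transform` recording the planted transform.
#' @export
generate_stage_series <- function(base, stage_deltas,
                                  stage_transforms = NULL,
                                  stage_labels = NULL) {
  stopifnot(inherits(base, "phantom_params"))
  k <- length(stage_deltas)
  if (is.null(stage_transforms)) stage_transforms <- rep(list(c(0, 0, 0)), k)
  if (length(stage_transforms) != k) stop("one transform per stage required")
  if (stage_deltas[1] != 0) stop("first stage must have zero thickness delta")
  if (any(stage_transforms[[1]] != 0)) stop("first stage must have the identity transform")
  for (tr in stage_transforms) {
    if (abs(tr[1]) > 40 || abs(tr[2]) > 40) stop("|dn|, |di| must be <= 40 px")
    if (abs(tr[3]) > 20) stop("|dz| must be <= 20 percent")
  }
  if (is.null(stage_labels)) stage_labels <- letters[seq_len(k)]
  axial <- base$spacing[[1]]
  base_tf <- base$thickness_fun %||%
    function(n, i, shape) .default_thickness(n, i, shape, base$footprint)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    dpx <- round(stage_deltas[j] / axial)
    pj <- base
    pj$thickness_fun <- local({
      dpx_j <- dpx
      function(n, i, shape) {
        g0 <- base_tf(n, i, shape)
        ifelse(g0 > 0, pmax(g0 + dpx_j, 0), 0)
      }
    })
    pj$seed <- base$seed + j - 1L
    ph <- generate_volume(pj)
    tr <- stage_transforms[[j]]
    if (any(tr != 0)) {
      # Background fill, not zero: a displaced acquisition images background
      # in the uncovered strip, and zero-filling would skew the min-max
      # normalization of the stage's C-scan projection.
      arr <- .warp_volume(unclass(ph$volume), tr[1], tr[2], tr[3],
                          fill = as.integer(base$levels$background))
      sp <- spacing_of(ph$volume)
      ph$volume <- oct_volume(arr, sp[[1]], sp[[2]], sp[[3]])
      ph$truth$outer_boundary <- .warp_matrix(ph$truth$outer_boundary, tr[1], tr[2], tr[3])
      ph$truth$inner_boundary <- .warp_matrix(ph$truth$inner_boundary, tr[1], tr[2], tr[3])
      ph$truth$thickness_px <- .warp_matrix(ph$truth$thickness_px, tr[1], tr[2], tr[3], fill = 0)
      ph$truth$tooth_mask <- .warp_matrix(ph$truth$tooth_mask, tr[1], tr[2], tr[3], fill = FALSE)
    }
    ph$truth$applied_transform <- c(dn = tr[1], di = tr[2], dz = tr[3])
    ph$stage_label <- stage_labels[j]
    out[[j]] <- ph
  }
  out
}

#' Export phantom ground truth as CSV files
#'
#' Writes `outer_boundary.csv`, `inner_boundary.csv`, `thickness_px.csv` and
#' `tooth_mask.csv` (all N x I, rows = columns n) into `dir`.
#'
#' @param truth The `truth` element returned by [generate_volume()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_ground_truth_csv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(truth$outer_boundary, file.path(dir, "outer_boundary.csv"))
  write_matrix_csv(truth$inner_boundary, file.path(dir, "inner_boundary.csv"))
  write_matrix_csv(truth$thickness_px, file.path(dir, "thickness_px.csv"))
  write_matrix_csv(truth$tooth_mask * 1, file.path(dir, "tooth_mask.csv"))
  invisible(dir)
}
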
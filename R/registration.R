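#' En-face (C-scan) projection of a volume, min-max normalized
#'
#' Each A-scan is summed over depth, and the resulting (column, B-scan)
#' image is rescaled to `[0, 1]`. A constant projection (zero denominator)
#' degenerates to all zeros with a warning.
#'
#' @param volume A median-filtered [oct_volume()].
#' @return Object of class `projection_image`: an N x I matrix in `[0, 1]`
#'   (rows = lateral columns, cols = B-scans).
#' @export
normalized_projection <- function(volume) {
  sums <- colSums(unclass(volume))  # collapses depth: N x I
  rng <- range(sums)
  if (diff(rng) == 0) {
    warning("constant projection: returning all zeros")
    out <- sums * 0
  } else {
    out <- (sums - rng[1]) / diff(rng)
  }
  structure(out, class = c("projection_image", "matrix"))
}

# Centre-anchored nearest-neighbour zoom with zero-fill: the output samples
# the input at stride s = 1 + dz/100 about the grid centre. dz > 0 shrinks
# the content (the moving image was magnified relative to the reference).
.zoom_map <- function(len, dz) {
  s <- 1 + dz / 100
  cc <- (len + 1) / 2
  src <- round(cc + (seq_len(len) - cc) * s)
  src[src < 1 | src > len] <- NA_integer_
  src
}

# Sample `img` at (n + dn, i + di) after zooming by dz; `fill` outside.
.sample_map <- function(img, dn, di, dz, fill = 0) {
  N <- nrow(img); I <- ncol(img)
  ns <- seq_len(N) + dn
  is <- seq_len(I) + di
  zn <- .zoom_map(N, dz); zi <- .zoom_map(I, dz)
  nsrc <- ifelse(ns >= 1 & ns <= N, zn[pmax(pmin(ns, N), 1)], NA_integer_)
  isrc <- ifelse(is >= 1 & is <= I, zi[pmax(pmin(is, I), 1)], NA_integer_)
  out <- matrix(fill, N, I)
  nok <- which(!is.na(nsrc)); iok <- which(!is.na(isrc))
  if (length(nok) && length(iok))
    out[nok, iok] <- img[nsrc[nok], isrc[iok]]
  out
}

#' Match criterion J between two projection images
#'
#' Mean absolute difference over the full grid between the reference image
#' and the moving image zoomed by `dz` percent (centre-anchored
#' nearest-neighbour) and shifted by `(dn, di)` pixels; zero is written for
#' samples falling outside the moving image, and the denominator is always
#' the full grid size.
#'
#' @param ref,moving Projection images (equal N x I shape).
#' @param dn,di Column/B-scan shift in pixels, each within `[-limit, limit]`.
#' @param dz Zoom in percent.
#' @param limit Shift search limit (default 40 px).
#' @return Scalar J >= 0.
#' @export
match_criterion <- function(ref, moving, dn, di, dz = 0, limit = 40) {
  if (!all(dim(ref) == dim(moving))) stop("images must have equal shape")
  if (abs(dn) > limit || abs(di) > limit)
    stop(sprintf("|dn| and |di| must be <= %d", limit))
  warped <- .sample_map(unclass(moving), dn, di, dz, fill = 0)
  mean(abs(unclass(ref) - warped))
}

#' Register a moving C-scan projection to the reference by exhaustive search
#'
#' Scans all integer shifts `dn, di` in `[-shift_range, shift_range]` and all
#' zoom levels, computing J for each candidate, and returns the global
#' minimum. Ties are broken towards the smallest Euclidean norm of
#' `(dn, di, dz)` and then lexicographically.
#'
#' @param ref,moving Projection images (equal shape).
#' @param config A [pipeline_config()] supplying `shift_range` and
#'   `zoom_levels`.
#' @return Object of class `registration_result`: `dn`, `di`, `dz`, `J`, and
#'   `J_surface` (a 3-D array shift x shift x zoom of all criterion values).
#' @export
register_projection <- function(ref, moving, config = pipeline_config()) {
  if (!all(dim(ref) == dim(moving))) stop("images must have equal shape")
  K <- config$shift_range
  zooms <- config$zoom_levels
  nshift <- 2L * K + 1L
  surf <- array(NA_real_, c(nshift, nshift, length(zooms)),
                dimnames = list(dn = -K:K, di = -K:K, dz = zooms))
  for (zi in seq_along(zooms)) {
    zmov <- .sample_map(unclass(moving), 0L, 0L, zooms[zi], fill = 0)
    surf[, , zi] <- j_surface_cpp(unclass(ref), zmov, as.integer(K))
  }
  jmin <- min(surf)
  cand <- which(surf == jmin, arr.ind = TRUE)
  dn <- cand[, 1] - K - 1L
  di <- cand[, 2] - K - 1L
  dz <- zooms[cand[, 3]]
  nrm <- dn^2 + di^2 + dz^2
  ord <- order(nrm, dn, di, dz)
  pick <- ord[1]
  structure(list(dn = as.integer(dn[pick]), di = as.integer(di[pick]),
                 dz = dz[pick], J = jmin, J_surface = surf),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> dn = %d px, di = %d px, dz = %g%%, J = %.6g\n",
              x$dn, x$di, x$dz, x$J))
  invisible(x)
}

#' Resample a thickness map onto the reference grid
#'
#' Applies the registering warp found by [register_projection()] to a
#' thickness map of the same stage, so that all stages live on the reference
#' stage's (n, i) grid. Undefined cells and zero-fill borders propagate as
#' `NA`.
#'
#' @param map A `thickness_map`.
#' @param r A `registration_result` obtained for this stage's projection.
#' @return The aligned `thickness_map`.
#' @export
apply_transform <- function(map, r) {
  stopifnot(inherits(map, "thickness_map"), inherits(r, "registration_result"))
  map$values <- .sample_map(map$values, r$dn, r$di, r$dz, fill = NA_real_)
  map
}

#' Dump a J surface as CSV (one shift grid per zoom level)
#'
#' @param r A `registration_result`.
#' @param dir Output directory; files are named `J_surface_dz<zoom>.csv`.
#' @return `dir`, invisibly.
#' @export
write_j_surface_csv <- function(r, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  zooms <- dimnames(r$J_surface)$dz
  for (zi in seq_along(zooms))
    write_matrix_csv(r$J_surface[, , zi],
                     file.path(dir, sprintf("J_surface_dz%s.csv", zooms[zi])))
  invisible(dir)
}
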
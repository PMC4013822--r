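#' Active-contour parameters
#'
#' @param search_range Maximum vertex move per sweep along its normal, px.
#' @param patch Side length of the grey-level averaging window evaluated on
#'   both sides of a vertex.
#' @param max_iters Sweep limit (termination guarantee).
#' @param init_margin Inset of the initial rectangular contour from the
#'   image frame, px.
#' @param n_vertices Number of contour vertices.
#' @return Object of class `contour_params`.
#' @export
contour_params <- function(search_range = 20, patch = 6, max_iters = 100,
                           init_margin = 3, n_vertices = 64) {
  p <- list(search_range = search_range, patch = patch, max_iters = max_iters,
            init_margin = init_margin, n_vertices = n_vertices)
  if (any(unlist(p) <= 0)) stop("all contour parameters must be positive")
  class(p) <- "contour_params"
  p
}

#' Median-smooth a projection image for contour extraction
#'
#' 2-D median filter (default 31 x 31) with edge replication, sized to the
#' typical tooth width so that speckle and small artefacts do not attract
#' the contour.
#'
#' @param proj A `projection_image` (or plain matrix).
#' @param h3 Mask size `c(rows, cols)`, both odd.
#' @return Smoothed image, same class and shape.
#' @export
smooth_for_roi <- function(proj, h3 = c(31, 31)) {
  if (any(dim(proj) < h3)) stop("image smaller than the median mask")
  if (any(h3 %% 2 == 0)) stop("mask sizes must be odd")
  out <- med2d_cpp(unclass(proj), as.integer(h3[1]), as.integer(h3[2]))
  class(out) <- class(proj)
  out
}

# Integral-image patch mean (patch x patch block centred at a point, clipped
# at the image border).
.patch_mean_fun <- function(img, patch) {
  R <- nrow(img); C <- ncol(img)
  S <- matrix(0, R + 1, C + 1)
  S[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))  # S[r+1,c+1] = sum img[1:r,1:c]
  h0 <- floor((patch - 1) / 2); h1 <- patch - 1 - h0
  function(r, c) {
    r0 <- pmax(1, round(r) - h0); r1 <- pmin(R, round(r) + h1)
    c0 <- pmax(1, round(c) - h0); c1 <- pmin(C, round(c) + h1)
    area <- (r1 - r0 + 1) * (c1 - c0 + 1)
    (S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0, c1 + 1)] -
       S[cbind(r1 + 1, c0)] + S[cbind(r0, c0)]) / area
  }
}

#' Delineate the tooth region of interest with a greedy active contour
#'
#' A closed polygon is initialized as a rectangle inset from the image frame
#' and iteratively refined: each vertex may move along its inward normal
#' (towards the current centroid) by up to `search_range` pixels per sweep,
#' and a move is accepted when it increases the contrast between the mean
#' grey levels of the `patch x patch` windows just inside and just outside
#' the vertex. The algorithm stops when a full sweep moves no vertex, or
#' after `max_iters` sweeps. The final polygon is rasterized (even-odd
#' rule), reduced to its largest connected region and hole-filled.
#'
#' @param smooth A smoothed projection image ([smooth_for_roi()]).
#' @param params A [contour_params()].
#' @return Object of class `roi_mask`: `mask` (logical N x I), `area_px`,
#'   `contour` (V x 2 matrix of (n, i) vertices), `iterations` and
#'   `energy_trace` (total accepted contrast per sweep, non-decreasing).
#' @export
active_contour_roi <- function(smooth, params = contour_params()) {
  img <- unclass(smooth)
  R <- nrow(img); C <- ncol(img)
  if (diff(range(img)) == 0) stop("flat image: no object to outline")
  pm <- .patch_mean_fun(img, params$patch)
  d_in <- max(2, floor(params$patch / 2) + 1)  # patch-centre offset from vertex

  # initial rectangle, n_vertices points along the perimeter
  m <- min(params$init_margin, floor((min(R, C) - 1) / 2))
  per <- 2 * (R - 2 * m) + 2 * (C - 2 * m)
  tpos <- seq(0, per, length.out = params$n_vertices + 1)[-(params$n_vertices + 1)]
  rect_point <- function(t) {
    a <- R - 2 * m; b <- C - 2 * m
    if (t < a) c(m + 1 + t, m + 1)
    else if (t < a + b) c(R - m, m + 1 + (t - a))
    else if (t < 2 * a + b) c(R - m - (t - a - b), C - m)
    else c(m + 1, C - m - (t - 2 * a - b))
  }
  V <- t(vapply(tpos, rect_point, numeric(2)))

  total_energy <- 0
  trace <- numeric(0)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    moved <- FALSE
    ctr <- colMeans(V)
    for (v in seq_len(nrow(V))) {
      p <- V[v, ]
      u <- ctr - p
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) next
      u <- u / nu
      ks <- seq(-1, params$search_range)
      cand_r <- pmin(pmax(round(p[1] + ks * u[1]), 1), R)
      cand_c <- pmin(pmax(round(p[2] + ks * u[2]), 1), C)
      keep <- !duplicated(cbind(cand_r, cand_c))
      cand_r <- cand_r[keep]; cand_c <- cand_c[keep]; kk <- ks[keep]
      # inside patch lies ahead along +u (towards the centroid), outside behind
      e_in <- pm(cand_r + round(d_in * u[1]), cand_c + round(d_in * u[2]))
      e_out <- pm(cand_r - round(d_in * u[1]), cand_c - round(d_in * u[2]))
      e <- e_in - e_out
      cur <- which(kk == 0)
      best <- which.max(e)
      if (length(cur) && e[best] > e[cur] + 1e-12) {
        V[v, ] <- c(cand_r[best], cand_c[best])
        total_energy <- total_energy + (e[best] - e[cur])
        moved <- TRUE
      }
    }
    trace <- c(trace, total_energy)
    if (!moved || iters >= params$max_iters) break
  }

  mask <- .rasterize_polygon(V, R, C)
  cl <- clean_slice_cpp(matrix(as.integer(mask), R, C))
  mask <- cl == 1L
  if (!any(mask)) stop("empty ROI mask: contour collapsed")
  structure(list(mask = mask, area_px = sum(mask), contour = V,
                 iterations = iters, energy_trace = trace),
            class = "roi_mask")
}

# Even-odd rasterization: grid cells whose centre lies inside the polygon.
.rasterize_polygon <- function(V, R, C) {
  nv <- nrow(V)
  px <- V[, 1]; py <- V[, 2]
  qx <- px[c(2:nv, 1)]; qy <- py[c(2:nv, 1)]
  gx <- rep(seq_len(R), C)
  gy <- rep(seq_len(C), each = R)
  inside <- rep(FALSE, R * C)
  for (e in seq_len(nv)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    if (y1 == y2) next
    cond <- (y1 > gy) != (y2 > gy)
    xs <- x1 + (gy - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, cond & gx < xs)
  }
  matrix(inside, R, C)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d grid, area %d px (%.1f%%), %d sweeps\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              100 * x$area_px / length(x$mask), x$iterations))
  invisible(x)
}

#' Restrict thickness maps to the ROI
#'
#' @param maps A `thickness_map` or list of aligned `thickness_map`s.
#' @param mask A `roi_mask` with matching grid shape.
#' @return Maps with all out-of-ROI cells set to `NA` (same list/single
#'   structure as the input).
#' @export
apply_roi <- function(maps, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!any(mask$mask)) stop("empty ROI mask")
  one <- function(m) {
    stopifnot(inherits(m, "thickness_map"))
    if (!all(dim(m$values) == dim(mask$mask))) stop("mask/map shape mismatch")
    m$values[!mask$mask] <- NA_real_
    m
  }
  if (inherits(maps, "thickness_map")) one(maps) else lapply(maps, one)
}

#' Write an ROI mask as CSV (and optional PGM preview)
#' @param mask A `roi_mask`.
#' @param path CSV path.
#' @param preview Also write a PGM preview?
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(mask, path, preview = FALSE) {
  write_matrix_csv(mask$mask * 1, path)
  if (preview) write_pgm(mask$mask * 1, sub("\\.csv$", ".pgm", path))
  invisible(path)
}
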
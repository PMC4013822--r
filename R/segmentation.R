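#' Otsu threshold of an 8-bit intensity sample
#'
#' Exhaustively maximises the between-class variance over all integer
#' thresholds; the binarization rule is `intensity > threshold`. When several
#' thresholds tie (e.g. an empty grey-level gap between two modes), the
#' rounded midpoint of the tied range is returned. A constant input returns
#' its single value (so that no pixel exceeds the threshold).
#'
#' @param x Integer vector/array of intensities in `[0, 255]`, or a length-256
#'   histogram of counts when `counts = TRUE`.
#' @param counts Set `TRUE` when `x` already is a histogram over grey levels
#'   0..255.
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(x, counts = FALSE) {
  h <- if (counts) as.numeric(x) else as.numeric(tabulate(as.integer(x) + 1L, 256L))
  tot <- sum(h)
  if (tot <= 0) stop("empty histogram")
  p <- h / tot
  b <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * b)
  muT <- mu[256]
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, 256)
  sb2[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  if (!any(is.finite(sb2))) return(which(h > 0)[1] - 1L)  # constant input
  ties <- which(sb2 >= max(sb2) - 1e-12)
  as.integer(round(mean(ties)) - 1L)
}

#' 3-D median filter of an OCT volume
#'
#' Pre-processing filter with a 3 x 3 x 3 mask and edge replication at the
#' borders; suppresses isolated speckle without displacing slab boundaries.
#'
#' @param volume An [oct_volume()] (or 0/1 integer array for binary use).
#' @param mask_shape Mask size; only `c(3, 3, 3)` is supported.
#' @return Filtered volume of the same class and shape.
#' @export
median_filter_3d <- function(volume, mask_shape = c(3, 3, 3)) {
  if (!identical(as.integer(mask_shape), c(3L, 3L, 3L)))
    stop("only a 3 x 3 x 3 mask is supported")
  d <- dim(volume)
  if (any(d < mask_shape))
    stop("volume smaller than the filter mask in at least one axis")
  out <- med3d_cpp(as.integer(volume), as.integer(d))
  attributes(out) <- attributes(volume)
  out
}

#' Detect the upper (outer) object boundary on every A-scan
#'
#' The global Otsu threshold `p_r` separates object from background; for
#' each (column, B-scan) the boundary `L_ef` is the smallest depth row whose
#' intensity exceeds `p_r`, undefined (`NA`) when no row qualifies.
#'
#' @param volume A median-filtered [oct_volume()].
#' @return List with `L_ef` (N x I integer matrix) and `p_r`.
#' @export
detect_upper_boundary <- function(volume) {
  pr <- otsu_threshold(unclass(volume))
  feats <- column_features_cpp(as.integer(volume), as.integer(dim(volume)), pr)
  if (all(is.na(feats$L_ef)))
    stop("no object: no pixel above the Otsu threshold anywhere")
  list(L_ef = feats$L_ef, p_r = pr)
}

#' Brightness histogram of one A-scan
#'
#' @param volume An [oct_volume()].
#' @param n Column index (1-based).
#' @param i B-scan index (1-based).
#' @param from First depth row to include (1-based); default whole column.
#' @return Integer vector of counts for grey levels `0..255`.
#' @export
column_histogram <- function(volume, n, i, from = 1L) {
  d <- dim(volume)
  if (n < 1 || n > d[2] || i < 1 || i > d[3]) stop("column out of range")
  col <- unclass(volume)[from:d[1], n, i]
  tabulate(as.integer(col) + 1L, 256L)
}

# Two-segment least-squares change point (line for the decaying part I,
# constant for the plateau part II); returns the plateau (suffix) of y.
.plateau_suffix <- function(y) {
  L <- length(y)
  if (L < 4) return(y)
  x <- seq_len(L)
  s1 <- cumsum(y); s2 <- cumsum(y^2); s3 <- cumsum(x * y)
  t <- 2:(L - 2)
  sx <- t * (t + 1) / 2
  sxx <- t * (t + 1) * (2 * t + 1) / 6
  cxx <- sxx - sx^2 / t
  cxy <- s3[t] - sx * s1[t] / t
  rss1 <- (s2[t] - s1[t]^2 / t) - ifelse(cxx > 0, cxy^2 / cxx, 0)
  a2 <- s1[L] - s1[t]; b2 <- s2[L] - s2[t]
  rss2 <- b2 - a2^2 / (L - t)
  tt <- t[which.min(rss1 + rss2)]  # smallest t on ties -> longest plateau
  y[(tt + 1):L]
}

#' Per-A-scan thresholds for the inner enamel boundary
#'
#' The modal grey level `p_r2` of the sub-surface column segment (rows
#' `L_ef..M`) marks the dentine plateau; `p_r3` is the plateau mean plus one
#' standard deviation, the plateau being the trailing segment located by a
#' two-segment least-squares change point. `p_r3` is clamped to be at least
#' `p_r2`. Reference implementation in R; [segment_enamel()] uses an
#' equivalent compiled batch path.
#'
#' @param volume A median-filtered [oct_volume()].
#' @param n,i Column and B-scan index (1-based).
#' @param L_ef Upper boundary row for this column (`NA` propagates).
#' @return `c(p_r2, p_r3)` (both `NA` when `L_ef` is undefined).
#' @export
inner_threshold <- function(volume, n, i, L_ef) {
  if (is.na(L_ef)) return(c(p_r2 = NA_real_, p_r3 = NA_real_))
  col <- as.numeric(unclass(volume)[L_ef:dim(volume)[1], n, i])
  h <- tabulate(as.integer(col) + 1L, 256L)
  p_r2 <- which.max(h) - 1  # which.max takes the smallest bin on ties
  pl <- .plateau_suffix(col)
  p_r3 <- mean(pl) + if (length(pl) >= 2) stats::sd(pl) else 0
  c(p_r2 = p_r2, p_r3 = max(p_r3, p_r2))
}

#' Binarize a volume with per-A-scan thresholds
#'
#' @param volume An [oct_volume()].
#' @param p_r2 Scalar threshold or N x I matrix of per-column thresholds
#'   (`NA` columns binarize to all zero).
#' @return 0/1 integer array, same shape as `volume`.
#' @export
binarize_enamel <- function(volume, p_r2) {
  d <- dim(volume)
  if (length(p_r2) == 1L) {
    thr <- array(p_r2, d)
  } else {
    if (!all(dim(p_r2) == d[2:3])) stop("threshold matrix must be N x I")
    thr <- array(rep(as.numeric(p_r2), each = d[1]), d)
  }
  out <- array(0L, d)
  cmp <- unclass(volume) > thr
  cmp[is.na(cmp)] <- FALSE
  out[cmp] <- 1L
  out
}

#' Clean a binary volume and keep the largest in-plane component
#'
#' 3 x 3 x 3 binary median, morphological closing with a 3 x 3 structuring
#' element per B-scan, hole filling, 8-connected labelling and selection of
#' the largest component per B-scan.
#'
#' @param bin 0/1 integer array.
#' @param se Structuring-element side length (default 3).
#' @return 0/1 integer array with attribute `empty_slices` listing B-scans
#'   where no component survived.
#' @export
refine_binary <- function(bin, se = 3L) {
  d <- dim(bin)
  out <- med3d_cpp(as.integer(bin), as.integer(d))
  dim(out) <- d
  empty <- integer(0)
  for (i in seq_len(d[3])) {
    sl <- closing2d_cpp(out[, , i], as.integer(se))
    sl <- clean_slice_cpp(sl)
    if (!any(sl == 1L)) empty <- c(empty, i)
    out[, , i] <- sl
  }
  attr(out, "empty_slices") <- empty
  out
}

#' Inner enamel boundary of one cleaned B-scan
#'
#' The raw inner boundary `L_inr(n)` is the first row below the component in
#' column `n` (exclusive convention: deepest component row + 1), defined on
#' the component's column span. `L_in(n)` is a least-squares cubic fit to the
#' defined `L_inr` values evaluated on the same span; with fewer than 4
#' defined columns the raw boundary is returned unchanged.
#'
#' @param L_W 0/1 integer array (output of [refine_binary()]) or a single
#'   M x N slice.
#' @param i B-scan index when `L_W` is 3-D.
#' @return List with `L_inr`, `L_in` (length-N vectors, `NA` off-span),
#'   `poly_coeffs` (intercept..cubic; `NA` on fallback) and `fallback` flag.
#' @export
extract_inner_boundary <- function(L_W, i = 1L) {
  sl <- if (length(dim(L_W)) == 3L) L_W[, , i] else L_W
  M <- nrow(sl); N <- ncol(sl)
  L_inr <- rep(NA_real_, N)
  for (n in seq_len(N)) {
    w <- which(sl[, n] == 1L)
    if (length(w)) L_inr[n] <- max(w) + 1
  }
  def <- which(!is.na(L_inr))
  if (!length(def)) stop("no component present in this B-scan")
  if (length(def) < 4L) {
    return(list(L_inr = L_inr, L_in = L_inr,
                poly_coeffs = rep(NA_real_, 4), fallback = TRUE))
  }
  x <- def
  fit <- stats::lm.fit(cbind(1, x, x^2, x^3), L_inr[def])
  co <- fit$coefficients
  L_in <- rep(NA_real_, N)
  span <- seq(min(def), max(def))
  L_in[span] <- co[1] + co[2] * span + co[3] * span^2 + co[4] * span^3
  list(L_inr = L_inr, L_in = L_in, poly_coeffs = unname(co), fallback = FALSE)
}

#' Outer enamel boundary of one B-scan
#'
#' The outer enamel boundary is the part of the object's upper boundary that
#' lies over the enamel component: `L_ef` restricted to the component's
#' contiguous column span, `NA` elsewhere.
#'
#' @param L_ef Length-N vector of upper-boundary rows for this B-scan.
#' @param span Integer vector of columns where the component is present.
#' @return Length-N vector `L_en`.
#' @export
extract_outer_boundary <- function(L_ef, span) {
  L_en <- rep(NA_real_, length(L_ef))
  if (length(span)) {
    keep <- seq(min(span), max(span))
    L_en[keep] <- L_ef[keep]
  }
  L_en
}

#' Segment the enamel layer on every B-scan of a volume
#'
#' Full boundary pipeline: 3-D median pre-filter, global Otsu surface
#' detection, per-A-scan thresholds, binarization at `p_r2` and at `p_r3`
#' (two parallel morphological cleanups), per-B-scan largest-component
#' extraction, disambiguation of columns where the two thresholded
#' boundaries disagree by more than `limit_shift_px` rows (replaced by the
#' running median of the 5 neighbouring columns), and cubic smoothing of the
#' inner boundary.
#'
#' @param volume An [oct_volume()].
#' @param config A [pipeline_config()]; supplies filter sizes and the
#'   disambiguation limit.
#' @param filtered Optional pre-computed median-filtered volume (used by
#'   [run_pipeline()] to avoid filtering twice).
#' @return An object of class `boundary_set`: matrices `L_ef`, `L_en`,
#'   `L_inr`, `L_in` (N x I), `poly_coeffs` (4 x I), `thresholds`
#'   (`p_r`, `p_r2`, `p_r3`), and bookkeeping (`empty_slices`,
#'   `fallback_slices`, `n_disambiguated`, `spacing`).
#' @export
segment_enamel <- function(volume, config = pipeline_config(), filtered = NULL) {
  filt <- filtered %||% median_filter_3d(volume, config$h1)
  d <- dim(volume)
  N <- d[2]; I <- d[3]
  pr <- otsu_threshold(unclass(filt))
  feats <- column_features_cpp(as.integer(filt), as.integer(d), pr)
  if (all(is.na(feats$L_ef)))
    stop("no object: no pixel above the Otsu threshold anywhere")
  B2 <- binarize_enamel(filt, feats$p_r2)
  B3 <- binarize_enamel(filt, feats$p_r3)
  W2 <- refine_binary(B2, config$se[1])
  W3 <- refine_binary(B3, config$se[1])
  L_ef <- feats$L_ef
  L_en <- matrix(NA_real_, N, I)
  L_inr <- matrix(NA_real_, N, I)
  L_in <- matrix(NA_real_, N, I)
  coeffs <- matrix(NA_real_, 4, I)
  fallback <- integer(0)
  n_disamb <- 0L
  empty <- attr(W2, "empty_slices")
  for (i in seq_len(I)) {
    if (i %in% empty) next
    b2 <- extract_inner_boundary(W2, i)
    # The working threshold lies between p_r2 and p_r3: the modal level p_r2
    # bisects the noisy dentine plateau, so the component binarized at p_r2
    # defines the object (span, outer boundary) but its bottom edge can leak
    # into dentine, while p_r3 — one standard deviation above the plateau —
    # marks where translucency actually ends. The inner boundary is taken
    # from the p_r3 route; columns where the two routes disagree by more
    # than the limit (the scale of the ambiguity, 70 px = 350 um at 5 um/px)
    # are flagged and clarified by the median of the 5 neighbouring columns.
    inr <- b2$L_inr
    if (!(i %in% attr(W3, "empty_slices"))) {
      b3 <- extract_inner_boundary(W3, i)
      def3 <- which(!is.na(b3$L_inr))
      use3 <- which(!is.na(inr) & !is.na(b3$L_inr))
      inr[use3] <- b3$L_inr[use3]
      bad <- use3[abs(b2$L_inr[use3] - b3$L_inr[use3]) > config$limit_shift_px]
      if (length(bad)) {
        n_disamb <- n_disamb + length(bad)
        for (n in bad) {
          nb <- intersect((n - 2):(n + 2), def3)
          inr[n] <- stats::median(b3$L_inr[nb])
        }
      }
    }
    def <- which(!is.na(inr))
    if (length(def) >= 4L) {
      x <- def
      fit <- stats::lm.fit(cbind(1, x, x^2, x^3), inr[def])
      co <- fit$coefficients
      span <- seq(min(def), max(def))
      L_in[span, i] <- co[1] + co[2] * span + co[3] * span^2 + co[4] * span^3
      coeffs[, i] <- unname(co)
    } else {
      L_in[, i] <- inr
      fallback <- c(fallback, i)
    }
    L_inr[, i] <- inr
    L_en[, i] <- extract_outer_boundary(L_ef[, i], def)
  }
  if (n_disamb > 0)
    message(sprintf("segment_enamel: %d column(s) disambiguated via the %d-px limit",
                    n_disamb, config$limit_shift_px))
  if (length(fallback))
    message(sprintf("segment_enamel: polynomial fallback on B-scan(s) %s",
                    paste(fallback, collapse = ", ")))
  structure(list(L_ef = L_ef, L_en = L_en, L_inr = L_inr, L_in = L_in,
                 poly_coeffs = coeffs,
                 thresholds = list(p_r = pr, p_r2 = feats$p_r2, p_r3 = feats$p_r3),
                 empty_slices = empty, fallback_slices = fallback,
                 n_disambiguated = n_disamb,
                 spacing = spacing_of(volume)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  d <- dim(x$L_ef)
  cat(sprintf("<boundary_set> %d columns x %d B-scans, p_r = %d\n",
              d[1], d[2], x$thresholds$p_r))
  cat(sprintf("  defined outer boundary: %d / %d columns\n",
              sum(!is.na(x$L_en)), length(x$L_en)))
  if (length(x$empty_slices))
    cat("  empty B-scans:", paste(x$empty_slices, collapse = ", "), "\n")
  invisible(x)
}

#' Export a boundary set as CSV
#'
#' Long format with columns `i, n, L_ef, L_en, L_inr, L_in`.
#'
#' @param bounds A `boundary_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(bounds, path) {
  d <- dim(bounds$L_ef)
  df <- data.frame(i = rep(seq_len(d[2]), each = d[1]),
                   n = rep(seq_len(d[1]), d[2]),
                   L_ef = as.vector(bounds$L_ef),
                   L_en = as.vector(bounds$L_en),
                   L_inr = as.vector(bounds$L_inr),
                   L_in = as.vector(bounds$L_in))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
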
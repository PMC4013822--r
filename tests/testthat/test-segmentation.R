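# Brute-force oracles, kept deliberately naive and independent of the
# compiled implementations they check.

oracle_median3d <- function(a) {
  d <- dim(a); out <- array(0L, d)
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (s in 1:d[3]) for (n in 1:d[2]) for (m in 1:d[1]) {
    nb <- a[cl((m - 1):(m + 1), 1, d[1]),
            cl((n - 1):(n + 1), 1, d[2]),
            cl((s - 1):(s + 1), 1, d[3])]
    out[m, n, s] <- sort(nb)[14]
  }
  out
}

oracle_otsu <- function(x) {
  x <- as.vector(x)
  sb2 <- rep(-Inf, 256)
  for (t in 0:255) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    sb2[t + 1] <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  ties <- which(sb2 >= max(sb2) - 1e-12)
  as.integer(round(mean(ties)) - 1L)  # midpoint of tied thresholds
}

test_that("3-D median filter matches the brute-force oracle", {
  expect_equal(unclass(median_filter_3d(oct_volume(array(7L, c(4, 4, 4))))),
               array(7L, c(4, 4, 4)), ignore_attr = TRUE)
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 255L
  expect_true(all(unclass(median_filter_3d(oct_volume(a))) == 0L))
  set.seed(31)
  for (rep in 1:3) {
    a <- array(sample(0:255, 7^3, replace = TRUE), c(7, 7, 7))
    expect_equal(unclass(median_filter_3d(oct_volume(a))), oracle_median3d(a),
                 ignore_attr = TRUE)
  }
  expect_error(median_filter_3d(oct_volume(array(0L, c(2, 5, 5)))), "smaller")
})

test_that("Otsu threshold equals exhaustive between-class-variance maximization", {
  x <- c(rep(0L, 50), rep(200L, 50))
  t0 <- otsu_threshold(x)            # midpoint of the empty gap between modes
  expect_gt(t0, 0); expect_lt(t0, 200)
  expect_identical(t0, oracle_otsu(x))
  set.seed(7)
  for (rep in 1:10) {
    x <- sample(0:255, 300, replace = TRUE, prob = runif(256)^3)
    expect_identical(otsu_threshold(x), oracle_otsu(x))
  }
  expect_identical(otsu_threshold(rep(37L, 10)), 37L)  # constant input
})

test_that("upper boundary detection finds the first supra-threshold row", {
  ph <- generate_volume(flat_phantom())
  ub <- detect_upper_boundary(median_filter_3d(ph$volume))
  expect_true(all(ub$L_ef == 100))
  dark <- oct_volume(array(5L, c(20, 8, 2)))
  expect_error(detect_upper_boundary(dark), "no object")
})

test_that("column histogram matches a direct tally and sums to M", {
  v <- oct_volume(array(100L, c(30, 4, 2)))
  h <- column_histogram(v, 2, 1)
  expect_identical(h[101], 30L); expect_identical(sum(h), 30L)
  set.seed(5)
  a <- array(sample(0:255, 40 * 3 * 2, replace = TRUE), c(40, 3, 2))
  v <- oct_volume(a)
  for (n in 1:3) for (i in 1:2) {
    h <- column_histogram(v, n, i)
    tally <- integer(256)
    for (m in 1:40) tally[a[m, n, i] + 1L] <- tally[a[m, n, i] + 1L] + 1L
    expect_identical(h, tally)
    expect_identical(sum(h), 40L)
  }
})

test_that("inner thresholds: histogram mode and plateau mean + sd", {
  # 600 px at 30, 200 px at 180 below the surface -> mode 30
  a <- array(0L, c(801, 1, 1))
  a[1, 1, 1] <- 200L                 # surface
  a[2:201, 1, 1] <- 180L
  a[202:801, 1, 1] <- 30L
  th <- inner_threshold(oct_volume(a), 1, 1, L_ef = 1)
  expect_equal(unname(th["p_r2"]), 30)
  # constant plateau -> p_r3 = plateau value (sd 0)
  b <- array(30L, c(100, 1, 1)); b[1:10] <- 200L
  th2 <- inner_threshold(oct_volume(b), 1, 1, L_ef = 1)
  expect_equal(unname(th2["p_r3"]), 30)
  # undefined surface propagates
  expect_true(all(is.na(inner_threshold(oct_volume(b), 1, 1, L_ef = NA))))
  # decaying part I + noisy plateau: p_r2 within 2 grey levels of the mode
  set.seed(11)
  col <- c(seq(220, 90, length.out = 150),
           60 + round(rnorm(400, 0, 2)))
  cc <- array(as.integer(pmax(pmin(round(col), 255), 0)), c(550, 1, 1))
  th3 <- inner_threshold(oct_volume(cc), 1, 1, L_ef = 1)
  expect_lte(abs(th3[["p_r2"]] - 60), 2)
  expect_gte(th3[["p_r3"]], th3[["p_r2"]])
})

test_that("batch threshold path agrees with the per-column reference", {
  set.seed(3)
  ph <- generate_volume(phantom_params(shape = c(340, 40, 4), seed = 3,
                                       speckle = list(strength = 0.15)))
  filt <- median_filter_3d(ph$volume)
  pr <- otsu_threshold(unclass(filt))
  feats <- enameloct:::column_features_cpp(as.integer(filt),
                                           as.integer(dim(filt)), pr)
  for (k in 1:25) {
    n <- sample(40, 1); i <- sample(4, 1)
    th <- inner_threshold(filt, n, i, feats$L_ef[n, i])
    if (is.na(feats$L_ef[n, i])) {
      expect_true(all(is.na(th)))
    } else {
      expect_equal(unname(th["p_r2"]), feats$p_r2[n, i])
      expect_equal(unname(th["p_r3"]), feats$p_r3[n, i])
    }
  }
})

test_that("binarization matches elementwise comparison", {
  set.seed(13)
  a <- array(sample(0:255, 20 * 6 * 3, replace = TRUE), c(20, 6, 3))
  v <- oct_volume(a)
  expect_true(all(binarize_enamel(v, 255) == 0))
  pos <- oct_volume(array(sample(1:255, 60, TRUE), c(10, 3, 2)))
  expect_true(all(binarize_enamel(pos, 0) == 1))
  thr <- matrix(sample(0:255, 18, TRUE), 6, 3)
  B <- binarize_enamel(v, thr)
  for (i in 1:3) for (n in 1:6)
    expect_identical(B[, n, i], as.integer(a[, n, i] > thr[n, i]))
})

test_that("refine_binary fills holes, removes specks, keeps the largest cluster", {
  mk <- function(sl) { a <- array(0L, c(dim(sl), 3)); for (i in 1:3) a[, , i] <- sl; a }
  sl <- matrix(0L, 40, 40); sl[10:30, 10:30] <- 1L; sl[20, 20] <- 0L
  out <- refine_binary(mk(sl))
  expect_identical(out[20, 20, 2], 1L)               # hole filled
  # rectangle preserved up to its four corner pixels (binary median)
  expect_gte(sum(out[, , 2]), 21L * 21L - 4L)
  expect_true(all(out[11:29, 11:29, 2] == 1L))
  # distant 2-px speck (noise clusters are no more than 2-3 pieces) removed
  sl2 <- sl; sl2[20, 20] <- 1L; sl2[38, 38] <- 1L; sl2[38, 39] <- 1L
  out2 <- refine_binary(mk(sl2))
  expect_identical(out2[38, 38, 2], 0L)
  # two components of 500 and 120 px: only the larger remains
  sl3 <- matrix(0L, 60, 40); sl3[5:24, 5:29] <- 1L; sl3[40:49, 5:16] <- 1L
  out3 <- refine_binary(mk(sl3))
  expect_true(all(out3[40:49, 5:16, 2] == 0L))
  expect_true(all(out3[6:23, 6:28, 2] == 1L))
  # idempotence
  expect_identical(refine_binary(out3), out3)
})

test_that("inner boundary extraction fits and falls back as specified", {
  # integer-valued polynomial edge: coefficients recovered to 1e-6 relative
  N <- 200
  edge_lin <- 520 - 2 * (1:N)
  sl0 <- matrix(0L, 600, N)
  for (n in 1:N) sl0[60:(edge_lin[n] - 1), n] <- 1L
  ib0 <- extract_inner_boundary(sl0)
  expect_equal(ib0$poly_coeffs, c(520, -2, 0, 0), tolerance = 1e-6)
  # rounded cubic edge: fitted curve stays within rounding of the generator
  co <- c(693.39, -3.21, 0.018, -0.0001)
  nn <- 1:120
  edge <- round(co[1] + co[2] * nn + co[3] * nn^2 + co[4] * nn^3)
  sl <- matrix(0L, 800, 120)
  for (n in nn) sl[100:(edge[n] - 1), n] <- 1L
  ib <- extract_inner_boundary(sl)
  expect_lt(max(abs(ib$L_in - edge), na.rm = TRUE), 1)
  expect_false(ib$fallback)
  # flat bottom edge: higher-order coefficients ~ 0
  sl2 <- matrix(0L, 500, 50); sl2[100:399, ] <- 1L
  ib2 <- extract_inner_boundary(sl2)
  expect_equal(ib2$L_in, rep(400, 50), tolerance = 1e-9)
  expect_lt(max(abs(ib2$poly_coeffs[2:4])), 1e-6)
  # cubic + uniform +/-3 px jitter: fit within 3 px of the generating cubic
  set.seed(21)
  true_edge <- round(420 - 0.5 * (1:N) + 0.004 * (1:N)^2 - 6e-6 * (1:N)^3)
  jit <- true_edge + sample(-3:3, N, replace = TRUE)
  sl3 <- matrix(0L, 600, N)
  for (n in 1:N) sl3[50:(jit[n] - 1), n] <- 1L
  ib3 <- extract_inner_boundary(sl3)
  expect_lte(max(abs(ib3$L_in - true_edge), na.rm = TRUE), 3)
  # fewer than 4 defined columns: raw fallback
  sl4 <- matrix(0L, 60, 10); sl4[10:20, 4:6] <- 1L
  ib4 <- extract_inner_boundary(sl4)
  expect_true(ib4$fallback)
  expect_identical(ib4$L_in, ib4$L_inr)
})

test_that("outer boundary restriction follows the component span", {
  L_ef <- c(rep(NA, 5), rep(50, 400), rep(NA, 7))
  full <- extract_outer_boundary(L_ef, span = 1:412)
  expect_identical(full, as.numeric(L_ef))
  part <- extract_outer_boundary(L_ef, span = 50:300)
  expect_true(all(is.na(part[c(1:49, 301:412)])))
  expect_true(all(part[50:300] == 50))
})

test_that("segment_enamel recovers a noise-free phantom exactly", {
  ph <- generate_volume(flat_phantom())
  b <- segment_enamel(ph$volume)
  expect_true(all(b$L_ef == ph$truth$outer_boundary))
  expect_true(all(b$L_en == ph$truth$outer_boundary))
  expect_true(all(b$L_inr == ph$truth$inner_boundary))
  expect_lt(max(abs(b$L_in - ph$truth$inner_boundary)), 1e-6)
  expect_true(all(b$L_ef <= b$L_inr, na.rm = TRUE))
  expect_error(segment_enamel(oct_volume(array(3L, c(20, 10, 3)))), "no object")
})

test_that("segmented thickness stays within 15% of truth under speckle", {
  ph <- generate_volume(phantom_params(shape = c(360, 96, 6), seed = 8,
                                       speckle = list(strength = 0.15)))
  b <- suppressMessages(segment_enamel(ph$volume))
  expect_true(all(b$L_ef <= b$L_inr + 1e-9, na.rm = TRUE))
  tm <- thickness_map(b)
  dd <- measurement_error(tm$values, truth_thickness_or_na(ph$truth))
  expect_lte(dd, 15)
  # the upper boundary is the easy part: mean error within 2 rows
  expect_lte(mean(abs(b$L_ef - ph$truth$outer_boundary), na.rm = TRUE), 2)
})

test_that("cubic fit residual never exceeds the best constant fit residual", {
  set.seed(17)
  for (rep in 1:5) {
    N <- 80
    edge <- round(200 + cumsum(rnorm(N, 0, 2)))
    sl <- matrix(0L, 400, N)
    for (n in 1:N) sl[50:(edge[n] - 1), n] <- 1L
    ib <- extract_inner_boundary(sl)
    rms_fit <- sqrt(mean((ib$L_in - ib$L_inr)^2, na.rm = TRUE))
    rms_const <- sqrt(mean((mean(ib$L_inr, na.rm = TRUE) - ib$L_inr)^2,
                           na.rm = TRUE))
    expect_lte(rms_fit, rms_const + 1e-9)
  }
})
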
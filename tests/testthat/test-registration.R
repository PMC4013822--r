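proj_of <- function(vol) normalized_projection(median_filter_3d(vol))

test_that("projection normalization spans [0,1] and handles constants", {
  ph <- generate_volume(reg_phantom())
  pr <- normalized_projection(ph$volume)
  expect_equal(min(pr), 0); expect_equal(max(pr), 1)
  expect_warning(z <- normalized_projection(oct_volume(array(9L, c(5, 6, 7)))),
                 "constant")
  expect_true(all(z == 0))
  # brute-force sum + rescale oracle
  set.seed(2)
  a <- array(sample(0:255, 10 * 4 * 3, TRUE), c(10, 4, 3))
  pr2 <- normalized_projection(oct_volume(a))
  sums <- matrix(0, 4, 3)
  for (n in 1:4) for (i in 1:3) sums[n, i] <- sum(a[, n, i])
  expect_equal(unclass(pr2), (sums - min(sums)) / (max(sums) - min(sums)),
               ignore_attr = TRUE)
})

test_that("match criterion equals a brute-force pixel loop", {
  set.seed(4)
  ref <- matrix(runif(64), 8, 8)
  mov <- matrix(runif(64), 8, 8)
  for (dn in -3:3) for (di in -3:3) {
    s <- 0
    for (n in 1:8) for (i in 1:8) {
      nn <- n + dn; ii <- i + di
      v <- if (nn >= 1 && nn <= 8 && ii >= 1 && ii <= 8) mov[nn, ii] else 0
      s <- s + abs(ref[n, i] - v)
    }
    expect_equal(match_criterion(ref, mov, dn, di, 0), s / 64)
  }
  expect_equal(match_criterion(ref, ref, 0, 0, 0), 0)
  expect_equal(match_criterion(matrix(0, 5, 5), matrix(1, 5, 5), 0, 0, 0), 1)
  expect_error(match_criterion(ref, mov, 41, 0, 0), "<= 40")
  expect_error(match_criterion(ref, matrix(0, 4, 4), 0, 0, 0), "equal shape")
})

test_that("the J surface agrees with match_criterion everywhere", {
  set.seed(9)
  ref <- matrix(runif(12 * 10), 12, 10)
  mov <- matrix(runif(12 * 10), 12, 10)
  cfg <- pipeline_config(shift_range = 4)
  r <- register_projection(ref, mov, cfg)
  for (dz in cfg$zoom_levels) for (dn in c(-4, -1, 0, 2, 4)) for (di in c(-3, 0, 4)) {
    expect_equal(r$J_surface[as.character(dn), as.character(di), as.character(dz)],
                 match_criterion(ref, mov, dn, di, dz, limit = 4))
  }
  expect_equal(r$J, min(r$J_surface))
})

test_that("self-registration is the identity with J = 0", {
  pr <- proj_of(generate_volume(reg_phantom())$volume)
  r <- register_projection(pr, pr, pipeline_config(shift_range = 10))
  expect_identical(c(r$dn, r$di), c(0L, 0L))
  expect_identical(r$dz, 0)
  expect_equal(r$J, 0)
})

test_that("planted shift (9, 4) and planted zooms are recovered exactly", {
  p <- reg_phantom()
  ser <- generate_stage_series(p, c(0, 0, 0),
                               list(c(0, 0, 0), c(9, 4, 0), c(0, 0, 10)))
  pref <- proj_of(ser[[1]]$volume)
  r_shift <- register_projection(pref, proj_of(ser[[2]]$volume))
  expect_identical(c(r_shift$dn, r_shift$di), c(9L, 4L))
  expect_identical(r_shift$dz, 0)
  r_zoom <- register_projection(pref, proj_of(ser[[3]]$volume))
  expect_identical(c(r_zoom$dn, r_zoom$di), c(0L, 0L))
  expect_identical(r_zoom$dz, 10)
  # internal consistency: reported optimum is the surface minimum
  expect_equal(r_zoom$J, min(r_zoom$J_surface))
})

test_that("apply_transform resamples maps onto the reference grid", {
  vals <- matrix(runif(30 * 20, 50, 90), 30, 20)
  tm <- structure(list(values = vals, unit = "um", stage_label = "b",
                       spacing_axial = 5), class = "thickness_map")
  ident <- structure(list(dn = 0L, di = 0L, dz = 0, J = 0),
                     class = "registration_result")
  expect_identical(apply_transform(tm, ident)$values, vals)
  shift <- structure(list(dn = 5L, di = -3L, dz = 0, J = 0),
                     class = "registration_result")
  out <- apply_transform(tm, shift)$values
  # interior agrees with a direct index shift; borders go undefined
  expect_equal(out[1:25, 4:20], vals[6:30, 1:17])
  expect_true(all(is.na(out[26:30, ])))
  expect_true(all(is.na(out[, 1:3])))
})

test_that("aligned phantom maps agree with the reference ground truth", {
  # smooth-surface phantom with constant in-footprint thickness: the aligned
  # stage map must land on the reference stage's ground-truth grid
  p <- stage_phantom_params()
  ser <- generate_stage_series(p, c(0, 0), list(c(0, 0, 0), c(5, -4, 0)))
  pref <- proj_of(ser[[1]]$volume)
  pmov <- proj_of(ser[[2]]$volume)
  r <- register_projection(pref, pmov)
  expect_identical(c(r$dn, r$di, r$dz), c(5L, -4L, 0))
  b <- suppressMessages(segment_enamel(ser[[2]]$volume))
  aligned <- apply_transform(thickness_map(b), r)
  truth_ref <- truth_thickness_or_na(ser[[1]]$truth)
  common <- !is.na(aligned$values) & !is.na(truth_ref)
  expect_gt(mean(common), 0.1)
  expect_lte(stats::quantile(abs(aligned$values - truth_ref)[common], 0.9), 1)
})
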
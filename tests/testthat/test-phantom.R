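test_that("noise-free phantom construction matches its own ground truth", {
  ph <- generate_volume(flat_phantom())
  vol <- unclass(ph$volume)
  pr <- otsu_threshold(vol)
  expect_gt(pr, 10); expect_lt(pr, 200)
  # first row above the Otsu threshold is the planted surface, every column
  first_above <- apply(vol > pr, c(2, 3), function(x) which(x)[1])
  expect_true(all(first_above == 100))
  expect_true(all(ph$truth$outer_boundary == 100))
  expect_true(all(ph$truth$inner_boundary == 170))
  expect_true(all(ph$truth$thickness_px == 70))
})

test_that("phantom generation is deterministic for a fixed seed", {
  p <- phantom_params(shape = c(60, 24, 3), seed = 42,
                      speckle = list(model = "rayleigh", strength = 0.2))
  a <- generate_volume(p)
  b <- generate_volume(p)
  expect_identical(unclass(a$volume), unclass(b$volume))
  p2 <- p; p2$seed <- 43L
  expect_false(identical(unclass(generate_volume(p2)$volume), unclass(a$volume)))
})

test_that("speckled volume is the noise-free volume at the planted boundaries", {
  p_noisy <- phantom_params(shape = c(120, 32, 4), seed = 9,
                            speckle = list(model = "rayleigh", strength = 0.3))
  p_clean <- p_noisy; p_clean$speckle$strength <- 0
  noisy <- generate_volume(p_noisy)
  clean <- generate_volume(p_clean)
  # identical geometry: same ground truth, and the underlying intensity step
  # locations agree exactly by construction
  expect_identical(noisy$truth, clean$truth)
  tr <- clean$truth
  for (i in seq_len(dim(clean$volume)[3])) {
    for (n in c(1, 16, 32)) {
      if (is.na(tr$outer_boundary[n, i])) next
      f <- tr$outer_boundary[n, i]; g <- tr$thickness_px[n, i]
      col <- unclass(clean$volume)[, n, i]
      expect_gt(col[f], col[f - 1])            # background -> enamel step
      expect_gt(col[f + g - 1], col[f + g])    # enamel -> dentine step
    }
  }
})

test_that("ground truth respects its invariants", {
  ph <- generate_volume(phantom_params(shape = c(340, 64, 12), seed = 2))
  tr <- ph$truth
  expect_true(all(tr$thickness_px >= 0))
  expect_identical(tr$tooth_mask, tr$thickness_px > 0)
  ok <- tr$tooth_mask
  expect_true(all((tr$inner_boundary - tr$outer_boundary)[ok] ==
                    tr$thickness_px[ok]))
})

test_that("parameter validation rejects bad level orderings and shapes", {
  expect_error(phantom_params(levels = list(background = 90, enamel = 200,
                                            dentine = 80)), "dentine > background")
  expect_error(phantom_params(levels = list(background = 10, enamel = 70,
                                            dentine = 80)), "enamel > dentine")
  expect_error(phantom_params(shape = c(10, 0, 3)), "positive")
  expect_error(generate_volume(flat_phantom(shape = c(100, 16, 2),
                                            surface = 80, thick = 40)),
               "within")
})

test_that("stage deltas convert to pixels and transforms are recorded", {
  p <- flat_phantom(shape = c(300, 32, 3))
  ser <- generate_stage_series(p, stage_deltas = c(0, -80),
                               stage_transforms = list(c(0, 0, 0), c(9, 4, 0)))
  # -80 um at 5 um/px = -16 px everywhere
  expect_true(all(ser[[2]]$truth$thickness_px[ser[[2]]$truth$tooth_mask] == 54))
  expect_equal(unname(ser[[2]]$truth$applied_transform), c(9, 4, 0))
  expect_equal(unname(ser[[1]]$truth$applied_transform), c(0, 0, 0))
  expect_identical(ser[[1]]$stage_label, "a")
})

test_that("stage series validates ranges and the identity first stage", {
  p <- flat_phantom(shape = c(120, 16, 2), surface = 30, thick = 20)
  expect_error(generate_stage_series(p, c(5, 0)), "zero thickness delta")
  expect_error(generate_stage_series(p, c(0, 0),
                                     list(c(1, 0, 0), c(0, 0, 0))), "identity")
  expect_error(generate_stage_series(p, c(0, 0),
                                     list(c(0, 0, 0), c(41, 0, 0))), "<= 40")
  expect_error(generate_stage_series(p, c(0, 0),
                                     list(c(0, 0, 0), c(0, 0, 30))), "<= 20")
})

test_that("thicker enamel never yields thinner recovered thickness (noise-free)", {
  base <- flat_phantom(shape = c(320, 48, 3), thick = 60)
  thicker <- flat_phantom(shape = c(320, 48, 3), thick = 85)
  t1 <- thickness_map(segment_enamel(generate_volume(base)$volume))
  t2 <- thickness_map(segment_enamel(generate_volume(thicker)$volume))
  expect_true(all(t2$values - t1$values >= 0))
})
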
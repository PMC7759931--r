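# Phantom generation, discretization, resampling and whole-lesion
# extraction.

test_that("discretization maps edges and interior values as specified", {
  spec <- discretization_spec(128, -400, 400)
  vol <- array(c(-400, 400, 0, -1000, 1000, 3.2, 396.9, -396.9),
               c(8, 1, 1))
  mask <- array(TRUE, c(8, 1, 1))
  lab <- discretize(vol, mask, spec)
  expect_equal(lab[1, 1, 1], 1L)     # lower edge
  expect_equal(lab[2, 1, 1], 128L)   # upper edge maps into the top bin
  expect_equal(lab[3, 1, 1], 65L)    # floor(400/6.25) + 1
  expect_equal(lab[4, 1, 1], 1L)     # below range clips
  expect_equal(lab[5, 1, 1], 128L)   # above range clips
  expect_equal(lab[7, 1, 1], 128L)
  expect_equal(lab[8, 1, 1], 1L)
  expect_error(discretization_spec(1, -400, 400))
  expect_error(discretization_spec(128, 400, -400))
})

test_that("phantom textures: constant fill, checker lattice, seeded noise", {
  ph <- generate_lesion_phantom(c(6, 6, 6), texture = list(
    type = "constant", value = 50), mask_radius = 2.5)
  expect_true(all(ph$volume[ph$mask] == 50))
  expect_true(any(ph$mask))

  ck <- generate_lesion_phantom(c(4, 4, 1), texture = list(
    type = "checker", period = 1, low = 0, high = 100))
  expect_equal(ck$volume[1, 1, 1], 0)
  expect_equal(ck$volume[2, 1, 1], 100)
  expect_equal(ck$volume[2, 2, 1], 0)
  expect_true(all(ck$volume %in% c(0, 100)))

  n1 <- generate_lesion_phantom(c(8, 8, 8), texture = list(
    type = "noise", sd = 30, corr_length = 3), seed = 99)
  n2 <- generate_lesion_phantom(c(8, 8, 8), texture = list(
    type = "noise", sd = 30, corr_length = 3), seed = 99)
  expect_identical(n1$volume, n2$volume)
  expect_true(all(n1$volume >= -1000 & n1$volume <= 1000))

  expect_error(generate_lesion_phantom(c(6, 6, 6), mask_radius = 0.01),
               "empty mask")
})

test_that("smoothed noise is spatially correlated", {
  ph <- generate_lesion_phantom(c(20, 20, 20), texture = list(
    type = "noise", sd = 1, corr_length = 2), seed = 5)
  v <- ph$volume
  lag1 <- cor(as.vector(v[-20, , ]), as.vector(v[-1, , ]))
  expect_gt(lag1, 0.5)
})

test_that("resampling is the identity for 1 mm input and preserves extent", {
  ph <- generate_lesion_phantom(c(6, 6, 6), mask_radius = 2.5)
  rs <- resample_isotropic(ph$volume, ph$mask, c(1, 1, 1))
  expect_equal(rs$volume, ph$volume)
  expect_equal(rs$mask, ph$mask > 0)

  # 2 mm constant volume: constant output with the same physical extent
  vol <- array(7, c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  rs2 <- resample_isotropic(vol, mask, c(2, 2, 2))
  expect_equal(dim(rs2$volume), c(10L, 10L, 10L))
  expect_true(all(abs(rs2$volume - 7) < 1e-12))
})

test_that("resampled sphere mask volume approximates the analytic volume", {
  # sphere r = 10 mm on a (1, 1, 5) mm grid
  shape <- c(31, 31, 7)
  spacing <- c(1, 1, 5)
  ctr <- shape * spacing / 2
  x <- (slice.index(array(0, shape), 1) - 0.5) * spacing[1]
  y <- (slice.index(array(0, shape), 2) - 0.5) * spacing[2]
  z <- (slice.index(array(0, shape), 3) - 0.5) * spacing[3]
  mask <- (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= 100
  vol <- array(0, shape)
  rs <- resample_isotropic(vol, mask, spacing, 1)
  v_mm3 <- sum(rs$mask)
  expect_lt(abs(v_mm3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
})

test_that("histogram features match closed forms", {
  vol <- array(50, c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  f <- histogram_shape_features(vol, mask)
  expect_equal(unname(f["StdDev"]), 0)
  expect_equal(unname(f["Entropy_h"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  expect_equal(unname(f["Volume"]), 1)  # 1000 voxels at 1 mm = 1 mL

  # two equal-count levels
  vol2 <- array(rep(c(-100, 100), 500), c(10, 10, 10))
  f2 <- histogram_shape_features(vol2, mask)
  expect_equal(unname(f2["Uniformity"]), 0.5)
  expect_equal(unname(f2["Entropy_h"]), log(2))

  # sphericity of a cube of side s: pi^(1/3) (6 s^3)^(2/3) / (6 s^2)
  s <- 10
  expect_equal(unname(f["Sphericity"]),
               pi^(1 / 3) * (6 * s^3)^(2 / 3) / (6 * s^2))
  expect_error(histogram_shape_features(vol, array(FALSE, c(10, 10, 10))))
})

test_that("extract_all yields the full set and enforces the 1 cm^3 rule", {
  ph <- generate_lesion_phantom(c(16, 16, 16), texture = list(
    type = "noise", mean = 40, sd = 50, corr_length = 2),
    mask_radius = 7, seed = 2)
  fv <- extract_all(ph$volume, ph$mask, ph$spacing)
  expect_true(all(radiomic_feature_names() %in% names(fv)))
  expect_true(all(is.finite(fv[radiomic_feature_names()])))
  expect_equal(sum(!attr(fv, "in_default_set")), 2)  # Min, Max extra

  fv2 <- extract_all(ph$volume, ph$mask, ph$spacing)
  expect_identical(fv, fv2)

  small <- generate_lesion_phantom(c(8, 8, 8), mask_radius = 3)
  expect_error(extract_all(small$volume, small$mask, small$spacing),
               "1 cm")
  fv3 <- extract_all(small$volume, small$mask, small$spacing,
                     extraction_config(override_min_volume = TRUE))
  expect_true(is.numeric(fv3["Mean"]))

  const <- generate_lesion_phantom(c(16, 16, 16), mask_radius = 7)
  fc <- extract_all(const$volume, const$mask, const$spacing)
  expect_equal(unname(fc["StdDev"]), 0)
  expect_equal(unname(fc["Contrast"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("feature maps: constant StdDev map is zero; Mean maps average; windows equal cropped extraction", {
  ph <- generate_lesion_phantom(c(6, 6, 6), texture = list(
    type = "constant", value = 30))
  m <- feature_map(ph$volume, ph$mask, ph$spacing, "StdDev")
  expect_true(all(m[ph$mask] == 0))
  mm <- feature_map(ph$volume, ph$mask, ph$spacing, "Mean")
  expect_true(all(abs(mm[ph$mask] - 30) < 1e-12))

  ph2 <- generate_lesion_phantom(c(6, 6, 6), texture = list(
    type = "noise", mean = 0, sd = 40, corr_length = 1), seed = 4)
  map2 <- feature_map(ph2$volume, ph2$mask, ph2$spacing, "Contrast")
  # interior voxel: value equals extraction on the cropped window
  win <- ph2$volume[2:4, 2:4, 2:4]
  lab <- discretize(win, array(TRUE, c(3, 3, 3)), discretization_spec())
  expect_equal(map2[3, 3, 3], unname(glcm_features(lab)["Contrast"]))
  expect_error(feature_map(ph2$volume, ph2$mask, ph2$spacing, "Volume"),
               "not mappable")
})

test_that("largest-lesion selection follows the max-at-any-timepoint rule", {
  lv <- data.frame(
    lesion_id = c("A", "A", "B", "B"),
    visit = c(1, 2, 1, 2),
    volume = c(45, 20, 20, 20))
  expect_equal(select_largest_lesion(lv), "A")
  expect_equal(select_largest_lesion(lv[lv$lesion_id == "B", ]), "B")
  # exact tie at different visits: earlier attainment wins
  tie <- data.frame(lesion_id = c("A", "B"), visit = c(2, 1),
                    volume = c(30, 30))
  expect_equal(select_largest_lesion(tie), "B")
  expect_error(select_largest_lesion(lv[0, ]))
})
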
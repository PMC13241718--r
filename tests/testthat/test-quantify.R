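geo1 <- voxel_geometry(1, 1, 8)

test_that("dsc matches its definition and the brute-force oracle", {
  m <- disc_mask(16, 7, 7, 4)
  expect_equal(dsc(m, m), 1)
  expect_equal(dsc(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(dsc(matrix(0, 4, 4), matrix(1, 4, 4)), 0)
  a <- matrix(0, 20, 20); a[1:10, 1:10] <- 1    # 100 px
  b <- matrix(0, 20, 20); b[6:15, 1:10] <- 1    # 100 px, overlap 50
  expect_equal(dsc(a, b), 0.5)
  set.seed(9)
  for (k in 1:25) {
    x <- random_mask(32, p = runif(1, 0.1, 0.6), seed = k)
    y <- random_mask(32, p = runif(1, 0.1, 0.6), seed = k + 100)
    expect_identical(dsc(x, y), oracle_dsc(x, y))
    expect_identical(dsc(x, y), dsc(y, x))
  }
})

test_that("hausdorff distance matches geometry and the all-pairs oracle", {
  m <- disc_mask(16, 7, 7, 4)
  expect_equal(hausdorff_mm(m, m, geo1), 0)
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(hausdorff_mm(a, b, geo1), 5)    # 3-4-5 triangle
  # anisotropic spacing
  expect_equal(hausdorff_mm(a, b, voxel_geometry(2, 1, 8)), sqrt(36 + 16))
  expect_true(is.na(hausdorff_mm(matrix(0, 4, 4), m[1:4, 1:4], geo1)))
  set.seed(10)
  for (k in 1:15) {
    x <- random_mask(14, 0.3, seed = k); y <- random_mask(14, 0.3, seed = k + 50)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(hausdorff_mm(x, y, voxel_geometry(1.5, 1.5, 8)),
                 oracle_hausdorff(x, y, 1.5, 1.5), tolerance = 1e-12)
    expect_equal(hausdorff_mm(x, y, geo1), hausdorff_mm(y, x, geo1))
  }
})

test_that("hausdorff satisfies the triangle inequality", {
  set.seed(12)
  x <- disc_mask(20, 9, 9, 5); y <- disc_mask(20, 5, 12, 4); z <- random_mask(20, 0.2, 3)
  dxy <- hausdorff_mm(x, y, geo1); dyz <- hausdorff_mm(y, z, geo1)
  dxz <- hausdorff_mm(x, z, geo1)
  expect_lte(dxz, dxy + dyz + 1e-12)
})

test_that("scar mass follows voxel geometry and tissue density", {
  expect_equal(scar_mass(matrix(0, 8, 8), geo1), 0)
  m1000 <- matrix(0, 40, 40); m1000[seq_len(1000)] <- 1
  expect_equal(scar_mass(m1000, voxel_geometry(1.5, 1.5, 8)), 18.9)
  # linear in pixel count, invariant to translation
  a <- matrix(0, 30, 30); a[1:5, 1:5] <- 1
  b <- matrix(0, 30, 30); b[20:24, 20:24] <- 1
  expect_equal(scar_mass(a, geo1), scar_mass(b, geo1))
  expect_equal(scar_mass((a + b > 0) * 1, geo1), 2 * scar_mass(a, geo1))
})

test_that("phantom wedge mass agrees with the analytic geometry formula", {
  set.seed(77)
  for (k in 1:5) {
    spec <- quiet_spec(grid_size = 128, r_endo_mm = runif(1, 12, 18),
                       r_epi_mm = runif(1, 32, 44),
                       scar_extent_deg = runif(1, 60, 240),
                       scar_transmurality = runif(1, 0.5, 1))
    sl <- generate_slice(spec)
    analytic_g <- analytic_scar_area_mm2(spec) * spec$slice_thickness_mm * 1.05 / 1000
    expect_lt(abs(scar_mass(sl$scar_mask, sl$geometry) - analytic_g) / analytic_g,
              0.02)
  }
})

test_that("mass error reports grams and percent of LV mass", {
  expect_equal(mass_error(10, 10, 100), list(error_g = 0, error_pct_lv = 0))
  expect_equal(mass_error(12, 10, 100), list(error_g = 2, error_pct_lv = 2))
  expect_true(is.na(mass_error(12, 10, 0)$error_pct_lv))
  set.seed(14)
  for (k in 1:10) {
    v <- runif(3, 1, 100)
    e <- mass_error(v[1], v[2], v[3])
    expect_equal(e$error_g, abs(v[1] - v[2]))
    expect_equal(e$error_pct_lv, 100 * abs(v[1] - v[2]) / v[3])
  }
})

test_that("fwhm recovers the true scar exactly on a two-level phantom", {
  sl <- generate_slice(quiet_spec(intensity_myo = 100, intensity_scar = 300))
  roi <- sl$scar_mask * 0
  core <- which(sl$scar_mask == 1, arr.ind = TRUE)
  roi[core[1:5, ]] <- 1
  out <- fwhm_segment(sl$image, sl$myo_mask, roi)
  expect_equal(dsc(out, sl$scar_mask), 1)
  # threshold is relative: positive rescaling leaves the output unchanged
  out2 <- fwhm_segment(sl$image * 3.7, sl$myo_mask, roi)
  expect_identical(out2, out)
  # the baseline-referenced variant is additionally offset-invariant
  out3 <- fwhm_segment(sl$image * 2 + 50, sl$myo_mask, roi, baseline = "myo_min")
  out4 <- fwhm_segment(sl$image, sl$myo_mask, roi, baseline = "myo_min")
  expect_identical(out3, out4)
})

test_that("fwhm edge cases: lone peak, exclusion zones, validation", {
  img <- matrix(10, 16, 16)
  myo <- matrix(1, 16, 16)
  img[8, 8] <- 100                       # everything else below half-peak
  roi <- matrix(0, 16, 16); roi[8, 8] <- 1
  out <- fwhm_segment(img, myo, roi)
  expect_equal(sum(out), 1)
  expect_equal(out[8, 8], 1)

  sl <- generate_slice(quiet_spec(intensity_myo = 100, intensity_scar = 300,
                                  scar_extent_deg = 90))
  roi2 <- sl$scar_mask * 0
  core <- which(sl$scar_mask == 1, arr.ind = TRUE)
  roi2[core[1:5, ]] <- 1
  # exclusion covering half the scar wedge halves the output
  full <- fwhm_segment(sl$image, sl$myo_mask, roi2)
  excl <- generate_slice(quiet_spec(intensity_myo = 100, intensity_scar = 300,
                                    scar_extent_deg = 45))$scar_mask
  part <- fwhm_segment(sl$image, sl$myo_mask, roi2, exclusion = excl)
  expect_equal(sum(part), sum(full) - sum(excl * full))

  expect_error(fwhm_segment(img, myo, matrix(0, 16, 16)), "empty")
  bad_roi <- matrix(0, 16, 16); bad_roi[1, 1] <- 1
  myo2 <- myo; myo2[1, 1] <- 0
  expect_error(fwhm_segment(img, myo2, bad_roi), "myocardium")
})

test_that("quantify_slice bundles the per-slice metrics", {
  sl <- generate_slice(quiet_spec())
  q <- quantify_slice(sl$scar_mask, sl$scar_mask, sl$geometry,
                      lv_mass = scar_mass(sl$myo_mask, sl$geometry))
  expect_equal(q$dsc, 1)
  expect_equal(q$hd_mm, 0)
  expect_equal(q$mass_error_g, 0)
  expect_equal(q$mass_error_pct_lv, 0)
})
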
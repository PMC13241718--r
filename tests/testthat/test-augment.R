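identity_plan <- function() {
  structure(list(flip_h = FALSE, flip_v = FALSE, rot_deg = 0, scale = 1,
                 shear_deg = 0, elastic = NULL, bias_coeffs = NULL,
                 noise_sd = 0, noise_seed = 1, blur_sigma = 0,
                 motion_len_px = 0, motion_deg = 0, gamma_log = 0,
                 clahe = FALSE, clahe_nx = 8, clahe_limit = 2),
            class = "transform_plan")
}

test_that("an all-off configuration samples the identity pipeline", {
  cfg <- augment_config(p_clahe = 1, p_flip = 0, p_gamma = 0, p_other = 0)
  plan <- sample_transform(cfg, seed = 1)
  expect_true(plan$clahe)
  expect_equal(plan$rot_deg, 0); expect_equal(plan$scale, 1)
  expect_null(plan$elastic); expect_null(plan$bias_coeffs)

  img <- matrix(runif(64 * 64), 64, 64)
  msk <- list(scar = disc_mask(64, 31, 31, 10))
  sp <- apply_spatial(img, msk, identity_plan(), voxel_geometry(1, 1, 8))
  expect_identical(sp$image, img)
  expect_identical(sp$masks$scar, msk$scar)
  expect_identical(apply_intensity(img, identity_plan()), img)
})

test_that("sampled plans are reproducible and inclusion rates match probabilities", {
  cfg <- augment_config()
  p1 <- sample_transform(cfg, seed = 42)
  p2 <- sample_transform(cfg, seed = 42)
  expect_identical(p1, p2)
  n_draw <- 10000
  inc_elastic <- 0; inc_gamma <- 0; inc_fliph <- 0
  for (s in seq_len(n_draw)) {
    pl <- sample_transform(cfg, seed = s)
    if (!is.null(pl$elastic)) inc_elastic <- inc_elastic + 1
    if (pl$gamma_log != 0) inc_gamma <- inc_gamma + 1
    if (pl$flip_h) inc_fliph <- inc_fliph + 1
  }
  se3 <- function(p) 3 * sqrt(p * (1 - p) / n_draw)
  expect_lt(abs(inc_elastic / n_draw - 0.3), se3(0.3))
  expect_lt(abs(inc_gamma / n_draw - 0.5), se3(0.5) + 0.01) # P(gamma drawn exactly 0) negligible
  expect_lt(abs(inc_fliph / n_draw - 0.5), se3(0.5))
})

test_that("magnitudes respect their configured ranges", {
  cfg <- augment_config(p_other = 1, p_gamma = 1)
  for (s in 1:200) {
    pl <- sample_transform(cfg, seed = s)
    expect_lte(abs(pl$rot_deg), 15)
    expect_gte(pl$scale, 0.9); expect_lte(pl$scale, 1.1)
    expect_lte(abs(pl$shear_deg), 8)
    expect_lte(max(abs(pl$elastic$disp_mm)), 7.5)
    expect_equal(dim(pl$elastic$disp_mm), c(7, 7, 2))
    expect_lte(max(abs(pl$bias_coeffs)), 0.5)
    expect_gte(pl$noise_sd, 0); expect_lte(pl$noise_sd, 0.1)
    expect_lte(abs(pl$gamma_log), 0.3)
  }
})

test_that("a pure rotation preserves the area of a centered disc", {
  plan <- identity_plan(); plan$rot_deg <- 10
  msk <- disc_mask(64, 31.5, 31.5, 20)
  sp <- apply_spatial(matrix(0, 64, 64), list(m = msk), plan, voxel_geometry(1, 1, 8))
  expect_true(all(sp$masks$m %in% c(0, 1)))
  expect_lt(abs(sum(sp$masks$m) - sum(msk)) / sum(msk), 0.02)
})

test_that("joint warps preserve binarity and scar-in-myocardium containment", {
  sl <- generate_slice(phantom_spec(grid_size = 64))
  cfg <- augment_config(p_other = 1, p_flip = 1, p_gamma = 1)
  for (s in 1:10) {
    plan <- sample_transform(cfg, seed = s)
    out <- apply_augmentation(sl, plan)
    expect_true(all(out$scar_mask %in% c(0, 1)))
    expect_true(all(out$myo_mask %in% c(0, 1)))
    expect_true(all(out$scar_mask <= out$myo_mask))
  }
})

test_that("additive noise has the configured standard deviation", {
  plan <- identity_plan(); plan$noise_sd <- 0.1
  devs <- vapply(1:30, function(s) {
    plan$noise_seed <- s
    out <- apply_intensity(matrix(5, 64, 64), plan)
    sd(out - 5)
  }, numeric(1))
  se <- 0.1 / sqrt(2 * 64 * 64)
  expect_lt(abs(mean(devs) - 0.1), 3 * se / sqrt(30))
})

test_that("gamma and its inverse cancel on the rescaled copy", {
  img <- matrix(runif(32 * 32), 32, 32)
  plan <- identity_plan(); plan$gamma_log <- 0.25
  inv <- identity_plan(); inv$gamma_log <- -0.25
  out <- apply_intensity(apply_intensity(img, plan), inv)
  expect_lt(max(abs(out - img)), 1e-6)
})

test_that("clahe increases local contrast without leaving the intensity range", {
  sl <- generate_slice(phantom_spec(grid_size = 64))
  plan <- identity_plan(); plan$clahe <- TRUE
  out <- apply_intensity(sl$image, plan)
  expect_equal(dim(out), dim(sl$image))
  expect_gte(min(out), min(sl$image) - 1e-8)
  expect_lte(max(out), max(sl$image) + 1e-8)
  expect_false(identical(out, sl$image))
})

test_that("a serialized plan replays to the exact same output", {
  cfg <- augment_config(p_other = 1, p_flip = 1, p_gamma = 1)
  plan <- sample_transform(cfg, seed = 77)
  sl <- generate_slice(phantom_spec(grid_size = 64))
  out1 <- apply_augmentation(sl, plan)
  plan2 <- plan_from_json(plan_to_json(plan))
  out2 <- apply_augmentation(sl, plan2)
  expect_equal(out2$image, out1$image, tolerance = 1e-12)
  expect_identical(out2$scar_mask, out1$scar_mask)
})
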
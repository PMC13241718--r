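test_that("noise-free phantom renders are piecewise constant with exact masks", {
  sl <- generate_slice(quiet_spec())
  expect_equal(sort(unique(as.vector(sl$image))), c(20, 60, 160, 180))
  expect_true(all(sl$scar_mask <= sl$myo_mask))
  # scar takes the scar intensity exactly
  expect_true(all(sl$image[sl$scar_mask == 1] == 160))

  empty <- generate_slice(quiet_spec(scar_extent_deg = 0))
  expect_equal(sum(empty$scar_mask), 0)
})

test_that("a 90-degree full-transmural wedge covers a quarter of the annulus", {
  sl <- generate_slice(quiet_spec(scar_extent_deg = 90, scar_transmurality = 1))
  ratio <- sum(sl$scar_mask) / sum(sl$myo_mask)
  expect_gte(ratio, 0.23)
  expect_lte(ratio, 0.27)
})

test_that("pixel-counted scar area matches the analytic wedge formula within 5%", {
  set.seed(42)
  for (k in 1:10) {
    spec <- quiet_spec(grid_size = 128,
                       r_endo_mm = runif(1, 12, 20),
                       r_epi_mm = runif(1, 32, 45),   # r_epi >= 20 px at 1.5 mm
                       scar_start_deg = runif(1, 0, 360),
                       scar_extent_deg = runif(1, 45, 270),
                       scar_transmurality = runif(1, 0.4, 1),
                       pixel_spacing_mm = 1.5)
    sl <- generate_slice(spec)
    px_area <- sum(sl$scar_mask) * 1.5^2
    expect_lt(abs(px_area - analytic_scar_area_mm2(spec)) / analytic_scar_area_mm2(spec),
              0.05)
  }
})

test_that("spec invariants are validated with informative errors", {
  expect_error(phantom_spec(r_endo_mm = 30, r_epi_mm = 25), "r_endo_mm")
  expect_error(phantom_spec(intensity_scar = 50, intensity_myo = 60), "hyperenhancement")
  expect_error(phantom_spec(scar_transmurality = 0), "scar_transmurality")
  expect_error(phantom_spec(scar_extent_deg = 400), "scar_extent_deg")
})

test_that("generation is deterministic under a fixed spec and seed", {
  a <- generate_slice(phantom_spec(seed = 7))
  b <- generate_slice(phantom_spec(seed = 7))
  expect_identical(a$image, b$image)
  d <- generate_slice(phantom_spec(seed = 8))
  expect_false(identical(a$image, d$image))
})

test_that("cohorts have distinct subject ids, burdens, and reproduce under seed", {
  co <- generate_cohort(1, make_spec_sampler(grid_size = 48),
                        slices_per_subject = 3, seed = 5)
  expect_length(co, 3)
  expect_equal(unique(vapply(co, function(r) r$subject_id, character(1))), "S001")

  co1 <- generate_cohort(4, make_spec_sampler(grid_size = 48), 2, seed = 9)
  co2 <- generate_cohort(4, make_spec_sampler(grid_size = 48), 2, seed = 9)
  expect_identical(lapply(co1, `[[`, "image"), lapply(co2, `[[`, "image"))
  expect_equal(nrow(attr(co1, "burden")), 4)
  # scar containment holds for every generated slice
  for (r in co1) expect_true(all(r$scar_mask <= r$myo_mask))
})

test_that("a fixed-spec sampler gives slices identical up to noise realizations", {
  fixed <- function(seed) quiet_spec(grid_size = 48)
  co <- generate_cohort(2, fixed, slices_per_subject = 2, seed = 1)
  # noise-free spec: all renders identical
  expect_identical(co[[1]]$image, co[[4]]$image)
  noisy <- function(seed) phantom_spec(grid_size = 48, seed = seed)
  con <- generate_cohort(1, noisy, slices_per_subject = 2, seed = 1)
  expect_false(identical(con[[1]]$image, con[[2]]$image))
  expect_identical(con[[1]]$scar_mask, con[[2]]$scar_mask)
})

test_that("stratified split hits the target fractions and is disjoint", {
  co <- generate_cohort(100, make_spec_sampler(grid_size = 48), 1, seed = 3)
  spl <- stratified_split(co, c(0.70, 0.15, 0.15), seed = 2)
  expect_equal(unname(lengths(spl)), c(70, 15, 15))
  expect_length(intersect(spl$train, spl$val), 0)
  expect_length(intersect(spl$train, spl$test), 0)
  expect_length(intersect(spl$val, spl$test), 0)

  one <- stratified_split(data.frame(subject_id = "A", scar_pixels = 5),
                          n_strata = 1, seed = 1)
  expect_equal(sum(lengths(one)), 1)
})

test_that("too few subjects for the requested strata falls back with a warning", {
  burden <- data.frame(subject_id = c("A", "B"), scar_pixels = c(1, 10))
  expect_warning(spl <- stratified_split(burden, n_strata = 4, seed = 1),
                 "fewer subjects")
  expect_equal(sum(lengths(spl)), 2)
})

test_that("split burden distributions are indistinguishable by a rank test", {
  set.seed(31)
  burden <- data.frame(subject_id = sprintf("P%04d", 1:1000),
                       scar_pixels = rlnorm(1000, meanlog = 6, sdlog = 1))
  spl <- stratified_split(burden, c(0.70, 0.15, 0.15), seed = 13)
  get_b <- function(ids) burden$scar_pixels[burden$subject_id %in% ids]
  kw <- kruskal.test(list(get_b(spl$train), get_b(spl$val), get_b(spl$test)))
  expect_gt(kw$p.value, 0.05)
})

test_that("simulated raters reproduce the jitter model", {
  msk <- disc_mask(64, 30, 30, 10)
  p0 <- simulate_rater(msk, jitter = c(0, 0), n_points = 3, seed = 1)
  expect_equal(p0$box, bbox_from_mask(msk))

  p1 <- simulate_rater(msk, jitter = c(5, 0.1), n_points = 3, seed = 1)
  p2 <- simulate_rater(msk, jitter = c(5, 0.1), n_points = 3, seed = 2)
  expect_lt(box_iou(p1$box, p2$box), 1)
  expect_error(simulate_rater(matrix(0, 8, 8)), "empty")
})

test_that("mean rater box-center displacement matches the folded-normal value", {
  msk <- disc_mask(96, 47, 47, 12)
  b0 <- bbox_from_mask(msk)
  c0 <- (b0[1] + b0[3]) / 2
  shift_sd <- 5
  n_draw <- 10000
  disp <- vapply(seq_len(n_draw), function(k) {
    b <- simulate_rater(msk, jitter = c(shift_sd, 0), n_points = 2, seed = k)$box
    abs((b[1] + b[3]) / 2 - c0)
  }, numeric(1))
  theo <- shift_sd * sqrt(2 / pi)      # E|N(0, sd)|
  se <- sd(disp) / sqrt(n_draw)
  expect_lt(abs(mean(disp) - theo), 3 * se + 0.05)  # 0.05 allows integer snapping
})
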
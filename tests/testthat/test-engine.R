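tiny_train_set <- function(n = 2, grid = 24) {
  lapply(seq_len(n), function(i) {
    sl <- generate_slice(quiet_spec(grid_size = grid, r_endo_mm = 5,
                                    r_epi_mm = 10, pixel_spacing_mm = 1.5),
                         subject_id = sprintf("T%d", i))
    normalize_intensity(sl)
  })
}

test_that("the learning-rate schedule halves every period", {
  cfg <- train_config(lr0 = 1e-4, lr_halving_period_epochs = 10)
  expect_equal(lr_at_epoch(cfg, 0), 1e-4)
  expect_equal(lr_at_epoch(cfg, 9), 1e-4)
  expect_equal(lr_at_epoch(cfg, 10), 5e-5)
  expect_equal(lr_at_epoch(cfg, 25), 2.5e-5)
})

test_that("prompt channels render the box fill and unit point peaks", {
  p <- prompt(box = c(2, 3, 6, 8), points = cbind(c(4, 10), c(5, 10)))
  ch <- render_prompt_channels(p, c(16, 16))
  expect_equal(sum(ch$box), 4 * 5)
  expect_equal(ch$box[3, 4], 1)      # 0-based (2,3) inside
  expect_equal(ch$points[5, 6], 1)   # peak exactly at the point
  expect_equal(ch$points[11, 11], 1)
  expect_true(all(ch$points >= 0 & ch$points <= 1))
  none <- render_prompt_channels(NULL, c(8, 8))
  expect_equal(sum(none$box) + sum(none$points), 0)
})

test_that("backbone output respects the contract", {
  bb <- tiny_backbone(channels = 6, seed = 2)
  sl <- tiny_train_set(1)[[1]]
  pr <- make_prompt(sl$scar_mask, "box_and_points", seed = 1)
  p <- backbone_forward(bb, sl$image, pr)
  expect_equal(dim(p), dim(sl$image))
  expect_true(all(p >= 0 & p <= 1))
  # prediction thresholds the probability map
  res <- predict_mask(bb, sl, pr, threshold = 0)
  expect_true(all(res$mask[res$prob > 0] == 1))
  res0 <- predict_mask(bb, sl, pr, threshold = 1.01)
  expect_equal(sum(res0$mask), 0)
})

test_that("backbone parameter gradients match finite differences", {
  bb <- tiny_backbone(channels = 4, seed = 3)
  sl <- tiny_train_set(1, grid = 16)[[1]]
  pr <- make_prompt(sl$scar_mask, "box_and_points", seed = 1)
  cfg <- loss_config(kl_reduction = "mean")
  pm <- backbone_forward(bb, sl$image, pr, keep_cache = TRUE)
  dP <- total_loss_grad(pm, sl$scar_mask, cfg)
  gr <- scarseg:::backbone_backward(bb, attr(pm, "cache"), dP)
  h <- 1e-5
  probes <- list(list("conv1", 5, 2, 3), list("conv2", 1, 4, 1),
                 list("conv3", 9, 2, 2))
  for (pb in probes) {
    grp <- pb[[1]]; t9 <- pb[[2]]; i <- pb[[3]]; j <- pb[[4]]
    bb2 <- bb
    bb2$params[[grp]]$W[[t9]][i, j] <- bb$params[[grp]]$W[[t9]][i, j] + h
    lp <- total_loss(backbone_forward(bb2, sl$image, pr), sl$scar_mask, cfg)$total
    bb2$params[[grp]]$W[[t9]][i, j] <- bb$params[[grp]]$W[[t9]][i, j] - h
    lm <- total_loss(backbone_forward(bb2, sl$image, pr), sl$scar_mask, cfg)$total
    fd <- (lp - lm) / (2 * h)
    an <- gr[[grp]]$W[[t9]][i, j]
    expect_lt(abs(an - fd) / (abs(fd) + 1e-8), 1e-4)
  }
})

test_that("a scripted validation trace stops at patience and restores the best epoch", {
  snap <- new.env()
  trace_metric <- function(epoch, backbone) {
    if (epoch == 30) snap$params <- backbone$params
    if (epoch <= 30) epoch / 100 else 0.30
  }
  cfg <- train_config(lr0 = 1e-3, max_epochs = 100,
                      early_stop_patience_epochs = 20, batch_size = 1, seed = 4)
  fit <- train_backbone(tiny_backbone(channels = 2, seed = 4),
                        tiny_train_set(1, grid = 16), list(), cfg,
                        val_metric = trace_metric)
  expect_equal(fit$epochs_run, 50)
  expect_equal(fit$best_epoch, 30)
  expect_equal(nrow(fit$history), 50)
  expect_identical(fit$backbone$params, snap$params)
})

test_that("training histories are seeded-deterministic and honor max_epochs", {
  cfg <- train_config(lr0 = 1e-3, max_epochs = 1,
                      early_stop_patience_epochs = 1, seed = 5)
  tr <- tiny_train_set(2, grid = 16)
  fit1 <- train_backbone(tiny_backbone(channels = 3, seed = 5), tr, tr[1], cfg)
  expect_equal(nrow(fit1$history), 1)
  fit2 <- train_backbone(tiny_backbone(channels = 3, seed = 5), tr, tr[1], cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$backbone$params, fit2$backbone$params)
  expect_error(train_backbone(tiny_backbone(), list(), tr, cfg), "empty")
})

test_that("frozen parameter groups are bit-identical before and after training", {
  cfg <- train_config(lr0 = 1e-2, max_epochs = 2,
                      early_stop_patience_epochs = 2, seed = 6)
  bb <- tiny_backbone(channels = 3, seed = 6, freeze = "conv1")
  before <- bb$params$conv1
  tr <- tiny_train_set(2, grid = 16)
  fit <- train_backbone(bb, tr, tr[1], cfg)
  expect_identical(fit$backbone$params$conv1, before)
  expect_false(identical(fit$backbone$params$conv2, bb$params$conv2))
})

test_that("morphological refinement shrinks and expands as set operations", {
  empty <- matrix(0, 16, 16)
  expect_equal(refine_mask(empty, "expand"), empty)
  line <- matrix(0, 16, 16); line[8, 3:12] <- 1
  expect_equal(sum(refine_mask(line, "shrink")), 0)   # 1-px line erodes away
  d <- disc_mask(64, 31, 31, 20)
  closed <- refine_mask(refine_mask(d, "expand"), "shrink")
  expect_identical(closed, d)                         # closing fixes a convex disc
  for (s in 1:5) {
    m <- random_mask(20, 0.4, seed = s)
    ex <- refine_mask(m, "expand"); sh <- refine_mask(m, "shrink")
    expect_true(all(ex >= m))
    expect_true(all(sh <= m))
  }
})
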
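# Backbone-agnostic prompt-conditioned segmentation.
#
# The backbone contract: forward(normalized image, prompt) -> probability map
# on the same grid with values in [0, 1], plus named trainable parameter
# groups (a freeze mask excludes groups from updates). The built-in
# reference backbone is a small dilated convolutional network over the image
# plus two prompt channels (the box rendered as a filled binary channel,
# points rendered as sigma = 2 Gaussian heatmaps); convolutions and their
# gradients are computed with tap-wise matrix products, and optimization
# uses AdamW (decoupled weight decay).

#' Render prompt conditioning channels
#'
#' @param p a [prompt()] (or NULL for unconditioned input).
#' @param grid_dim (rows, cols).
#' @param point_sigma Gaussian heatmap SD in pixels.
#' @return list with `box` and `points` matrices.
#' @export
render_prompt_channels <- function(p, grid_dim, point_sigma = 2) {
  nr <- grid_dim[1]; nc <- grid_dim[2]
  box_ch <- matrix(0, nr, nc)
  pts_ch <- matrix(0, nr, nc)
  if (!is.null(p)) {
    if (!is.null(p$box)) {
      b <- clamp_box(round(p$box), grid_dim)
      box_ch[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- 1
    }
    if (!is.null(p$points) && nrow(p$points) > 0) {
      rr <- matrix(0:(nr - 1), nr, nc)
      cc <- t(matrix(0:(nc - 1), nc, nr))
      for (k in seq_len(nrow(p$points))) {
        d2 <- (rr - p$points[k, 1])^2 + (cc - p$points[k, 2])^2
        pts_ch <- pmax(pts_ch, exp(-d2 / (2 * point_sigma^2)))
      }
    }
  }
  list(box = box_ch, points = pts_ch)
}

# ---- convolution plumbing -------------------------------------------------

# linear indices of the 9 dilated taps for every output pixel, into a
# zero-padded (nr + 2d) x (nc + 2d) grid stored column-major
conv_indices <- function(nr, nc, d) {
  pr <- nr + 2 * d
  r <- rep(seq_len(nr), nc) + d
  c <- rep(seq_len(nc), each = nr) + d
  offs <- expand.grid(dr = c(-d, 0, d), dc = c(-d, 0, d))
  idx <- matrix(0L, nr * nc, 9)
  for (t in 1:9) {
    idx[, t] <- (c + offs$dc[t] - 1L) * pr + (r + offs$dr[t])
  }
  idx
}

pad_features <- function(Fm, nr, nc, d) {
  # Fm: (nr*nc) x C column-major feature matrix -> padded (pr*pc) x C
  pr <- nr + 2 * d; pc <- nc + 2 * d
  P <- matrix(0, pr * pc, ncol(Fm))
  r <- rep(seq_len(nr), nc) + d
  c <- rep(seq_len(nc), each = nr) + d
  P[(c - 1L) * pr + r, ] <- Fm
  P
}

conv_forward <- function(Fm, W, b, nr, nc, d, idx) {
  # W: list of 9 matrices inC x outC; b: length outC
  P <- pad_features(Fm, nr, nc, d)
  out <- matrix(rep(b, each = nr * nc), nr * nc, length(b))
  for (t in 1:9) out <- out + P[idx[, t], , drop = FALSE] %*% W[[t]]
  list(out = out, P = P)
}

conv_backward <- function(dOut, P, W, nr, nc, d, idx) {
  dW <- vector("list", 9)
  dP <- matrix(0, nrow(P), nrow(W[[1]]))
  for (t in 1:9) {
    Xt <- P[idx[, t], , drop = FALSE]
    dW[[t]] <- crossprod(Xt, dOut)
    dXt <- dOut %*% t(W[[t]])
    dP[idx[, t], ] <- dP[idx[, t], , drop = FALSE] + dXt
  }
  db <- colSums(dOut)
  # unpad
  pr <- nr + 2 * d
  r <- rep(seq_len(nr), nc) + d
  c <- rep(seq_len(nc), each = nr) + d
  list(dW = dW, db = db, dF = dP[(c - 1L) * pr + r, , drop = FALSE])
}

# ---- backbone -------------------------------------------------------------

#' Create the reference tiny segmentation backbone
#'
#' A three-layer dilated 3x3 convolutional network (dilations 1, 2, 4) over
#' `channels` features, followed by a 1x1 sigmoid head. Inputs are the
#' normalized image and the two rendered prompt channels.
#'
#' @param channels hidden feature width (default 12).
#' @param seed initialization seed.
#' @param freeze character vector of parameter-group names excluded from
#'   training (e.g. "conv1"); the prompt rendering itself has no parameters.
#' @return object of class `scarseg_backbone`.
#' @export
tiny_backbone <- function(channels = 12, seed = 1, freeze = character(0)) {
  in_ch <- 3
  dil <- c(1, 2, 4)
  with_seed(seed, {
    mk <- function(ic, oc) {
      sdv <- sqrt(2 / (9 * ic))
      lapply(1:9, function(t) matrix(rnorm(ic * oc, 0, sdv), ic, oc))
    }
    params <- list(
      conv1 = list(W = mk(in_ch, channels), b = numeric(channels)),
      conv2 = list(W = mk(channels, channels), b = numeric(channels)),
      conv3 = list(W = mk(channels, channels), b = numeric(channels)),
      head = list(W = matrix(rnorm(channels, 0, sqrt(1 / channels)), channels, 1),
                  b = 0)
    )
    structure(list(name = "tiny_dilated_cnn", channels = channels,
                   dilations = dil, params = params, freeze = freeze,
                   point_sigma = 2),
              class = "scarseg_backbone")
  })
}

backbone_inputs <- function(backbone, image, prompt) {
  ch <- render_prompt_channels(prompt, dim(image), backbone$point_sigma)
  cbind(as.vector(image), as.vector(ch$box), as.vector(ch$points))
}

#' Forward pass of a backbone
#'
#' @param backbone a `scarseg_backbone`.
#' @param image normalized image matrix.
#' @param prompt a [prompt()] or NULL.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return probability matrix in `[0, 1]` (with attribute "cache" when
#'   `keep_cache`).
#' @export
backbone_forward <- function(backbone, image, prompt = NULL, keep_cache = FALSE) {
  nr <- nrow(image); nc <- ncol(image)
  X <- backbone_inputs(backbone, image, prompt)
  pr <- backbone$params
  dil <- backbone$dilations
  idx <- lapply(dil, function(d) conv_indices(nr, nc, d))
  c1 <- conv_forward(X, pr$conv1$W, pr$conv1$b, nr, nc, dil[1], idx[[1]])
  a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(a1, pr$conv2$W, pr$conv2$b, nr, nc, dil[2], idx[[2]])
  a2 <- pmax(c2$out, 0)
  c3 <- conv_forward(a2, pr$conv3$W, pr$conv3$b, nr, nc, dil[3], idx[[3]])
  a3 <- pmax(c3$out, 0)
  z <- as.vector(a3 %*% pr$head$W) + pr$head$b
  p <- 1 / (1 + exp(-z))
  out <- matrix(p, nr, nc)
  if (keep_cache) {
    attr(out, "cache") <- list(X = X, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                               c3 = c3, a3 = a3, p = p, idx = idx,
                               nr = nr, nc = nc)
  }
  out
}

backbone_backward <- function(backbone, cache, dP) {
  # dP: matrix gradient of loss wrt output probabilities
  pr <- backbone$params
  dil <- backbone$dilations
  nr <- cache$nr; nc <- cache$nc
  p <- cache$p
  dz <- as.vector(dP) * p * (1 - p)
  g_headW <- crossprod(cache$a3, dz)
  g_headb <- sum(dz)
  da3 <- matrix(dz, ncol = 1) %*% t(pr$head$W)
  da3[cache$a3 <= 0] <- 0
  b3 <- conv_backward(da3, cache$c3$P, pr$conv3$W, nr, nc, dil[3], cache$idx[[3]])
  da2 <- b3$dF; da2[cache$a2 <= 0] <- 0
  b2 <- conv_backward(da2, cache$c2$P, pr$conv2$W, nr, nc, dil[2], cache$idx[[2]])
  da1 <- b2$dF; da1[cache$a1 <= 0] <- 0
  b1 <- conv_backward(da1, cache$c1$P, pr$conv1$W, nr, nc, dil[1], cache$idx[[1]])
  list(conv1 = list(W = b1$dW, b = b1$db),
       conv2 = list(W = b2$dW, b = b2$db),
       conv3 = list(W = b3$dW, b = b3$db),
       head = list(W = g_headW, b = g_headb))
}

# ---- optimizer ------------------------------------------------------------

adamw_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       freeze = character(0)) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(w, g, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    w <- w - lr * (mh / (sqrt(vh) + eps) + decay * w)
    list(w = w, m = m, v = v)
  }
  for (grp in names(params)) {
    if (grp %in% freeze) next
    for (fld in names(params[[grp]])) {
      w <- params[[grp]][[fld]]; g <- grads[[grp]][[fld]]
      decay <- if (fld == "b") 0 else weight_decay
      if (is.list(w)) {
        for (t9 in seq_along(w)) {
          r <- upd(w[[t9]], g[[t9]], state$m[[grp]][[fld]][[t9]],
                   state$v[[grp]][[fld]][[t9]], decay)
          params[[grp]][[fld]][[t9]] <- r$w
          state$m[[grp]][[fld]][[t9]] <- r$m
          state$v[[grp]][[fld]][[t9]] <- r$v
        }
      } else {
        r <- upd(w, g, state$m[[grp]][[fld]], state$v[[grp]][[fld]], decay)
        params[[grp]][[fld]] <- r$w
        state$m[[grp]][[fld]] <- r$m
        state$v[[grp]][[fld]] <- r$v
      }
    }
  }
  list(params = params, state = state)
}

# ---- schedule and training ------------------------------------------------

#' Training configuration
#'
#' Defaults mirror the fine-tuning schedule: AdamW with initial learning
#' rate 1e-4 and weight decay 1e-2, learning rate halved every 10 epochs, at
#' most 100 epochs with early stopping after 20 epochs without improvement
#' in validation DSC.
#'
#' @param lr0 initial learning rate.
#' @param weight_decay decoupled weight decay.
#' @param lr_halving_period_epochs epochs between halvings.
#' @param max_epochs maximum epochs.
#' @param early_stop_patience_epochs consecutive non-improving epochs before
#'   stopping.
#' @param batch_size gradient-accumulation batch size.
#' @param seed RNG seed for shuffling and per-epoch prompt regeneration.
#' @param loss a [loss_config()].
#' @param freeze parameter groups excluded from updates.
#' @param strategies prompting strategies sampled per example per epoch.
#' @param prompt_jitter list(max_shift_px, max_expand_frac) for box prompt
#'   augmentation during training.
#' @param point_range point-count range for sampled point prompts.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, weight_decay = 1e-2,
                         lr_halving_period_epochs = 10, max_epochs = 100,
                         early_stop_patience_epochs = 20, batch_size = 4,
                         seed = 1, loss = loss_config(kl_reduction = "mean"),
                         freeze = character(0),
                         strategies = c("box_only", "points_only", "box_and_points"),
                         prompt_jitter = list(max_shift_px = 10, max_expand_frac = 0.20),
                         point_range = c(2, 10)) {
  stopifnot_scalar_num(lr0, "lr0", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(max_epochs, "max_epochs", lo = 1)
  if (early_stop_patience_epochs > max_epochs) {
    stop("patience must not exceed max_epochs", call. = FALSE)
  }
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a (0-based) epoch under the stepwise halving schedule
#'
#' `lr0 * 0.5 ^ floor(epoch / period)`.
#' @param config a [train_config()].
#' @param epoch 0-based epoch index.
#' @return learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot_scalar_num(epoch, "epoch", lo = 0)
  config$lr0 * 0.5^(epoch %/% config$lr_halving_period_epochs)
}

make_train_prompt <- function(scar_mask, strategy, config, seed, grid_dim) {
  box <- NULL; pts <- NULL
  if (strategy %in% c("box_only", "box_and_points")) {
    box <- bbox_from_mask(scar_mask)
    box <- augment_box(box, grid_dim,
                       max_shift_px = config$prompt_jitter$max_shift_px,
                       max_expand_frac = config$prompt_jitter$max_expand_frac,
                       seed = derive_seed(seed, 1))
  }
  if (strategy %in% c("points_only", "box_and_points")) {
    pts <- sample_points(scar_mask, n_range = config$point_range,
                         seed = derive_seed(seed, 2))
  }
  prompt(box = box, points = pts, strategy = strategy)
}

#' Mean validation DSC of a backbone over a slice set
#'
#' Deterministic exact prompts (tight box + seeded points). `box_jitter`
#' optionally perturbs the evaluation boxes with [augment_box()] to probe
#' robustness to inconsistent prompt placement.
#'
#' @param backbone a backbone.
#' @param slices list of [slice_record()]s with scar masks.
#' @param strategy prompting strategy for evaluation.
#' @param threshold binarization threshold.
#' @param seed seed for point sampling (and box jitter).
#' @param box_jitter NULL, or list(max_shift_px, max_expand_frac).
#' @return mean DSC.
#' @export
evaluate_dsc <- function(backbone, slices, strategy = "box_and_points",
                         threshold = 0.5, seed = 99, box_jitter = NULL) {
  vals <- vapply(seq_along(slices), function(i) {
    sl <- slices[[i]]
    pr <- make_prompt(sl$scar_mask, strategy = strategy,
                      seed = derive_seed(seed, i), n_range = c(5, 5))
    if (!is.null(box_jitter) && !is.null(pr$box)) {
      pr$box <- augment_box(pr$box, dim(sl$image),
                            max_shift_px = box_jitter$max_shift_px,
                            max_expand_frac = box_jitter$max_expand_frac,
                            seed = derive_seed(seed, 5000 + i))
    }
    res <- predict_mask(backbone, sl, pr, threshold = threshold)
    dsc(res$mask, sl$scar_mask)
  }, numeric(1))
  mean(vals)
}

#' Train a backbone with the composite loss and early stopping
#'
#' Optimizes [total_loss()] with AdamW under the stepwise learning-rate
#' schedule. Prompts are regenerated every epoch with prompt augmentation
#' (jittered boxes, resampled points) and, by default, a per-example draw
#' from the configured prompting strategies. Validation mean DSC is tracked;
#' training stops when `early_stop_patience_epochs` pass without an
#' improvement greater than 1e-5, and the checkpoint with the best
#' validation DSC is returned. Fully seeded and reproducible.
#'
#' @param backbone a `scarseg_backbone`.
#' @param train_set,val_set lists of normalized [slice_record()]s with scar
#'   masks.
#' @param config a [train_config()].
#' @param val_metric optional function(epoch, backbone) returning the
#'   validation score, replacing the DSC evaluation (used to exercise the
#'   schedule and stopping logic in isolation).
#' @param verbose print per-epoch progress.
#' @return list with `backbone` (best checkpoint), `history` (data.frame:
#'   epoch, lr, loss components, val_dsc), `best_epoch`, `epochs_run`.
#' @export
train_backbone <- function(backbone, train_set, val_set, config = train_config(),
                           val_metric = NULL, verbose = FALSE) {
  if (length(train_set) == 0) stop("empty training set", call. = FALSE)
  if (length(val_set) == 0 && is.null(val_metric)) stop("empty validation set", call. = FALSE)
  state <- adamw_init(backbone$params)
  frozen_before <- backbone$params[backbone$freeze]
  best <- list(dsc = -Inf, params = backbone$params, epoch = 0L)
  since_improve <- 0L
  hist <- list()
  n_tr <- length(train_set)
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_at_epoch(config, epoch - 1)
    ord <- with_seed(derive_seed(config$seed, 7000 + epoch), sample.int(n_tr))
    comp <- c(dice = 0, bce = 0, kl = 0, total = 0)
    acc <- NULL; acc_n <- 0L
    for (j in seq_along(ord)) {
      sl <- train_set[[ord[j]]]
      sd_j <- derive_seed(config$seed, epoch * 100000 + ord[j])
      strat <- if (length(config$strategies) == 1) config$strategies else
        with_seed(derive_seed(sd_j, 5), sample(config$strategies, 1))
      pr <- make_train_prompt(sl$scar_mask, strat, config, sd_j, dim(sl$image))
      pmap <- backbone_forward(backbone, sl$image, pr, keep_cache = TRUE)
      l <- total_loss(pmap, sl$scar_mask, config$loss)
      if (!is.finite(l$total)) {
        stop(sprintf("NaN/Inf loss at epoch %d, sample %d", epoch, ord[j]), call. = FALSE)
      }
      comp <- comp + c(l$dice, l$bce, l$kl, l$total)
      dP <- total_loss_grad(pmap, sl$scar_mask, config$loss)
      g <- backbone_backward(backbone, attr(pmap, "cache"), dP)
      acc <- if (is.null(acc)) g else add_grads(acc, g)
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || j == n_tr) {
        acc <- scale_grads(acc, 1 / acc_n)
        st <- adamw_step(backbone$params, acc, state, lr, config$weight_decay,
                         freeze = backbone$freeze)
        backbone$params <- st$params; state <- st$state
        acc <- NULL; acc_n <- 0L
      }
    }
    comp <- comp / n_tr
    vd <- if (is.null(val_metric)) {
      evaluate_dsc(backbone, val_set, strategy = "box_and_points",
                   seed = derive_seed(config$seed, 31))
    } else val_metric(epoch, backbone)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                loss_dice = comp[1], loss_bce = comp[2],
                                loss_kl = comp[3], loss_total = comp[4],
                                val_dsc = vd)
    epochs_run <- epoch
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e loss %.4f val DSC %.4f",
                      epoch, lr, comp[4], vd))
    }
    if (vd > best$dsc + 1e-5) {
      best <- list(dsc = vd, params = backbone$params, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$early_stop_patience_epochs) break
    }
  }
  backbone$params <- best$params
  backbone$params[backbone$freeze] <- frozen_before
  list(backbone = backbone,
       history = do.call(rbind, hist),
       best_epoch = best$epoch,
       epochs_run = epochs_run)
}

add_grads <- function(a, b) {
  if (is.list(a)) mapply(add_grads, a, b, SIMPLIFY = FALSE) else a + b
}
scale_grads <- function(a, f) {
  if (is.list(a)) lapply(a, scale_grads, f = f) else a * f
}

#' Segment a slice with a backbone and prompt
#'
#' @param backbone a backbone.
#' @param slice a preprocessed [slice_record()].
#' @param prompt a [prompt()].
#' @param threshold binarization threshold (default 0.5).
#' @return list with `prob` (probability map) and `mask` (binary).
#' @export
predict_mask <- function(backbone, slice, prompt = NULL, threshold = 0.5) {
  img <- if (inherits(slice, "slice_record")) slice$image else slice
  p <- backbone_forward(backbone, img, prompt)
  list(prob = p, mask = (p >= threshold) * 1)
}

#' Morphological mask refinement
#'
#' Single-iteration erosion ("shrink") or dilation ("expand") with a 3x3
#' elliptical structuring element; at this size the rasterized ellipse is
#' the 4-connected cross.
#'
#' @param mask binary matrix.
#' @param direction "shrink" or "expand".
#' @return refined binary matrix.
#' @export
refine_mask <- function(mask, direction = c("shrink", "expand")) {
  direction <- match.arg(direction)
  if (sum(mask) == 0 && direction == "expand") return(mask)
  kern <- EBImage::makeBrush(3, shape = "diamond")
  out <- if (direction == "shrink") EBImage::erode(mask, kern) else EBImage::dilate(mask, kern)
  m <- matrix(as.numeric(EBImage::imageData(out) > 0.5), nrow(mask), ncol(mask))
  m
}
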
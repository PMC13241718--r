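# Uncertainty-aware supervision: Gaussian soft labels and the composite
# Dice + binary cross-entropy + Kullback-Leibler training objective.
#
# For a slice with pixels i = 1..N, predicted probabilities p_i, binary
# ground truth g_i and soft labels s_i:
#   L_Dice = 1 - (2 sum p_i g_i + eps) / (sum p_i + sum g_i + eps)
#   L_BCE  = -(1/N) sum [ g_i log p_i + (1 - g_i) log(1 - p_i) ]
#   L_KL   = sum s_i log( s_i / (p_i + eps) )         (0 log 0 := 0)
#   L_total = lambda_Dice L_Dice + lambda_BCE L_BCE + lambda_KL L_KL
# The KL term is evaluated on the scar-class probability map exactly as
# written (the maps are not normalized distributions, so it may be negative).

#' Loss configuration
#'
#' Default weights are the validated configuration lambda_BCE = 0.62,
#' lambda_Dice = 0.60, lambda_KL = 0.64 with soft-label smoothing sigma = 2.
#' `normalize_lambdas` optionally divides the weights by their sum.
#'
#' @param lambda_dice,lambda_bce,lambda_kl non-negative component weights.
#' @param sigma Gaussian soft-label standard deviation in pixels (>= 0).
#' @param epsilon numerical stability constant.
#' @param normalize_lambdas divide weights by their sum (default FALSE).
#' @param kl_reduction "sum" evaluates the KL term exactly as printed; "mean"
#'   divides it by the pixel count N, putting it on the same per-pixel scale
#'   as the BCE term (the stabilizing normalization used for training: the
#'   raw sum grows with slice area and would otherwise dominate the
#'   composite objective).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(lambda_dice = 0.60, lambda_bce = 0.62, lambda_kl = 0.64,
                        sigma = 2.0, epsilon = 1e-6, normalize_lambdas = FALSE,
                        kl_reduction = c("sum", "mean")) {
  kl_reduction <- match.arg(kl_reduction)
  for (nm in c("lambda_dice", "lambda_bce", "lambda_kl")) {
    stopifnot_scalar_num(get(nm), nm, lo = 0)
  }
  stopifnot_scalar_num(sigma, "sigma", lo = 0)
  stopifnot_scalar_num(epsilon, "epsilon", lo = 0, strict_lo = TRUE)
  lam <- c(lambda_dice, lambda_bce, lambda_kl)
  if (normalize_lambdas && sum(lam) > 0) lam <- lam / sum(lam)
  structure(list(lambda_dice = lam[1], lambda_bce = lam[2], lambda_kl = lam[3],
                 sigma = sigma, epsilon = epsilon, kl_reduction = kl_reduction),
            class = "loss_config")
}

#' Gaussian soft labels from a binary mask
#'
#' Filters the 0/1 mask with a normalized 2-D Gaussian kernel (reflective
#' boundaries, truncated at 4 sigma) and clips to `[0, 1]`. `sigma = 0`
#' returns the mask unchanged. Smoothing encodes boundary/annotation
#' uncertainty at the scar-myocardium interface.
#'
#' @param g binary matrix.
#' @param sigma standard deviation in pixels.
#' @return matrix of soft labels in `[0, 1]`.
#' @export
make_soft_labels <- function(g, sigma = 2.0) {
  stopifnot(is.matrix(g))
  if (sigma == 0) return(g)
  pmin(pmax(gaussian_filter2d(g, sigma), 0), 1)
}

#' Soft Dice loss
#'
#' @param p probability matrix in `[0, 1]`.
#' @param g binary matrix of the same shape.
#' @param eps stability constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  check_same_shape(p, g, "p and g")
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

dice_loss_grad <- function(p, g, eps = 1e-6) {
  num <- 2 * sum(p * g) + eps
  den <- sum(p) + sum(g) + eps
  -(2 * g * den - num) / den^2
}

#' Binary cross-entropy loss
#'
#' Mean over all pixels; `p` is clamped to `[eps, 1 - eps]` before the logs.
#' @inheritParams dice_loss
#' @return scalar loss (>= 0).
#' @export
bce_loss <- function(p, g, eps = 1e-6) {
  check_same_shape(p, g, "p and g")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

bce_loss_grad <- function(p, g, eps = 1e-6) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  grad <- -(g / pc - (1 - g) / (1 - pc)) / length(p)
  grad[p < eps | p > 1 - eps] <- 0
  grad
}

#' Kullback-Leibler term against soft labels
#'
#' Pointwise sum of `s_i * log(s_i / (p_i + eps))` with the convention
#' `0 * log 0 = 0`. Evaluated on the scar-class map only and not
#' symmetrized; because the maps are not normalized distributions the value
#' may be negative.
#'
#' @param s soft-label matrix in `[0, 1]`.
#' @param p probability matrix of the same shape.
#' @param eps stability constant.
#' @return scalar.
#' @export
kl_loss <- function(s, p, eps = 1e-6) {
  check_same_shape(s, p, "s and p")
  nz <- s > 0
  sum(s[nz] * log(s[nz] / (p[nz] + eps)))
}

kl_loss_grad <- function(s, p, eps = 1e-6) {
  -s / (p + eps)
}

#' Composite training loss with per-component breakdown
#'
#' Soft labels are generated internally from `g` with `config$sigma`.
#'
#' @param p probability matrix.
#' @param g binary ground truth matrix.
#' @param config a [loss_config()].
#' @return list with `total` and components `dice`, `bce`, `kl`.
#' @export
total_loss <- function(p, g, config = loss_config()) {
  s <- make_soft_labels(g, config$sigma)
  ld <- dice_loss(p, g, config$epsilon)
  lb <- bce_loss(p, g, config$epsilon)
  lk <- kl_loss(s, p, config$epsilon)
  if (config$kl_reduction == "mean") lk <- lk / length(p)
  list(total = config$lambda_dice * ld + config$lambda_bce * lb + config$lambda_kl * lk,
       dice = ld, bce = lb, kl = lk)
}

#' Gradient of the composite loss with respect to the probability map
#'
#' @inheritParams total_loss
#' @return matrix of the same shape as `p`.
#' @export
total_loss_grad <- function(p, g, config = loss_config()) {
  s <- make_soft_labels(g, config$sigma)
  kl_scale <- if (config$kl_reduction == "mean") 1 / length(p) else 1
  config$lambda_dice * dice_loss_grad(p, g, config$epsilon) +
    config$lambda_bce * bce_loss_grad(p, g, config$epsilon) +
    config$lambda_kl * kl_scale * kl_loss_grad(s, p, config$epsilon)
}
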
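# Training-time augmentation: spatial warps applied identically to image and
# masks, then intensity corruptions on the image alone. Each transform is
# included per-sample with its configured probability; a sampled plan is
# serializable and replays exactly (noise carries its own seed).

#' Augmentation configuration
#'
#' Magnitudes and per-sample probabilities: rotations +/-15 deg, isotropic
#' scaling +/-10%, affine shear (+/-8 deg), elastic deformation on a 7x7
#' control grid with up to 7.5 mm displacement, third-order polynomial bias
#' fields with coefficients up to 0.5, zero-mean Gaussian noise with SD in
#' [0, 0.1] (normalized-intensity scale), mild Gaussian blur (sigma in
#' [0, 1] px), log-space gamma +/-0.3, and CLAHE. CLAHE is applied to all
#' samples, flips and gamma at 50%, all other augmentations at 30%.
#'
#' @param rot_deg_max,scale_frac_max,shear_deg_max spatial magnitudes.
#' @param elastic_grid,elastic_disp_mm_max elastic control grid side and
#'   maximum per-control-point displacement in mm.
#' @param bias_order,bias_coeff_max polynomial bias field order and maximum
#'   coefficient magnitude.
#' @param noise_sd_range,blur_sigma_range,gamma_log_max intensity magnitudes.
#' @param clahe_nx,clahe_limit CLAHE tile grid side and clip limit.
#' @param p_clahe,p_flip,p_gamma,p_other inclusion probabilities.
#' @param include_motion experimental directional-blur motion proxy, included
#'   at `p_other` when TRUE.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(rot_deg_max = 15, scale_frac_max = 0.10,
                           shear_deg_max = 8,
                           elastic_grid = 7, elastic_disp_mm_max = 7.5,
                           bias_order = 3, bias_coeff_max = 0.5,
                           noise_sd_range = c(0, 0.1),
                           blur_sigma_range = c(0, 1),
                           gamma_log_max = 0.3,
                           clahe_nx = 8, clahe_limit = 2,
                           p_clahe = 1.0, p_flip = 0.5, p_gamma = 0.5,
                           p_other = 0.3,
                           include_motion = FALSE) {
  for (p in c(p_clahe, p_flip, p_gamma, p_other)) {
    stopifnot_scalar_num(p, "probability", lo = 0, hi = 1)
  }
  structure(as.list(environment()), class = "augment_config")
}

#' Sample a transform plan
#'
#' Each transform is included independently with its configured probability;
#' included magnitudes are drawn uniformly within their ranges. The returned
#' plan replays exactly (see [plan_to_json()]).
#'
#' @param config an [augment_config()].
#' @param seed RNG seed.
#' @return object of class `transform_plan`.
#' @export
sample_transform <- function(config = augment_config(), seed = 1) {
  with_seed(seed, {
    inc <- function(p) runif(1) < p
    plan <- list(
      flip_h = inc(config$p_flip),
      flip_v = inc(config$p_flip),
      rot_deg = if (inc(config$p_other)) runif(1, -config$rot_deg_max, config$rot_deg_max) else 0,
      scale = if (inc(config$p_other)) runif(1, 1 - config$scale_frac_max, 1 + config$scale_frac_max) else 1,
      shear_deg = if (inc(config$p_other)) runif(1, -config$shear_deg_max, config$shear_deg_max) else 0,
      elastic = NULL, bias_coeffs = NULL,
      noise_sd = 0, noise_seed = derive_seed(seed, 101),
      blur_sigma = 0, motion_len_px = 0, motion_deg = 0,
      gamma_log = 0,
      clahe = inc(config$p_clahe),
      clahe_nx = config$clahe_nx, clahe_limit = config$clahe_limit
    )
    if (inc(config$p_other)) {
      g <- config$elastic_grid
      plan$elastic <- list(
        grid = g,
        disp_mm = array(runif(2 * g * g, -config$elastic_disp_mm_max,
                              config$elastic_disp_mm_max), dim = c(g, g, 2)))
    }
    if (inc(config$p_other)) {
      ord <- config$bias_order
      n_coef <- (ord + 1) * (ord + 2) / 2
      plan$bias_coeffs <- runif(n_coef, -config$bias_coeff_max, config$bias_coeff_max)
    }
    if (inc(config$p_other)) {
      plan$noise_sd <- runif(1, config$noise_sd_range[1], config$noise_sd_range[2])
    }
    if (inc(config$p_other)) {
      plan$blur_sigma <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
    }
    if (isTRUE(config$include_motion) && inc(config$p_other)) {
      plan$motion_len_px <- sample(2:5, 1)
      plan$motion_deg <- runif(1, 0, 180)
    }
    if (inc(config$p_gamma)) {
      plan$gamma_log <- runif(1, -config$gamma_log_max, config$gamma_log_max)
    }
    structure(plan, class = "transform_plan")
  })
}

is_identity_spatial <- function(plan) {
  !plan$flip_h && !plan$flip_v && plan$rot_deg == 0 && plan$scale == 1 &&
    plan$shear_deg == 0 && is.null(plan$elastic)
}

#' Apply the spatial part of a plan jointly to an image and its masks
#'
#' One geometric warp (flips, rotation, scaling, shear about the image
#' center, plus elastic deformation converted from mm to pixels via the
#' geometry) is applied identically to the image (bicubic) and every mask
#' (nearest-neighbour, so masks stay binary and containment is preserved).
#' An identity plan returns the inputs bit-identically.
#'
#' @param image numeric matrix.
#' @param masks named list of binary matrices (possibly empty).
#' @param plan a `transform_plan`.
#' @param geometry a [voxel_geometry()] (for the mm-to-pixel conversion of
#'   elastic displacements).
#' @return list with `image` and `masks`.
#' @export
apply_spatial <- function(image, masks, plan, geometry = voxel_geometry(1, 1)) {
  if (is_identity_spatial(plan)) return(list(image = image, masks = masks))
  nr <- nrow(image); nc <- ncol(image)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- plan$rot_deg * pi / 180
  sh <- tan(plan$shear_deg * pi / 180)
  # forward affine A = R %*% Shear %*% S, with flips as axis sign changes
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  H <- matrix(c(1, 0, sh, 1), 2, 2)
  S <- diag(c(plan$scale, plan$scale))
  Fm <- diag(c(if (plan$flip_v) -1 else 1, if (plan$flip_h) -1 else 1))
  A <- Fm %*% R %*% H %*% S
  Ainv <- solve(A)
  ro <- matrix(seq_len(nr), nr, nc) - cr
  co <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  ri <- Ainv[1, 1] * ro + Ainv[1, 2] * co + cr
  ci <- Ainv[2, 1] * ro + Ainv[2, 2] * co + cc
  if (!is.null(plan$elastic)) {
    g <- plan$elastic$grid
    dr <- resize_image(plan$elastic$disp_mm[, , 1], nr, nc, "bicubic") /
      geometry$row_spacing_mm
    dc <- resize_image(plan$elastic$disp_mm[, , 2], nr, nc, "bicubic") /
      geometry$col_spacing_mm
    ri <- ri + dr
    ci <- ci + dc
  }
  warp <- function(m, method) {
    matrix(sample_image(m, as.vector(ri), as.vector(ci), method = method), nr, nc)
  }
  out_img <- warp(image, "bicubic")
  out_masks <- lapply(masks, function(m) if (is.null(m)) NULL else as_binary(warp(m, "nearest")))
  list(image = out_img, masks = out_masks)
}

clahe_matrix <- function(img, nx = 8, limit = 2) {
  rng <- range(img)
  if (rng[1] == rng[2]) return(img)
  x01 <- (img - rng[1]) / (rng[2] - rng[1])
  # EBImage images are (x, y); transpose in and out
  eq <- EBImage::clahe(EBImage::Image(t(x01)), nx = nx, ny = nx, limit = limit)
  t(EBImage::imageData(eq)) * (rng[2] - rng[1]) + rng[1]
}

poly_bias_field <- function(nr, nc, coeffs, order = 3) {
  x <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  f <- matrix(0, nr, nc)
  k <- 1
  for (d in 0:order) {
    for (i in 0:d) {
      f <- f + coeffs[k] * x^(d - i) * y^i
      k <- k + 1
    }
  }
  exp(f)
}

#' Apply the intensity part of a plan to an image
#'
#' Fixed order: multiplicative polynomial bias field, Gaussian blur,
#' additive Gaussian noise (seeded from the plan), gamma modulation on a
#' min-max rescaled copy, then CLAHE. Masks are never touched. A plan with
#' all magnitudes zero and CLAHE off is the identity.
#'
#' @param image numeric matrix.
#' @param plan a `transform_plan`.
#' @return transformed matrix.
#' @export
apply_intensity <- function(image, plan) {
  x <- image
  if (!is.null(plan$bias_coeffs)) {
    x <- x * poly_bias_field(nrow(x), ncol(x), plan$bias_coeffs)
  }
  if (plan$blur_sigma > 0) x <- gaussian_filter2d(x, plan$blur_sigma)
  if (plan$motion_len_px > 1) x <- motion_blur(x, plan$motion_len_px, plan$motion_deg)
  if (plan$noise_sd > 0) {
    x <- x + with_seed(plan$noise_seed,
                       matrix(rnorm(length(x), 0, plan$noise_sd), nrow(x), ncol(x)))
  }
  if (plan$gamma_log != 0) {
    rng <- range(x)
    if (rng[1] < rng[2]) {
      x01 <- (x - rng[1]) / (rng[2] - rng[1])
      x <- x01^exp(plan$gamma_log) * (rng[2] - rng[1]) + rng[1]
    }
  }
  if (isTRUE(plan$clahe)) x <- clahe_matrix(x, nx = plan$clahe_nx, limit = plan$clahe_limit)
  x
}

# experimental motion-artifact proxy: mean along a short line segment
motion_blur <- function(img, len_px, angle_deg) {
  th <- angle_deg * pi / 180
  t_off <- seq(-(len_px - 1) / 2, (len_px - 1) / 2, length.out = len_px)
  nr <- nrow(img); nc <- ncol(img)
  R <- matrix(seq_len(nr), nr, nc); C <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  acc <- matrix(0, nr, nc)
  for (t in t_off) {
    acc <- acc + matrix(sample_image(img, as.vector(R + t * sin(th)),
                                     as.vector(C + t * cos(th)), "bilinear"), nr, nc)
  }
  acc / length(t_off)
}

#' Apply a full plan to a slice record
#'
#' Spatial warp on image and all present masks, then intensity transforms on
#' the image.
#'
#' @param slice a [slice_record()].
#' @param plan a `transform_plan`.
#' @return augmented [slice_record()].
#' @export
apply_augmentation <- function(slice, plan) {
  masks <- list(myo = slice$myo_mask, scar = slice$scar_mask,
                excl = slice$exclusion_mask)
  sp <- apply_spatial(slice$image, masks, plan, slice$geometry)
  img <- apply_intensity(sp$image, plan)
  slice_record(img, slice$geometry,
               myo_mask = sp$masks$myo, scar_mask = sp$masks$scar,
               exclusion_mask = sp$masks$excl,
               subject_id = slice$subject_id, slice_index = slice$slice_index)
}

#' Serialize / deserialize a transform plan to JSON
#'
#' Replaying a deserialized plan reproduces the augmented output exactly.
#' @param plan a `transform_plan`.
#' @return JSON string.
#' @export
plan_to_json <- function(plan) {
  p <- unclass(plan)
  if (!is.null(p$elastic)) {
    p$elastic$disp_mm <- list(dim = dim(p$elastic$disp_mm),
                              values = as.vector(p$elastic$disp_mm))
  }
  jsonlite::toJSON(p, auto_unbox = TRUE, null = "null", digits = NA)
}

#' @rdname plan_to_json
#' @param json JSON string as produced by [plan_to_json()].
#' @export
plan_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  if (!is.null(p$elastic)) {
    p$elastic$disp_mm <- array(p$elastic$disp_mm$values, dim = p$elastic$disp_mm$dim)
  }
  structure(p, class = "transform_plan")
}
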
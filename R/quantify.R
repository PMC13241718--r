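# Segmentation evaluation (DSC, Hausdorff distance in mm) and clinical
# quantification (scar mass from voxel geometry; FWHM reference method).

MYO_DENSITY_G_PER_CM3 <- 1.05

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; both masks empty gives 1, exactly one empty
#' gives 0.
#'
#' @param pred,gt binary matrices on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred, gt) {
  check_same_shape(pred, gt, "pred and gt")
  a <- sum(pred > 0); b <- sum(gt > 0)
  if (a + b == 0) return(1)
  2 * sum(pred > 0 & gt > 0) / (a + b)
}

# foreground pixels 4-adjacent to background (or on the image border),
# returned as 0-based (row, col)
boundary_pixels <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  up <- pad[1:nr, 2:(nc + 1)]; dn <- pad[3:(nr + 2), 2:(nc + 1)]
  lf <- pad[2:(nr + 1), 1:nc]; rt <- pad[2:(nr + 1), 3:(nc + 2)]
  bd <- m & !(up & dn & lf & rt)
  which(bd, arr.ind = TRUE) - 1
}

#' Symmetric Hausdorff distance between mask boundaries, in mm
#'
#' Maximum of the two directed maxima of Euclidean boundary-to-boundary
#' distances, with rows and columns scaled anisotropically by the pixel
#' spacing. Returns `NA` (undefined) if either mask is empty.
#'
#' @param pred,gt binary matrices.
#' @param geometry a [voxel_geometry()].
#' @return distance in mm, or `NA_real_`.
#' @export
hausdorff_mm <- function(pred, gt, geometry) {
  check_same_shape(pred, gt, "pred and gt")
  if (sum(pred) == 0 || sum(gt) == 0) return(NA_real_)
  a <- boundary_pixels(pred); b <- boundary_pixels(gt)
  ay <- a[, 1] * geometry$row_spacing_mm; ax <- a[, 2] * geometry$col_spacing_mm
  by <- b[, 1] * geometry$row_spacing_mm; bx <- b[, 2] * geometry$col_spacing_mm
  d2 <- outer(ay, by, "-")^2 + outer(ax, bx, "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Scar mass of a mask from voxel geometry
#'
#' Pixel count x in-plane voxel area x through-plane extent, converted with
#' a myocardial tissue density of 1.05 g/cm^3. Per slice; volumes sum over
#' slices.
#'
#' @param mask binary matrix.
#' @param geometry a [voxel_geometry()]; `thickness_mm` is the through-plane
#'   extent used for integration.
#' @return mass in grams.
#' @export
scar_mass <- function(mask, geometry) {
  vol_mm3 <- sum(mask > 0) * geometry$row_spacing_mm * geometry$col_spacing_mm *
    geometry$thickness_mm
  vol_mm3 * MYO_DENSITY_G_PER_CM3 / 1000
}

#' Absolute scar-mass error in grams and as percent of LV mass
#'
#' @param pred_mass,gt_mass masses in grams.
#' @param lv_mass left-ventricular myocardial mass in grams (for the percent
#'   form); non-positive gives `NA` percent.
#' @return list with `error_g` and `error_pct_lv`.
#' @export
mass_error <- function(pred_mass, gt_mass, lv_mass = NA_real_) {
  err <- abs(pred_mass - gt_mass)
  pct <- if (!is.na(lv_mass) && lv_mass > 0) 100 * err / lv_mass else NA_real_
  list(error_g = err, error_pct_lv = pct)
}

#' Full-width-at-half-maximum scar segmentation
#'
#' The reference semi-automated method: the peak intensity is taken inside an
#' operator-placed region of interest in the infarct core, and myocardial
#' voxels exceeding 50% of that peak are labeled scar; operator-drawn
#' exclusion zones are then subtracted. With `baseline = "none"` (default)
#' the threshold is `0.5 * peak`, literally; `baseline = "myo_min"` uses
#' `min + 0.5 * (peak - min)` over the myocardium, which is additionally
#' invariant to intensity offsets.
#'
#' @param image numeric matrix.
#' @param myo_mask binary myocardium mask.
#' @param roi non-empty binary region of interest, contained in `myo_mask`.
#' @param exclusion optional binary exclusion mask subtracted from the output.
#' @param baseline "none" or "myo_min".
#' @return binary scar mask.
#' @export
fwhm_segment <- function(image, myo_mask, roi, exclusion = NULL,
                         baseline = c("none", "myo_min")) {
  baseline <- match.arg(baseline)
  check_same_shape(image, myo_mask, "image and myo_mask")
  check_same_shape(image, roi, "image and roi")
  if (sum(roi) == 0) stop("roi is empty", call. = FALSE)
  if (any(roi > myo_mask)) stop("roi must lie inside the myocardium", call. = FALSE)
  peak <- max(image[roi > 0])
  thr <- if (baseline == "none") 0.5 * peak else {
    lo <- min(image[myo_mask > 0])
    lo + 0.5 * (peak - lo)
  }
  out <- (myo_mask > 0 & image > thr) * 1
  if (!is.null(exclusion)) out[exclusion > 0] <- 0
  out
}

#' Per-slice quantification summary
#'
#' @param pred,gt binary masks.
#' @param geometry a [voxel_geometry()].
#' @param lv_mass optional LV myocardial mass in grams.
#' @return data.frame with dsc, hd_mm, pred/gt scar mass, mass error (g, %LV).
#' @export
quantify_slice <- function(pred, gt, geometry, lv_mass = NA_real_) {
  pm <- scar_mass(pred, geometry)
  gm <- scar_mass(gt, geometry)
  err <- mass_error(pm, gm, lv_mass)
  data.frame(dsc = dsc(pred, gt),
             hd_mm = hausdorff_mm(pred, gt, geometry),
             pred_mass_g = pm, gt_mass_g = gm,
             mass_error_g = err$error_g,
             mass_error_pct_lv = err$error_pct_lv)
}
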
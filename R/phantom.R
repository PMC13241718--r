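# Synthetic short-axis LGE phantom: annular myocardium with a hyperenhanced
# subendocardial scar wedge, scanner-like corruptions, exact ground truth.
#
# Conventions: pixel coordinates are 0-based (row, col); pixel (r, c) has its
# center at physical position ((r - center_r) * spacing, (c - center_c) *
# spacing) relative to the annulus center. Boxes are half-open
# [r0, r1) x [c0, c1).

#' Voxel geometry of a short-axis slice
#'
#' @param row_spacing_mm,col_spacing_mm in-plane pixel spacing in mm.
#' @param thickness_mm through-plane extent in mm used for volume integration.
#' @return object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(row_spacing_mm, col_spacing_mm = row_spacing_mm,
                           thickness_mm = 8) {
  stopifnot_scalar_num(row_spacing_mm, "row_spacing_mm", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(col_spacing_mm, "col_spacing_mm", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(thickness_mm, "thickness_mm", lo = 0, strict_lo = TRUE)
  structure(list(row_spacing_mm = row_spacing_mm,
                 col_spacing_mm = col_spacing_mm,
                 thickness_mm = thickness_mm),
            class = "voxel_geometry")
}

#' Specification of a synthetic LGE slice
#'
#' Defaults emulate a mid-ventricular short-axis acquisition: 1.5 mm in-plane
#' spacing and 8 mm slice thickness (scanners in multicenter LGE studies span
#' roughly 1.2-2.0 mm and 6-10 mm), an annulus of endocardial radius 15 mm and
#' epicardial radius 25 mm, and a bright subendocardial scar wedge
#' (hyperenhancement: scar signal well above remote myocardium, blood pool
#' bright as in LGE).
#'
#' @param grid_size pixels per side.
#' @param pixel_spacing_mm in-plane spacing (isotropic).
#' @param slice_thickness_mm through-plane extent.
#' @param center annulus center in 0-based pixel coordinates (row, col);
#'   default is the grid center.
#' @param r_endo_mm,r_epi_mm endocardial/epicardial radii in mm.
#' @param scar_start_deg,scar_extent_deg angular wedge of scar (degrees).
#' @param scar_transmurality fraction of wall thickness occupied by scar,
#'   measured from the endocardial border outward, in (0, 1].
#' @param intensity_blood,intensity_myo,intensity_scar,intensity_bg mean
#'   signal levels of blood pool, remote myocardium, scar and background.
#' @param noise_sd additive Gaussian noise SD on the intensity scale.
#' @param bias_amplitude amplitude of the multiplicative low-order polynomial
#'   bias field (0 disables it).
#' @param seed RNG seed controlling noise and bias realizations.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128,
                         pixel_spacing_mm = 1.5,
                         slice_thickness_mm = 8,
                         center = NULL,
                         r_endo_mm = 15,
                         r_epi_mm = 25,
                         scar_start_deg = 30,
                         scar_extent_deg = 90,
                         scar_transmurality = 0.75,
                         intensity_blood = 180,
                         intensity_myo = 60,
                         intensity_scar = 160,
                         intensity_bg = 20,
                         noise_sd = 10,
                         bias_amplitude = 0.2,
                         seed = 1) {
  stopifnot_scalar_num(grid_size, "grid_size", lo = 16)
  stopifnot_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(slice_thickness_mm, "slice_thickness_mm", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(r_endo_mm, "r_endo_mm", lo = 0, strict_lo = TRUE)
  stopifnot_scalar_num(r_epi_mm, "r_epi_mm", lo = 0, strict_lo = TRUE)
  if (r_endo_mm >= r_epi_mm) stop("`r_endo_mm` must be smaller than `r_epi_mm`", call. = FALSE)
  stopifnot_scalar_num(scar_extent_deg, "scar_extent_deg", lo = 0, hi = 360)
  stopifnot_scalar_num(scar_transmurality, "scar_transmurality", lo = 0, hi = 1, strict_lo = TRUE)
  if (intensity_scar <= intensity_myo) {
    stop("`intensity_scar` must exceed `intensity_myo` (hyperenhancement)", call. = FALSE)
  }
  stopifnot_scalar_num(noise_sd, "noise_sd", lo = 0)
  stopifnot_scalar_num(bias_amplitude, "bias_amplitude", lo = 0)
  if (is.null(center)) center <- c((grid_size - 1) / 2, (grid_size - 1) / 2)
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 center = center,
                 r_endo_mm = r_endo_mm, r_epi_mm = r_epi_mm,
                 scar_start_deg = scar_start_deg,
                 scar_extent_deg = scar_extent_deg,
                 scar_transmurality = scar_transmurality,
                 intensity_blood = intensity_blood,
                 intensity_myo = intensity_myo,
                 intensity_scar = intensity_scar,
                 intensity_bg = intensity_bg,
                 noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 seed = seed),
            class = "phantom_spec")
}

#' One short-axis slice with geometry and optional ground-truth masks
#'
#' @param image numeric matrix.
#' @param geometry a [voxel_geometry()].
#' @param myo_mask,scar_mask,exclusion_mask optional binary matrices on the
#'   image grid; `scar_mask` must be contained in `myo_mask` when both given.
#' @param subject_id,slice_index identifiers.
#' @return object of class `slice_record`.
#' @export
slice_record <- function(image, geometry, myo_mask = NULL, scar_mask = NULL,
                         exclusion_mask = NULL, subject_id = "S1",
                         slice_index = 1L) {
  stopifnot(is.matrix(image), inherits(geometry, "voxel_geometry"))
  for (m in list(myo_mask, scar_mask, exclusion_mask)) {
    if (!is.null(m)) check_same_shape(image, m, "image and mask")
  }
  if (!is.null(myo_mask) && !is.null(scar_mask) && any(scar_mask > myo_mask)) {
    stop("scar_mask must be contained in myo_mask", call. = FALSE)
  }
  structure(list(image = image, geometry = geometry,
                 myo_mask = myo_mask, scar_mask = scar_mask,
                 exclusion_mask = exclusion_mask,
                 subject_id = subject_id, slice_index = as.integer(slice_index)),
            class = "slice_record")
}

# angular membership of a wedge [start, start + extent) measured in degrees,
# wrapped to [0, 360)
in_wedge <- function(theta_deg, start, extent) {
  if (extent <= 0) return(rep(FALSE, length(theta_deg)))
  if (extent >= 360) return(rep(TRUE, length(theta_deg)))
  rel <- (theta_deg - start) %% 360
  rel < extent
}

# low-order (quadratic) polynomial surface with random coefficients,
# normalized so max |field| = 1 over the grid
bias_surface <- function(n, seed) {
  with_seed(seed, {
    co <- runif(6, -1, 1)
    x <- seq(-1, 1, length.out = n)
    X <- matrix(x, n, n); Y <- t(X)
    f <- co[1] * X + co[2] * Y + co[3] * X * Y + co[4] * X^2 + co[5] * Y^2 +
      co[6] * (X^2 - Y^2)
    m <- max(abs(f))
    if (m == 0) f else f / m
  })
}

#' Generate a synthetic LGE slice from a phantom specification
#'
#' The noise-free render is piecewise constant over background, blood pool
#' (disc of radius `r_endo_mm`), myocardium (annulus) and the scar wedge
#' (limited to `scar_transmurality` of the wall measured from the endocardium
#' outward). The image is then corrupted by a multiplicative bias field and
#' additive Gaussian noise; the returned masks are the exact noise-free label
#' sets. Identical spec and seed give identical output.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id,slice_index identifiers stored on the record.
#' @return a [slice_record()] with `myo_mask` and `scar_mask` set.
#' @export
generate_slice <- function(spec, subject_id = "S1", slice_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  r <- matrix(0:(n - 1), n, n)          # row index, 0-based
  c <- t(r)
  dy <- (r - spec$center[1]) * spec$pixel_spacing_mm
  dx <- (c - spec$center[2]) * spec$pixel_spacing_mm
  rad <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360

  blood <- rad < spec$r_endo_mm
  myo <- rad >= spec$r_endo_mm & rad < spec$r_epi_mm
  r_scar_out <- spec$r_endo_mm +
    spec$scar_transmurality * (spec$r_epi_mm - spec$r_endo_mm)
  scar <- myo & rad < r_scar_out &
    in_wedge(theta, spec$scar_start_deg, spec$scar_extent_deg)

  img <- matrix(spec$intensity_bg, n, n)
  img[blood] <- spec$intensity_blood
  img[myo] <- spec$intensity_myo
  img[scar] <- spec$intensity_scar

  if (spec$bias_amplitude > 0) {
    img <- img * (1 + spec$bias_amplitude * bias_surface(n, derive_seed(spec$seed, 1)))
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed(derive_seed(spec$seed, 2),
                           matrix(rnorm(n * n, 0, spec$noise_sd), n, n))
  }
  slice_record(img,
               voxel_geometry(spec$pixel_spacing_mm, spec$pixel_spacing_mm,
                              spec$slice_thickness_mm),
               myo_mask = myo * 1, scar_mask = scar * 1,
               subject_id = subject_id, slice_index = slice_index)
}

#' Analytic scar wedge area of a phantom specification
#'
#' Area in mm^2 of the wedge annulus between `r_endo` and the transmural
#' scar boundary, spanning `scar_extent_deg` degrees.
#' @param spec a [phantom_spec()].
#' @return area in mm^2.
#' @export
analytic_scar_area_mm2 <- function(spec) {
  r_out <- spec$r_endo_mm +
    spec$scar_transmurality * (spec$r_epi_mm - spec$r_endo_mm)
  (spec$scar_extent_deg / 360) * pi * (r_out^2 - spec$r_endo_mm^2)
}

#' Default sampler of phantom specifications
#'
#' Returns a function `f(seed)` drawing a `phantom_spec` with anatomy and
#' signal levels varied over clinically plausible ranges: endocardial radius
#' 12-18 mm, wall thickness 8-12 mm, scar wedge 40-160 degrees with
#' transmurality 0.4-1, and per-subject signal level jitter.
#'
#' @param grid_size pixels per side of the generated slices.
#' @param pixel_spacing_mm in-plane spacing.
#' @param noise_sd,bias_amplitude corruption levels for all drawn specs.
#' @return function taking a seed and returning a [phantom_spec()].
#' @export
make_spec_sampler <- function(grid_size = 128, pixel_spacing_mm = 1.5,
                              noise_sd = 10, bias_amplitude = 0.2) {
  force(grid_size); force(pixel_spacing_mm); force(noise_sd); force(bias_amplitude)
  function(seed) {
    with_seed(seed, {
      r_endo <- runif(1, 12, 18)
      wall <- runif(1, 8, 12)
      half_fov <- grid_size * pixel_spacing_mm / 2
      # keep the epicardium inside the field of view
      r_epi <- min(r_endo + wall, 0.9 * half_fov)
      ctr_jit <- runif(2, -0.05, 0.05) * grid_size
      phantom_spec(grid_size = grid_size,
                   pixel_spacing_mm = pixel_spacing_mm,
                   center = (grid_size - 1) / 2 + ctr_jit,
                   r_endo_mm = min(r_endo, r_epi - 4),
                   r_epi_mm = r_epi,
                   scar_start_deg = runif(1, 0, 360),
                   scar_extent_deg = runif(1, 40, 160),
                   scar_transmurality = runif(1, 0.4, 1),
                   intensity_blood = runif(1, 160, 200),
                   intensity_myo = runif(1, 50, 70),
                   intensity_scar = runif(1, 140, 180),
                   intensity_bg = runif(1, 15, 25),
                   noise_sd = noise_sd,
                   bias_amplitude = bias_amplitude,
                   seed = derive_seed(seed, 17))
    })
  }
}

#' Generate a cohort of synthetic subjects
#'
#' Each subject receives one spec from `spec_sampler`; its slices share that
#' anatomy and differ only in their noise/bias realizations (derived seeds).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param spec_sampler function(seed) -> `phantom_spec`; default
#'   [make_spec_sampler()].
#' @param slices_per_subject slices per subject.
#' @param seed master seed.
#' @return list of [slice_record()]s with an attribute `burden`: a data.frame
#'   (subject_id, scar_pixels) of per-subject total scar burden.
#' @export
generate_cohort <- function(n_subjects, spec_sampler = make_spec_sampler(),
                            slices_per_subject = 3, seed = 1) {
  stopifnot_scalar_num(n_subjects, "n_subjects", lo = 1)
  records <- vector("list", n_subjects * slices_per_subject)
  burden <- numeric(n_subjects)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    spec <- spec_sampler(derive_seed(seed, i))
    for (s in seq_len(slices_per_subject)) {
      sl_spec <- spec
      sl_spec$seed <- derive_seed(spec$seed, 1000 + s)
      rec <- generate_slice(sl_spec, subject_id = ids[i], slice_index = s)
      k <- k + 1L
      records[[k]] <- rec
      burden[i] <- burden[i] + sum(rec$scar_mask)
    }
  }
  attr(records, "burden") <- data.frame(subject_id = ids, scar_pixels = burden,
                                        stringsAsFactors = FALSE)
  records
}

#' Subject-level stratified split by total scar burden
#'
#' Subjects are binned into quantile strata of scar burden and allocated to
#' train/validation/test within each stratum, so that infarct size is
#' balanced across splits. The split is at subject level: no subject appears
#' in two sets.
#'
#' @param cohort list of [slice_record()]s (as from [generate_cohort()]), or a
#'   data.frame with columns `subject_id`, `scar_pixels`.
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param n_strata number of quantile bins (default 4); reduced with a warning
#'   when there are fewer subjects than strata.
#' @param seed RNG seed for within-stratum shuffling.
#' @return list with character vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(cohort, fractions = c(0.70, 0.15, 0.15),
                             n_strata = 4, seed = 1) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three numbers summing to 1", call. = FALSE)
  }
  burden <- if (is.data.frame(cohort)) cohort else attr(cohort, "burden")
  if (is.null(burden)) {
    ids <- vapply(cohort, function(r) r$subject_id, character(1))
    px <- vapply(cohort, function(r) sum(r$scar_mask), numeric(1))
    burden <- aggregate(list(scar_pixels = px), list(subject_id = ids), sum)
  }
  n <- nrow(burden)
  if (n < n_strata) {
    warning(sprintf("fewer subjects (%d) than strata (%d); using %d strata",
                    n, n_strata, max(1, n)))
    n_strata <- max(1, n)
  }
  # global target sizes: cumulative rounding gives exact total
  cum <- round(cumsum(fractions) * n)
  target <- diff(c(0, cum))
  qs <- quantile(burden$scar_pixels, probs = seq(0, 1, length.out = n_strata + 1),
                 type = 7)
  strat <- cut(burden$scar_pixels, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
  strat[is.na(strat)] <- 1L
  sets <- list(character(0), character(0), character(0))
  remaining <- target
  with_seed(seed, {
    for (s in sort(unique(strat))) {
      ids_s <- sample(burden$subject_id[strat == s])
      ns <- length(ids_s)
      # within-stratum quota by largest remainder, capped by global remainder
      quota <- remaining / sum(remaining) * ns
      base <- floor(quota)
      extra <- ns - sum(base)
      if (extra > 0) {
        ord <- order(quota - base, decreasing = TRUE)
        base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
      }
      base <- pmin(base, remaining)
      # any residue (from capping) goes to sets with spare capacity
      while (sum(base) < ns) {
        j <- which.max(remaining - base)
        base[j] <- base[j] + 1
      }
      idx <- rep(seq_len(3), times = base)
      for (j in 1:3) sets[[j]] <- c(sets[[j]], ids_s[idx == j])
      remaining <- remaining - base
    }
  })
  list(train = sets[[1]], val = sets[[2]], test = sets[[3]])
}

#' Simulate a rater drawing a prompt for a ground-truth mask
#'
#' Models imperfect human prompt placement: the tight box around the mask is
#' shifted by a Gaussian offset (`shift_sd_px` per axis) and each dimension
#' rescaled by a factor `1 + N(0, expand_sd_frac)` about the box center, then
#' `n_points` foreground points are sampled inside the mask. Distinct seeds
#' model distinct raters or rounds.
#'
#' @param gt_mask non-empty binary matrix.
#' @param jitter numeric length-2: (shift_sd_px, expand_sd_frac).
#' @param n_points number of positive points.
#' @param seed RNG seed.
#' @return a [make_prompt()] style prompt (strategy "box_and_points").
#' @export
simulate_rater <- function(gt_mask, jitter = c(3, 0.05), n_points = 3, seed = 1) {
  if (sum(gt_mask) == 0) stop("gt_mask is empty", call. = FALSE)
  box <- bbox_from_mask(gt_mask)
  n <- dim(gt_mask)
  with_seed(seed, {
    shift <- rnorm(2, 0, jitter[1])
    fac <- 1 + rnorm(2, 0, jitter[2])
    h <- (box[3] - box[1]) * fac[1]
    w <- (box[4] - box[2]) * fac[2]
    cr <- (box[1] + box[3]) / 2 + shift[1]
    cc <- (box[2] + box[4]) / 2 + shift[2]
    b <- c(round(cr - h / 2), round(cc - w / 2), round(cr + h / 2), round(cc + w / 2))
    b <- clamp_box(b, n)
    pts_seed <- derive_seed(seed, 3)
    prompt(box = b,
           points = sample_points(gt_mask, n_range = c(n_points, n_points),
                                  seed = pts_seed),
           strategy = "box_and_points")
  })
}
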
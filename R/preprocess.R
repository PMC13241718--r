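# Slice standardization: bicubic resampling to the model grid with preserved
# anatomical aspect ratio, then per-slice percentile clipping and z-scoring.

#' Preprocessing configuration
#'
#' @param target_size side length of the model grid in pixels (default 256).
#' @param clip_lo,clip_hi intensity clipping percentiles (defaults 0.1 and
#'   99.9).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = 256, clip_lo = 0.1, clip_hi = 99.9) {
  stopifnot_scalar_num(target_size, "target_size", lo = 16)
  stopifnot_scalar_num(clip_lo, "clip_lo", lo = 0, hi = 100)
  stopifnot_scalar_num(clip_hi, "clip_hi", lo = 0, hi = 100)
  if (clip_lo >= clip_hi) stop("clip_lo must be below clip_hi", call. = FALSE)
  structure(list(target_size = as.integer(target_size),
                 clip_lo = clip_lo, clip_hi = clip_hi),
            class = "preprocess_config")
}

#' Resample a slice to the model grid
#'
#' The image is resampled bicubically and masks with nearest-neighbour (so
#' they stay exactly binary). Both axes are scaled by the same physical
#' factor — the spacing of the output grid is chosen so that the larger
#' physical extent fits `target_size` pixels — and the shorter axis is padded
#' symmetrically with the image minimum, preserving the anatomical aspect
#' ratio. Output spacings are rescaled so the physical field of view is
#' unchanged.
#'
#' @param slice a [slice_record()] with known geometry.
#' @param config a [preprocess_config()].
#' @return resampled [slice_record()].
#' @export
resample_to_grid <- function(slice, config = preprocess_config()) {
  g <- slice$geometry
  if (is.null(g)) {
    stop("slice has no geometry; supply pixel spacing (voxel_geometry) before resampling",
         call. = FALSE)
  }
  ts <- config$target_size
  h_mm <- nrow(slice$image) * g$row_spacing_mm
  w_mm <- ncol(slice$image) * g$col_spacing_mm
  new_sp <- max(h_mm, w_mm) / ts
  out_r <- max(1L, min(ts, as.integer(round(h_mm / new_sp))))
  out_c <- max(1L, min(ts, as.integer(round(w_mm / new_sp))))

  pad_to <- function(m, value) {
    if (nrow(m) == ts && ncol(m) == ts) return(m)
    out <- matrix(value, ts, ts)
    r0 <- (ts - nrow(m)) %/% 2
    c0 <- (ts - ncol(m)) %/% 2
    out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
    out
  }
  img <- resize_image(slice$image, out_r, out_c, method = "bicubic")
  img <- pad_to(img, min(slice$image))
  resample_mask <- function(m) {
    if (is.null(m)) return(NULL)
    pad_to(as_binary(resize_image(m, out_r, out_c, method = "nearest")), 0)
  }
  slice_record(img,
               voxel_geometry(new_sp, new_sp, g$thickness_mm),
               myo_mask = resample_mask(slice$myo_mask),
               scar_mask = resample_mask(slice$scar_mask),
               exclusion_mask = resample_mask(slice$exclusion_mask),
               subject_id = slice$subject_id, slice_index = slice$slice_index)
}

#' Per-slice intensity normalization
#'
#' Pixel values are clipped at the `clip_lo` / `clip_hi` percentiles (linear
#' interpolation over the whole slice), then z-scored using the population
#' (1/N) standard deviation computed after clipping. Each slice is normalized
#' independently. A constant slice returns all zeros with a warning.
#'
#' @param slice a [slice_record()].
#' @param config a [preprocess_config()].
#' @return normalized [slice_record()].
#' @export
normalize_intensity <- function(slice, config = preprocess_config()) {
  x <- slice$image
  q <- quantile(x, probs = c(config$clip_lo, config$clip_hi) / 100,
                names = FALSE, type = 7)
  x <- pmin(pmax(x, q[1]), q[2])
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) {
    warning("constant slice: returning all zeros")
    x[] <- 0
  } else {
    x <- (x - mu) / sd_pop
  }
  out <- slice
  out$image <- x
  out
}

#' Standard preprocessing: resample then normalize
#'
#' @inheritParams resample_to_grid
#' @return preprocessed [slice_record()].
#' @export
preprocess_slice <- function(slice, config = preprocess_config()) {
  normalize_intensity(resample_to_grid(slice, config), config)
}
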
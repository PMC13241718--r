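# Image sampling and resizing primitives.
#
# Bicubic interpolation uses the Keys convolution kernel with a = -0.5 (the
# conventional "bicubic" of image processing); borders are handled by
# replicating the edge pixel. All samplers take 1-based continuous pixel
# coordinates at pixel centers.

cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

#' Sample an image at continuous coordinates
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of equal length; 1-based row/col coordinates at
#'   pixel centers.
#' @param method one of "bicubic", "bilinear", "nearest".
#' @return numeric vector of sampled values.
#' @keywords internal
sample_image <- function(img, r, c, method = c("bicubic", "bilinear", "nearest")) {
  method <- match.arg(method)
  nr <- nrow(img); nc <- ncol(img)
  if (method == "nearest") {
    ri <- clamp_idx(as.integer(round(r)), nr)
    ci <- clamp_idx(as.integer(round(c)), nc)
    return(img[cbind(ri, ci)])
  }
  if (method == "bilinear") {
    r0 <- clamp_idx(floor(r), nr); c0 <- clamp_idx(floor(c), nc)
    r1 <- clamp_idx(r0 + 1, nr);   c1 <- clamp_idx(c0 + 1, nc)
    fr <- pmin(pmax(r - floor(r), 0), 1); fc <- pmin(pmax(c - floor(c), 0), 1)
    v00 <- img[cbind(r0, c0)]; v01 <- img[cbind(r0, c1)]
    v10 <- img[cbind(r1, c0)]; v11 <- img[cbind(r1, c1)]
    return((1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11))
  }
  # bicubic: 4x4 neighborhood around floor(r), floor(c)
  rf <- floor(r); cf <- floor(c)
  fr <- r - rf; fc <- c - cf
  out <- numeric(length(r))
  wr <- list(); wc <- list()
  for (k in 1:4) {
    wr[[k]] <- cubic_kernel(fr - (k - 2))
    wc[[k]] <- cubic_kernel(fc - (k - 2))
  }
  for (i in 1:4) {
    ri <- clamp_idx(rf + (i - 2), nr)
    rowacc <- numeric(length(r))
    for (j in 1:4) {
      ci <- clamp_idx(cf + (j - 2), nc)
      rowacc <- rowacc + wc[[j]] * img[cbind(ri, ci)]
    }
    out <- out + wr[[i]] * rowacc
  }
  out
}

#' Resize a 2-D image to a new grid
#'
#' Pixel centers are aligned so that the physical field of view is preserved.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols target dimensions.
#' @param method interpolation method passed to [sample_image()].
#' @return numeric matrix `out_rows` x `out_cols`.
#' @keywords internal
resize_image <- function(img, out_rows, out_cols, method = "bicubic") {
  nr <- nrow(img); nc <- ncol(img)
  if (out_rows == nr && out_cols == nc) return(img)
  rq <- (seq_len(out_rows) - 0.5) * (nr / out_rows) + 0.5
  cq <- (seq_len(out_cols) - 0.5) * (nc / out_cols) + 0.5
  R <- matrix(rq, out_rows, out_cols)
  C <- matrix(cq, out_rows, out_cols, byrow = TRUE)
  matrix(sample_image(img, as.vector(R), as.vector(C), method = method),
         out_rows, out_cols)
}

#' Separable Gaussian filter with reflective boundaries
#'
#' Kernel truncated at 4 standard deviations and normalized to unit sum, so
#' constants are preserved and mass is conserved away from borders.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` returns the input.
#' @return filtered matrix.
#' @keywords internal
gaussian_filter2d <- function(img, sigma) {
  stopifnot_scalar_num(sigma, "sigma", lo = 0)
  if (sigma == 0) return(img)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, kern, rad) {
    n <- nrow(m)
    # mirror padding (edge sample not repeated)
    pm <- rbind(m[clamp_idx(rad:1 + 1, n), , drop = FALSE], m,
                m[clamp_idx(n - (1:rad), n), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(kern)) {
      out <- out + kern[t] * pm[(t - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  out <- conv1(img, k, rad)
  t(conv1(t(out), k, rad))
}
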
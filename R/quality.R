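# Per-slice image-quality and heterogeneity metrics, plus cluster-structure
# analysis of the resulting feature vectors.

#' Image-quality metrics of a slice
#'
#' SNR and CNR are measured between scar and healthy myocardium (healthy =
#' myocardium minus scar): `SNR = mean(scar) / sd(healthy)` (set
#' `snr_numerator = "myo"` to use the healthy-myocardium signal instead) and
#' `CNR = |mean(scar) - mean(healthy)| / sd(healthy)`. Entropy (base-2
#' Shannon, 256-bin histogram) and dynamic range are computed on the image
#' min-max rescaled to 8-bit [0, 255]; the intensity coefficient of
#' variation is `100 * sd / mean` over the raw slice.
#'
#' @param slice a [slice_record()]; SNR/CNR require `myo_mask` and
#'   `scar_mask` and are `NA` otherwise.
#' @param snr_numerator "scar" or "myo".
#' @return one-row data.frame: snr, cnr, entropy_bits, dynamic_range,
#'   intensity_cov_pct, scar_pixels.
#' @export
quality_metrics <- function(slice, snr_numerator = c("scar", "myo")) {
  snr_numerator <- match.arg(snr_numerator)
  img <- slice$image
  snr <- cnr <- NA_real_
  scar_px <- if (is.null(slice$scar_mask)) NA_integer_ else sum(slice$scar_mask > 0)
  if (!is.null(slice$myo_mask) && !is.null(slice$scar_mask)) {
    healthy <- slice$myo_mask > 0 & slice$scar_mask == 0
    scar <- slice$scar_mask > 0
    if (sum(healthy) >= 2 && sum(scar) >= 1) {
      s_h <- sd(img[healthy])
      if (s_h > 0) {
        num <- if (snr_numerator == "scar") mean(img[scar]) else mean(img[healthy])
        snr <- num / s_h
        cnr <- abs(mean(img[scar]) - mean(img[healthy])) / s_h
      }
    }
  }
  rng <- range(img)
  if (rng[1] == rng[2]) {
    ent <- 0; dr <- 0
  } else {
    x8 <- floor((img - rng[1]) / (rng[2] - rng[1]) * 255.9999)
    p <- tabulate(x8 + 1, nbins = 256) / length(x8)
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
    dr <- max(x8) - min(x8)
  }
  cov_pct <- if (mean(img) == 0) NA_real_ else 100 * sd(img) / mean(img)
  data.frame(snr = snr, cnr = cnr, entropy_bits = ent, dynamic_range = dr,
             intensity_cov_pct = cov_pct, scar_pixels = scar_px)
}

mean_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) <= 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' K-means cluster-structure analysis of quality vectors
#'
#' Features are standardized to zero mean / unit SD, k-means (20 restarts,
#' seeded) is run for each candidate k, and the k maximizing the mean
#' silhouette is selected.
#'
#' @param vectors data.frame or matrix of per-slice quality features (rows =
#'   slices); columns with zero variance are dropped.
#' @param k_candidates integer vector of candidate cluster counts.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return list with `best_k`, `labels` (for best_k), and `silhouette`
#'   (named by k).
#' @export
cluster_quality <- function(vectors, k_candidates = 2:4, seed = 1, nstart = 20) {
  X <- as.matrix(vectors)
  X <- X[, apply(X, 2, function(col) sd(col) > 0), drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 vectors", call. = FALSE)
  if (ncol(X) == 0) stop("all features are constant; silhouette undefined", call. = FALSE)
  X <- scale(X)
  sil <- c(); labs <- list()
  for (k in k_candidates) {
    if (k >= nrow(X)) next
    fit <- with_seed(derive_seed(seed, k),
                     kmeans(X, centers = k, nstart = nstart, iter.max = 50))
    sil[as.character(k)] <- mean_silhouette(X, fit$cluster)
    labs[[as.character(k)]] <- fit$cluster
  }
  if (length(sil) == 0) stop("no feasible k in k_candidates", call. = FALSE)
  best <- names(sil)[which.max(sil)]
  list(best_k = as.integer(best), labels = labs[[best]], silhouette = sil)
}

#' Rank-sum comparison of a metric across two clusters
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test of `metric` between the
#' two label groups.
#'
#' @param metric numeric vector, one value per slice.
#' @param labels two-group labels aligned with `metric`.
#' @return list with `statistic` (W), `p_value`, group sizes.
#' @export
compare_groups <- function(metric, labels) {
  gs <- unique(labels)
  if (length(gs) != 2) stop("exactly two groups required", call. = FALSE)
  x <- metric[labels == gs[1]]; y <- metric[labels == gs[2]]
  if (length(x) == 0 || length(y) == 0) stop("a group is empty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n1 = length(x), n2 = length(y))
}
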
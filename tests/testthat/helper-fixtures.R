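# Shared fixtures, built in code.

quiet_spec <- function(...) {
  phantom_spec(noise_sd = 0, bias_amplitude = 0, ...)
}

# small disc mask centered at (cr, cc) 0-based, radius in px
disc_mask <- function(n, cr, cc, radius) {
  r <- matrix(0:(n - 1), n, n)
  c <- t(r)
  ((r - cr)^2 + (c - cc)^2 <= radius^2) * 1
}

random_mask <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * n, 1, p), n, n)
}

# brute-force pixel-loop Dice
oracle_dsc <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] > 0) sa <- sa + 1
    if (b[i, j] > 0) sb <- sb + 1
    if (a[i, j] > 0 && b[i, j] > 0) inter <- inter + 1
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# brute-force Hausdorff over boundary sets (4-adjacency boundary)
oracle_hausdorff <- function(a, b, rs, cs) {
  bnd <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (m[i, j] > 0) {
        nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < nr) m[i + 1, j] else 0,
                if (j > 1) m[i, j - 1] else 0, if (j < nc) m[i, j + 1] else 0)
        if (any(nb == 0) || i == 1 || i == nr || j == 1 || j == nc) {
          out <- rbind(out, c(i - 1, j - 1))
        }
      }
    }
    out
  }
  A <- bnd(a); B <- bnd(b)
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt(((P[i, 1] - Q[j, 1]) * rs)^2 + ((P[i, 2] - Q[j, 2]) * cs)^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

oracle_box_iou <- function(a, b, n = 40) {
  # pixel-rasterized IoU on an n x n grid (boxes are half-open, 0-based)
  fill <- function(bx) {
    m <- matrix(0, n, n)
    if (bx[1] < bx[3] && bx[2] < bx[4]) {
      m[(bx[1] + 1):bx[3], (bx[2] + 1):bx[4]] <- 1
    }
    m
  }
  ma <- fill(a); mb <- fill(b)
  un <- sum(ma | mb)
  if (un == 0) return(0)
  sum(ma & mb) / un
}
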
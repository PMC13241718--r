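# Box and point prompts conditioning a segmentation.
#
# Boxes are 0-based half-open rectangles (r0, c0, r1, c1): rows r0..r1-1 and
# cols c0..c1-1 are inside. Points are 0-based (row, col) pairs.

PROMPT_STRATEGIES <- c("box_only", "points_only", "box_and_points", "detector")

#' Construct a prompt
#'
#' @param box optional numeric length-4 (r0, c0, r1, c1), half-open, 0-based.
#' @param points optional n x 2 matrix of (row, col) foreground points.
#' @param strategy one of "box_only", "points_only", "box_and_points",
#'   "detector"; must be consistent with the populated fields.
#' @return object of class `prompt`.
#' @export
prompt <- function(box = NULL, points = NULL, strategy = "box_and_points") {
  strategy <- match.arg(strategy, PROMPT_STRATEGIES)
  if (!is.null(box)) {
    stopifnot(length(box) == 4)
    if (box[1] >= box[3] || box[2] >= box[4]) {
      stop("box must be non-empty: r0 < r1 and c0 < c1", call. = FALSE)
    }
  }
  if (!is.null(points)) {
    points <- matrix(as.numeric(points), ncol = 2)
  }
  needs_box <- strategy %in% c("box_only", "box_and_points", "detector")
  needs_pts <- strategy %in% c("points_only", "box_and_points")
  if (needs_box && is.null(box)) stop("strategy '", strategy, "' requires a box", call. = FALSE)
  if (needs_pts && is.null(points)) stop("strategy '", strategy, "' requires points", call. = FALSE)
  if (strategy == "box_only") points <- NULL
  if (strategy == "points_only") box <- NULL
  structure(list(box = if (is.null(box)) NULL else as.numeric(box),
                 points = points, strategy = strategy),
            class = "prompt")
}

clamp_box <- function(box, grid_dim) {
  b <- c(max(box[1], 0), max(box[2], 0),
         min(box[3], grid_dim[1]), min(box[4], grid_dim[2]))
  # never empty: fall back to at least one pixel
  if (b[1] >= b[3]) { b[1] <- max(0, min(box[1], grid_dim[1] - 1)); b[3] <- b[1] + 1 }
  if (b[2] >= b[4]) { b[2] <- max(0, min(box[2], grid_dim[2] - 1)); b[4] <- b[2] + 1 }
  b
}

#' Minimal enclosing box of a mask with a safety margin
#'
#' @param mask non-empty binary matrix.
#' @param margin_px margin added on each side (default 2), clamped to the grid.
#' @return numeric length-4 box (r0, c0, r1, c1), half-open, 0-based.
#' @export
bbox_from_mask <- function(mask, margin_px = 2) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  r0 <- min(idx[, 1]) - 1; r1 <- max(idx[, 1])    # to 0-based half-open
  c0 <- min(idx[, 2]) - 1; c1 <- max(idx[, 2])
  clamp_box(c(r0 - margin_px, c0 - margin_px, r1 + margin_px, c1 + margin_px),
            dim(mask))
}

#' Randomly perturb a box to simulate inconsistent placement
#'
#' The whole box is shifted by one integer offset pair drawn uniformly in
#' `[-max_shift_px, max_shift_px]`, then width and height are scaled up by a
#' uniform factor in `[1, 1 + max_expand_frac]` about the center
#' (`mode = "whole_box"`, the default). `mode = "per_edge"` instead jitters
#' each edge independently. Output is clamped to the grid and never empty.
#'
#' @param box length-4 half-open box.
#' @param grid_dim image dimensions (rows, cols) used for clamping.
#' @param max_shift_px maximum absolute integer shift (default 10).
#' @param max_expand_frac maximum fractional expansion (default 0.20).
#' @param seed RNG seed.
#' @param mode "whole_box" or "per_edge".
#' @return length-4 box.
#' @export
augment_box <- function(box, grid_dim, max_shift_px = 10, max_expand_frac = 0.20,
                        seed = 1, mode = c("whole_box", "per_edge")) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "whole_box") {
      sh <- sample(seq(-max_shift_px, max_shift_px), 2, replace = TRUE)
      f <- runif(1, 1, 1 + max_expand_frac)
      cr <- (box[1] + box[3]) / 2 + sh[1]
      cc <- (box[2] + box[4]) / 2 + sh[2]
      h <- (box[3] - box[1]) * f
      w <- (box[4] - box[2]) * f
      b <- c(round(cr - h / 2), round(cc - w / 2),
             round(cr + h / 2), round(cc + w / 2))
    } else {
      d <- sample(seq(-max_shift_px, max_shift_px), 4, replace = TRUE)
      b <- box + d
      f <- runif(1, 1, 1 + max_expand_frac)
      cr <- (b[1] + b[3]) / 2; cc <- (b[2] + b[4]) / 2
      b <- c(round(cr - (b[3] - b[1]) * f / 2), round(cc - (b[4] - b[2]) * f / 2),
             round(cr + (b[3] - b[1]) * f / 2), round(cc + (b[4] - b[2]) * f / 2))
    }
    clamp_box(b, grid_dim)
  })
}

#' Sample positive points inside a mask
#'
#' The number of points is drawn uniformly from `n_range` (capped at the
#' foreground size); points are sampled uniformly without replacement from
#' the foreground pixels.
#'
#' @param mask non-empty binary matrix.
#' @param n_range integer length-2 range of point counts (default 2..10).
#' @param seed RNG seed.
#' @return n x 2 matrix of 0-based (row, col) points.
#' @export
sample_points <- function(mask, n_range = c(2, 10), seed = 1) {
  fg <- which(mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("mask is empty", call. = FALSE)
  with_seed(seed, {
    n <- if (n_range[1] == n_range[2]) n_range[1] else
      sample(seq(n_range[1], n_range[2]), 1)
    n <- min(n, nrow(fg))
    sel <- sample.int(nrow(fg), n)
    cbind(row = fg[sel, 1] - 1, col = fg[sel, 2] - 1)
  })
}

#' Build a prompt for a mask under a given strategy
#'
#' For box strategies the box is the mask's [bbox_from_mask()]; the
#' "detector" strategy instead passes an externally supplied box through
#' unchanged (the abstract detector seam).
#'
#' @param mask binary matrix (required unless strategy is "detector" with
#'   `detector_box` supplied and no points are needed).
#' @param strategy prompting strategy.
#' @param seed RNG seed for point sampling.
#' @param n_range point count range for strategies that sample points.
#' @param detector_box externally supplied box for the "detector" strategy.
#' @return a [prompt()].
#' @export
make_prompt <- function(mask = NULL, strategy = "box_and_points", seed = 1,
                        n_range = c(2, 10), detector_box = NULL) {
  strategy <- match.arg(strategy, PROMPT_STRATEGIES)
  if (strategy == "detector") {
    if (is.null(detector_box)) stop("detector strategy requires `detector_box`", call. = FALSE)
    return(prompt(box = detector_box, strategy = "detector"))
  }
  if (is.null(mask)) stop("strategy '", strategy, "' requires a mask", call. = FALSE)
  box <- if (strategy %in% c("box_only", "box_and_points")) bbox_from_mask(mask) else NULL
  pts <- if (strategy %in% c("points_only", "box_and_points")) {
    sample_points(mask, n_range = n_range, seed = seed)
  } else NULL
  prompt(box = box, points = pts, strategy = strategy)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b length-4 half-open boxes.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  area <- function(x) (x[3] - x[1]) * (x[4] - x[2])
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Serialize / deserialize a prompt to JSON
#'
#' Format: `{"box": [r0,c0,r1,c1], "points": [[r,c],...], "strategy": "..."}`.
#' @param p a [prompt()].
#' @return JSON string.
#' @export
prompt_to_json <- function(p) {
  jsonlite::toJSON(list(box = p$box,
                        points = if (is.null(p$points)) NULL else unname(apply(p$points, 1, as.numeric, simplify = FALSE)),
                        strategy = p$strategy),
                   auto_unbox = TRUE, null = "null", digits = NA)
}

#' @rdname prompt_to_json
#' @param json JSON string as produced by [prompt_to_json()].
#' @export
prompt_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  pts <- if (is.null(x$points)) NULL else if (is.matrix(x$points)) x$points else
    do.call(rbind, x$points)
  prompt(box = x$box, points = pts, strategy = x$strategy)
}
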
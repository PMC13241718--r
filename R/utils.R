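#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in scarseg route their randomness through this
#' helper so that identical seeds give identical results without clobbering
#' the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @param seed parent seed.
#' @param stream integer stream index.
#' @return numeric seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483629
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if ((strict_lo && x <= lo) || (!strict_lo && x < lo) || x > hi) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same grid shape (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

as_binary <- function(mask) {
  storage.mode(mask) <- "double"
  (mask > 0.5) * 1
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 1))
}
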
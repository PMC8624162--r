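#' @keywords internal
"_PACKAGE"

# Image batches are 4-D arrays with dim = c(channels, height, width, batch).
# Helpers below normalize inputs to that layout and provide seeded RNG.

#' Coerce an array to the channel-first image-batch layout
#'
#' Accepts a 2-D matrix (height x width, single image), a 3-D array
#' (c, h, w) or a 4-D array (c, h, w, n) and returns a 4-D array.
#'
#' @param x numeric array.
#' @return 4-D array with dim `c(c, h, w, n)`.
#' @export
as_image_batch <- function(x) {
  if (is.null(dim(x))) stop("expected an array, got a bare vector", call. = FALSE)
  d <- dim(x)
  if (length(d) == 2L) {
    dim(x) <- c(1L, d[1L], d[2L], 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop("expected a 2-, 3- or 4-D array", call. = FALSE)
  }
  x
}

batch_size <- function(x) dim(x)[4L]
n_channels <- function(x) dim(x)[1L]

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# Per-sample sum over (c, h, w), returns length-n vector.
per_sample_sum <- function(x) {
  d <- dim(x)
  colSums(matrix(x, prod(d[1:3]), d[4L]))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of sub-seeds from one integer seed (kept below 2^31).
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1009 * k) %% 2147483587)
}

#' Pad an image batch to spatial multiples of a power of two
#'
#' Multi-scale flows require height and width divisible by `2^(L-1)`;
#' odd sizes are never padded implicitly because invertibility must be
#' exact. This utility zero-pads on the bottom/right edges.
#'
#' @param x image batch (coerced by [as_image_batch()]).
#' @param multiple positive integer the spatial sizes must divide into.
#' @return padded 4-D array.
#' @export
pad_to_multiple <- function(x, multiple) {
  x <- as_image_batch(x)
  d <- dim(x)
  h2 <- as.integer(ceiling(d[2L] / multiple) * multiple)
  w2 <- as.integer(ceiling(d[3L] / multiple) * multiple)
  if (h2 == d[2L] && w2 == d[3L]) return(x)
  out <- array(0, c(d[1L], h2, w2, d[4L]))
  out[, seq_len(d[2L]), seq_len(d[3L]), ] <- x
  out
}
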
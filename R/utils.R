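#' @keywords internal
"_PACKAGE"

# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of per-unit seeds from one base seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# Bounding box of a logical/label mask, padded and clipped to the image.
mask_bbox <- function(mask, pad = 1L) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(
    r = max(1L, min(idx[, 1L]) - pad):min(nrow(mask), max(idx[, 1L]) + pad),
    c = max(1L, min(idx[, 2L]) - pad):min(ncol(mask), max(idx[, 2L]) + pad)
  )
}

# Distance (in px) of every pixel to the nearest pixel NOT in `mask`,
# treating everything outside the matrix as background.
dist_to_complement <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask != 0)
  d <- EBImage::distmap(m)
  matrix(d, nrow(m), ncol(m))[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
}

# Distance of every pixel to the nearest pixel IN `mask` (0 inside mask).
dist_to_mask <- function(mask) {
  if (!any(mask != 0)) stop("dist_to_mask: empty mask", call. = FALSE)
  dist_to_complement(mask == 0)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) > 2L) {
    if (all(dim(x)[-(1:2)] == 1L)) dim(x) <- dim(x)[1:2]
    else stop("expected a 2D single-channel image", call. = FALSE)
  }
  if (!is.matrix(x)) stop("expected a 2D matrix image", call. = FALSE)
  x
}

# Relabel positive labels to contiguous 1..n keeping order of first appearance
# by label value; returns integer matrix.
relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(u)) out[] <- match(labels, u, nomatch = 0L)
  out
}
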
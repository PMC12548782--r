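#' Detect diffraction-limited spots and integrate per-cell signal
#'
#' White-top-hat enhancement with a disc of `tophat_radius`, robust
#' thresholding at `median + k * MAD` of the enhanced image, size filtering,
#' and assignment of each spot to the cell containing its centroid. The
#' integrated signal of a spot is the sum of its pixel intensities above the
#' local background, estimated as the median intensity in a 2-px annulus
#' around the spot. Because the threshold is MAD-relative, spot counts are
#' invariant under multiplication of the channel by a positive constant.
#'
#' @param spot_channel 2D intensity matrix.
#' @param cells cells `LabelMap` aligned to the channel (or `NULL` to treat
#'   the whole field as one cell).
#' @param tophat_radius disc radius (px) of the top-hat structuring element.
#' @param k MAD multiplier of the detection threshold.
#' @param min_area,max_area admissible spot areas, px^2.
#' @return list with `spots` (data.frame: `spot`, `cell`, `row`, `col`,
#'   `area`, `integrated_signal`) and `per_cell` (data.frame: `cell`,
#'   `n_spots`, `integrated_signal`, one row per cell label including
#'   spotless cells).
#' @export
detect_spots <- function(spot_channel, cells = NULL, tophat_radius = 4,
                         k = 5, min_area = 2, max_area = 90) {
  img <- as_matrix(spot_channel)
  clab <- if (is.null(cells)) matrix(1L, nrow(img), ncol(img))
          else as_matrix(cells)
  th <- as_matrix(EBImage::whiteTopHat(img / 65535, disc_brush(tophat_radius))) * 65535
  med <- stats::median(th)
  # MAD floored at 1% of the enhanced dynamic range so a noise-free
  # background (MAD = 0) still yields a meaningful threshold; the floor
  # scales with the image, preserving intensity-scale invariance
  madv <- max(stats::mad(th), 0.01 * (max(th) - med))
  if (madv <= 0) madv <- 1e-12
  thr <- med + k * madv
  lab <- as_matrix(EBImage::bwlabel(th > thr))
  lab <- relabel(drop_small(lab, min_area))

  n <- max(lab)
  rows <- vector("list", n)
  ann_brush <- disc_brush(2)
  for (i in seq_len(n)) {
    px <- lab == i
    area <- sum(px)
    if (area > max_area) next
    idx <- which(px, arr.ind = TRUE)
    cent <- round(colMeans(idx))
    cell <- clab[cent[1L], cent[2L]]
    if (cell == 0L) {                      # fall back to modal cell under spot
      under <- clab[px]
      under <- under[under > 0]
      cell <- if (length(under)) as.integer(names(which.max(table(under))))
              else 0L
    }
    bb <- mask_bbox(px, pad = 4L)
    sub <- px[bb$r, bb$c]
    ann <- as_matrix(EBImage::dilate(sub, ann_brush)) != 0 & !sub
    bg <- stats::median(img[bb$r, bb$c][ann])
    rows[[i]] <- data.frame(
      spot = i, cell = cell, row = cent[1L], col = cent[2L], area = area,
      integrated_signal = max(sum(img[px] - bg), 0))
  }
  spots <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(spots))
    spots <- data.frame(spot = integer(0), cell = integer(0),
                        row = integer(0), col = integer(0), area = integer(0),
                        integrated_signal = numeric(0))
  ncell <- max(clab)
  per_cell <- data.frame(
    cell = seq_len(ncell),
    n_spots = vapply(seq_len(ncell),
                     function(i) sum(spots$cell == i), integer(1)),
    integrated_signal = vapply(seq_len(ncell), function(i)
      sum(spots$integrated_signal[spots$cell == i]), numeric(1)))
  list(spots = spots, per_cell = per_cell)
}

#' Transwell migration ratio
#'
#' Ratio of total above-background fluorescence on the basal (trans) side of
#' the membrane to that on the top (cis) side, typically from an actin
#' channel. Each image is segmented by Otsu thresholding; the background is
#' the median intensity outside the foreground and is subtracted before
#' summing.
#'
#' @param trans_image,cis_image 2D intensity matrices.
#' @return the trans/cis ratio (dimensionless).
#' @export
transwell_ratio <- function(trans_image, cis_image) {
  tr <- above_background_total(as_matrix(trans_image))
  ci <- above_background_total(as_matrix(cis_image))
  if (ci <= 0)
    stop("cis image has no above-background signal; ratio undefined",
         call. = FALSE)
  tr / ci
}

above_background_total <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(0)
  thr <- resolve_threshold(img, "otsu")
  fg <- img > thr
  if (!any(fg)) return(0)
  bg <- stats::median(img[!fg])
  sum(img[fg] - bg)
}

#' Fraction of cells that migrated in a 3D invasion assay
#'
#' Cells are embedded in a collagen matrix and invade toward the plate
#' bottom; nuclei are counted at the plate bottom and at elevated optical
#' planes. The migrated percentage is `100 * bottom / (bottom + sum(planes))`
#' under the default convention (`migrated = "bottom"`); the opposite
#' convention is available and recorded in the result.
#'
#' @param bottom nuclei count at the plate bottom.
#' @param planes nuclei counts at the elevated planes.
#' @param migrated which compartment counts as migrated.
#' @return percentage in `[0, 100]` with attribute `"convention"`.
#' @export
invasion_fraction <- function(bottom, planes,
                              migrated = c("bottom", "planes")) {
  migrated <- match.arg(migrated)
  if (bottom < 0 || any(planes < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- bottom + sum(planes)
  if (total == 0) stop("total cell count is zero; fraction undefined",
                       call. = FALSE)
  num <- if (migrated == "bottom") bottom else sum(planes)
  structure(100 * num / total, convention = migrated)
}

#' Count nuclei on a stack of plane images
#'
#' Segments each optical plane with [segment_nuclei()] and returns per-plane
#' counts, for use with [invasion_fraction()].
#'
#' @param plane_images list of 2D DNA-channel matrices, bottom plane first.
#' @param ... passed to [segment_nuclei()].
#' @return integer vector of nuclei counts, one per plane.
#' @export
count_nuclei_planes <- function(plane_images, ...) {
  vapply(plane_images, function(img) max(segment_nuclei(img, ...)),
         integer(1))
}
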
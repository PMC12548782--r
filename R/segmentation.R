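#' Segment nuclei from a DNA-stain channel
#'
#' Gaussian smoothing, global thresholding (Otsu by default) and connected
#' component labeling; optionally, touching nuclei are split by a watershed on
#' the distance transform.
#'
#' @param dna_channel 2D intensity matrix (non-negative counts).
#' @param smoothing Gaussian sigma in px applied before thresholding
#'   (0 disables).
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param min_area minimum object area in px^2; smaller components are
#'   discarded.
#' @param split split touching nuclei with a distance-transform watershed.
#' @return A `LabelMap`: integer label matrix (0 = background) with attributes
#'   `kind = "nuclei"` and the parameters used.
#' @export
segment_nuclei <- function(dna_channel, smoothing = 2, threshold = "otsu",
                           min_area = 80, split = TRUE) {
  img <- as_matrix(dna_channel)
  if (any(img < 0)) stop("dna_channel must be non-negative", call. = FALSE)
  sm <- if (smoothing > 0) as_matrix(EBImage::gblur(img, sigma = smoothing))
        else img
  thr <- resolve_threshold(sm, threshold)
  mask <- sm > thr
  if (!any(mask))
    return(new_label_map(matrix(0L, nrow(img), ncol(img)), "nuclei",
                         list(smoothing = smoothing, threshold = thr,
                              min_area = min_area, split = split)))
  labels <- if (split) {
    dm <- EBImage::distmap(mask)
    as_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    as_matrix(EBImage::bwlabel(mask))
  }
  labels <- drop_small(labels, min_area)
  new_label_map(relabel(labels), "nuclei",
                list(smoothing = smoothing, threshold = thr,
                     min_area = min_area, split = split))
}

#' Segment cell bodies around nuclear seeds
#'
#' Seeded region growing (Voronoi propagation weighted by image gradient) of
#' the above-threshold foreground of a cytoplasmic/body channel, one cell per
#' nucleus. With `method = "nearest-seed"` the propagation is purely
#' geometric, assigning each foreground pixel to the nearest nucleus.
#'
#' @param nuclei nuclei `LabelMap` from [segment_nuclei()].
#' @param body_channel 2D intensity matrix aligned to `nuclei`.
#' @param threshold `"otsu"` or a fixed intensity threshold defining the
#'   foreground.
#' @param method `"srg"` (intensity-weighted seeded region growing) or
#'   `"nearest-seed"`.
#' @param lambda regularization of [EBImage::propagate()]; larger values make
#'   boundaries more Euclidean.
#' @return A `LabelMap` of kind `"cells"`; cell labels equal their nucleus
#'   labels and every cell mask contains its nucleus.
#' @export
segment_cells <- function(nuclei, body_channel, threshold = "otsu",
                          method = c("srg", "nearest-seed"), lambda = 1e-4) {
  method <- match.arg(method)
  img <- as_matrix(body_channel)
  seeds <- as_matrix(nuclei)
  if (!all(dim(img) == dim(seeds)))
    stop("nuclei LabelMap and body_channel must have the same shape",
         call. = FALSE)
  if (max(seeds) == 0L)
    return(new_label_map(matrix(0L, nrow(img), ncol(img)), "cells",
                         list(threshold = NA, method = method)))
  thr <- resolve_threshold(img, threshold)
  fg <- img > thr
  orphan <- setdiff(unique(seeds[seeds > 0 & !fg]), unique(seeds[fg & seeds > 0]))
  if (length(orphan))
    warning(sprintf(
      "nucleus label(s) %s outside foreground; their cells are the nucleus footprint",
      paste(orphan, collapse = ", ")))
  fg <- fg | seeds > 0                      # cells always cover their nuclei
  if (method == "nearest-seed") lambda <- 1e8
  cells <- as_matrix(EBImage::propagate(img / max(img, 1), seeds,
                                        mask = fg, lambda = lambda))
  storage.mode(cells) <- "integer"
  new_label_map(cells, "cells",
                list(threshold = thr, method = method, lambda = lambda))
}

new_label_map <- function(labels, kind, params) {
  storage.mode(labels) <- "integer"
  structure(labels, kind = kind, params = params, class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap (%s): %d x %d px, %d objects\n",
              attr(x, "kind"), nrow(x), ncol(x), max(x)))
  invisible(x)
}

resolve_threshold <- function(img, threshold) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) return(rng[2L])    # flat image: nothing above
    return(EBImage::otsu(EBImage::Image(img / 65535), range = c(0, 1)) * 65535)
  }
  stop("threshold must be 'otsu' or a numeric value", call. = FALSE)
}

drop_small <- function(labels, min_area) {
  if (max(labels) == 0L) return(labels)
  tab <- tabulate(labels[labels > 0], nbins = max(labels))
  kill <- which(tab < min_area)
  if (length(kill)) labels[labels %in% kill] <- 0L
  labels
}

#' Quality-control flags for segmented cells
#'
#' Flags border-touching cells, cells with out-of-range area, and
#' out-of-focus cells. The focus score is the variance of the Laplacian of
#' the ER channel within the cell mask, normalized by the squared mean
#' intensity (dimensionless and invariant to intensity scaling); defocused
#' cells score low.
#'
#' @param cells cells `LabelMap`.
#' @param field `FieldImage` (or a named list of channel matrices) providing
#'   the ER channel.
#' @param min_area,max_area admissible cell area range, px^2.
#' @param focus_threshold cells with focus score below this are flagged
#'   out-of-focus. The default was calibrated once on the bundled synthetic
#'   fixture family (sharp vs. `blur_sigma >= 3` px).
#' @param er_channel channel name used for the focus score.
#' @return data.frame with one row per cell label: `label`, `area`, `border`,
#'   `area_out_of_range`, `focus_score`, `out_of_focus`, and `qc_pass` (no
#'   flag set).
#' @export
qc_filter <- function(cells, field, min_area = 400, max_area = 50000,
                      focus_threshold = 0.04, er_channel = "er") {
  labels <- as_matrix(cells)
  er <- as_matrix(if (inherits(field, "FieldImage"))
    field$channels[[er_channel]] else field[[er_channel]])
  if (!all(dim(er) == dim(labels)))
    stop("cells LabelMap and field must have the same shape", call. = FALSE)
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      border = logical(0), area_out_of_range = logical(0),
                      focus_score = numeric(0), out_of_focus = logical(0),
                      qc_pass = logical(0)))
  areas <- tabulate(labels[labels > 0], nbins = n)
  edge_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)]))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap_img <- as_matrix(EBImage::filter2(er, lap, boundary = 0))
  focus <- vapply(seq_len(n), function(i) {
    px <- labels == i
    mu <- mean(er[px])
    if (mu <= 0) return(0)
    stats::var(lap_img[px]) / mu^2
  }, numeric(1))
  out <- data.frame(
    label = seq_len(n), area = areas,
    border = seq_len(n) %in% edge_labels,
    area_out_of_range = areas < min_area | areas > max_area,
    focus_score = focus,
    out_of_focus = focus < focus_threshold)
  out$qc_pass <- !(out$border | out$area_out_of_range | out$out_of_focus)
  out
}
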
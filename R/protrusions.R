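#' Decompose a cell mask into body and protrusions
#'
#' The cell body is the morphological opening of the mask with a disc of
#' `opening_radius`; protrusions are the connected components of the
#' remainder with area at least `min_protrusion_area`. Each protrusion's
#' length is the geodesic (within-component) distance from its attachment to
#' the body out to its tip, and its orientation is the angle of the
#' attachment-to-tip vector (degrees, mathematical convention). Manually
#' segmented protrusion masks, when supplied, bypass the automatic
#' decomposition and are measured the same way.
#'
#' @param cell_mask logical matrix for a single cell.
#' @param opening_radius disc radius (px) of the opening defining the body.
#' @param min_protrusion_area minimum protrusion area, px^2.
#' @param manual_masks optional integer label matrix of manually segmented
#'   protrusions (same shape as `cell_mask`); the body is then
#'   `cell_mask & manual_masks == 0`.
#' @return A `ProtrusionSet`: list with `protrusions` (data.frame: `id`,
#'   `length`, `theta` absolute orientation, `alpha` angle to the longest
#'   protrusion folded to `[0, 180]`, `area`), `body_area`,
#'   `body_major_axis`, `n`. Ties in length resolve to the lowest component
#'   id.
#' @export
decompose_protrusions <- function(cell_mask, opening_radius = 8,
                                  min_protrusion_area = 20,
                                  manual_masks = NULL) {
  cm <- as_matrix(cell_mask) != 0
  if (!any(cm)) stop("empty cell mask", call. = FALSE)
  if (is.null(manual_masks)) {
    if (opening_radius <= 0) stop("opening_radius must be > 0", call. = FALSE)
    body <- as_matrix(EBImage::opening(cm, disc_brush(opening_radius))) != 0
    if (!any(body))
      stop("opening erased the whole cell; opening_radius too large",
           call. = FALSE)
    comp <- as_matrix(EBImage::bwlabel(cm & !body))
  } else {
    comp <- as_matrix(manual_masks)
    storage.mode(comp) <- "integer"
    body <- cm & comp == 0L
  }
  comp <- drop_small(comp, min_protrusion_area)
  comp <- relabel(comp)
  body_dil <- as_matrix(EBImage::dilate(body, disc_brush(1))) != 0

  n <- max(comp)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    px <- comp == i
    att <- px & body_dil                  # attachment: touches the body
    if (!any(att)) next                   # detached debris, not a protrusion
    gd <- geodesic_distance(px, att)
    # +1: geodesic is center-to-center, a run of n pixels spans n px
    len <- max(gd[is.finite(gd)]) + 1
    # tip = centroid of the far end of the geodesic field; averaging over the
    # tip region keeps the orientation estimate stable for blunt tips
    tip_idx <- which(is.finite(gd) & gd >= len - 2.5, arr.ind = TRUE)
    tip <- colMeans(tip_idx)
    att_idx <- which(att, arr.ind = TRUE)
    a_cent <- colMeans(att_idx)
    theta <- atan2(-(tip[1L] - a_cent[1L]),
                   tip[2L] - a_cent[2L]) * 180 / pi
    rows[[i]] <- data.frame(id = i, length = len, theta = theta,
                            area = sum(px))
  }
  prot <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(prot))
    prot <- data.frame(id = integer(0), length = numeric(0),
                       theta = numeric(0), area = integer(0))

  bm <- EBImage::computeFeatures.moment(matrix(as.integer(body), nrow(body)))
  ps <- list(protrusions = prot, body_area = sum(body),
             body_major_axis = unname(bm[1L, "m.majoraxis"]),
             n = nrow(prot))
  class(ps) <- "ProtrusionSet"
  set_alpha(ps)
}

# alpha_i: angle between protrusion i and the longest protrusion, folded to
# [0, 180]; the longest protrusion (lowest id on ties) has alpha = 0.
set_alpha <- function(ps) {
  p <- ps$protrusions
  if (nrow(p)) {
    longest <- which.max(p$length)        # ties -> lowest index
    alpha <- (p$theta - p$theta[longest]) %% 360
    alpha[alpha > 180] <- 360 - alpha[alpha > 180]
    p$alpha <- alpha
    ps$protrusions <- p[order(p$id), ]
  } else ps$protrusions$alpha <- numeric(0)
  ps
}

#' Build a ProtrusionSet from measured lengths and angles
#'
#' Convenience constructor when protrusion geometry is known (e.g. manual
#' measurements): angles are re-expressed relative to the longest protrusion.
#'
#' @param lengths protrusion lengths, px (all > 0).
#' @param angles absolute orientations, degrees.
#' @param body_major_axis cell-body major axis, px.
#' @param areas optional protrusion areas.
#' @return A `ProtrusionSet`.
#' @export
protrusion_set <- function(lengths, angles, body_major_axis = NA_real_,
                           areas = NA_real_) {
  if (length(lengths) != length(angles))
    stop("lengths and angles must have equal length", call. = FALSE)
  if (any(lengths <= 0)) stop("all lengths must be > 0", call. = FALSE)
  areas <- rep_len(areas, length(lengths))
  ps <- list(protrusions = data.frame(id = seq_along(lengths),
                                      length = lengths, theta = angles,
                                      area = areas),
             body_area = NA_real_, body_major_axis = body_major_axis,
             n = length(lengths))
  class(ps) <- "ProtrusionSet"
  set_alpha(ps)
}

#' @export
print.ProtrusionSet <- function(x, ...) {
  cat(sprintf("ProtrusionSet: %d protrusion(s), body major axis %.1f px\n",
              x$n, x$body_major_axis))
  if (x$n) print(x$protrusions, row.names = FALSE)
  invisible(x)
}

#' Protrusion polarity index
#'
#' `Pi = sum_i (1 - |sin(alpha_i)|) * L_i / sum_i L_i`, where `alpha_i` is
#' the angle between protrusion i and the longest protrusion and `L_i` its
#' length. The sum includes the longest protrusion itself (`alpha = 0`,
#' weight 1), so a single-protrusion cell has `Pi = 1`; antiparallel
#' protrusions (`alpha = 180`) also carry weight 1, as polarity is axial.
#'
#' @param p a `ProtrusionSet`.
#' @return `Pi` in `[0, 1]`, or `NA` (with `"reason"` attribute) for a cell
#'   without protrusions.
#' @export
polarity_index <- function(p) {
  stopifnot(inherits(p, "ProtrusionSet"))
  pr <- p$protrusions
  if (nrow(pr) == 0L) return(structure(NA_real_, reason = "no protrusions"))
  w <- 1 - abs(sin(pr$alpha * pi / 180))
  sum(w * pr$length) / sum(pr$length)
}

#' Relative length of the largest protrusion
#'
#' Length of the longest protrusion divided by the major axis of the cell
#' body.
#'
#' @param p a `ProtrusionSet` with a known `body_major_axis`.
#' @return the ratio, or `NA` (with `"reason"`) without protrusions.
#' @export
largest_protrusion_relative_length <- function(p) {
  stopifnot(inherits(p, "ProtrusionSet"))
  if (p$n == 0L) return(structure(NA_real_, reason = "no protrusions"))
  if (!is.finite(p$body_major_axis) || p$body_major_axis <= 0)
    stop("body major axis must be positive", call. = FALSE)
  max(p$protrusions$length) / p$body_major_axis
}

#' Protrusion metrics for every cell of a label map
#'
#' @param cells cells `LabelMap` (or integer label matrix).
#' @param opening_radius,min_protrusion_area passed to
#'   [decompose_protrusions()].
#' @return data.frame per cell: `label`, `n_protrusions`,
#'   `relative_protrusion_area` (total protrusion area / body area),
#'   `polarity_index`, `relative_largest_length`.
#' @export
protrusion_features <- function(cells, opening_radius = 8,
                                min_protrusion_area = 20) {
  clab <- as_matrix(cells)
  n <- max(clab)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    full <- clab == i
    if (!any(full)) next
    bb <- mask_bbox(full, pad = 2L)
    ps <- tryCatch(
      decompose_protrusions(full[bb$r, bb$c], opening_radius,
                            min_protrusion_area),
      error = function(e) NULL)
    rows[[i]] <- if (is.null(ps)) {
      data.frame(label = i, n_protrusions = NA_integer_,
                 relative_protrusion_area = NA_real_,
                 polarity_index = NA_real_,
                 relative_largest_length = NA_real_)
    } else {
      data.frame(
        label = i, n_protrusions = ps$n,
        relative_protrusion_area = if (ps$n)
          sum(ps$protrusions$area) / ps$body_area else 0,
        polarity_index = as.numeric(polarity_index(ps)),
        relative_largest_length = if (ps$n)
          as.numeric(largest_protrusion_relative_length(ps)) else NA_real_)
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Geodesic distance within `region` from the pixel set `sources`, using
# chamfer metric (1 for 4-neighbors, sqrt(2) diagonal), iterated forward and
# backward raster sweeps until convergence.
geodesic_distance <- function(region, sources) {
  nr <- nrow(region); nc <- ncol(region)
  d <- matrix(Inf, nr, nc)
  d[sources] <- 0
  d[!region] <- NA
  sq2 <- sqrt(2)
  repeat {
    changed <- FALSE
    for (j in seq_len(nc)) for (i in seq_len(nr)) {      # forward sweep
      if (is.na(d[i, j])) next
      v <- d[i, j]
      if (i > 1 && !is.na(d[i - 1, j])) v <- min(v, d[i - 1, j] + 1)
      if (j > 1 && !is.na(d[i, j - 1])) v <- min(v, d[i, j - 1] + 1)
      if (i > 1 && j > 1 && !is.na(d[i - 1, j - 1]))
        v <- min(v, d[i - 1, j - 1] + sq2)
      if (i < nr && j > 1 && !is.na(d[i + 1, j - 1]))
        v <- min(v, d[i + 1, j - 1] + sq2)
      if (v < d[i, j]) { d[i, j] <- v; changed <- TRUE }
    }
    for (j in rev(seq_len(nc))) for (i in rev(seq_len(nr))) { # backward sweep
      if (is.na(d[i, j])) next
      v <- d[i, j]
      if (i < nr && !is.na(d[i + 1, j])) v <- min(v, d[i + 1, j] + 1)
      if (j < nc && !is.na(d[i, j + 1])) v <- min(v, d[i, j + 1] + 1)
      if (i < nr && j < nc && !is.na(d[i + 1, j + 1]))
        v <- min(v, d[i + 1, j + 1] + sq2)
      if (i > 1 && j < nc && !is.na(d[i - 1, j + 1]))
        v <- min(v, d[i - 1, j + 1] + sq2)
      if (v < d[i, j]) { d[i, j] <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  d[!region] <- NA
  d
}
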
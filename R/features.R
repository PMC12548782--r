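#' Normalized radial coordinate of the cytoplasm
#'
#' For every cytoplasmic pixel p, computes
#' `d_n(p) = d_nuc(p) / (d_nuc(p) + d_edge(p))` where `d_nuc` is the
#' Euclidean distance to the nucleus mask and `d_edge` the distance to the
#' complement of the cell mask. `d_n` is 0 at the nuclear boundary and 1 at
#' the cell edge, so bands defined on it sit at constant *relative* distances
#' between the nuclear boundary and the cell edge for every cell, regardless
#' of cell size or shape.
#'
#' @param cell_mask,nucleus_mask logical matrices of the same shape; the
#'   nucleus must lie inside the cell.
#' @return numeric matrix with `d_n` on cytoplasmic pixels and `NA`
#'   elsewhere (including inside the nucleus).
#' @export
normalized_radial_coordinate <- function(cell_mask, nucleus_mask) {
  cm <- as_matrix(cell_mask) != 0
  nm <- as_matrix(nucleus_mask) != 0
  if (!all(dim(cm) == dim(nm)))
    stop("cell and nucleus masks must have the same shape", call. = FALSE)
  if (!any(nm)) stop("empty nucleus mask", call. = FALSE)
  if (any(nm & !cm))
    stop("nucleus mask is not contained in the cell mask", call. = FALSE)
  cyto <- cm & !nm
  if (!any(cyto))
    stop("cell has no cytoplasm (nucleus fills the cell mask)", call. = FALSE)
  # half-pixel correction: distance-map values are center-to-center, but the
  # mask boundary runs between pixel centers; without it bands drift with
  # cell size and the fixed-relative-distance property degrades
  d_nuc <- pmax(dist_to_mask(nm) - 0.5, 0)
  d_edge <- pmax(dist_to_complement(cm) - 0.5, 0)
  dn <- matrix(NA_real_, nrow(cm), ncol(cm))
  denom <- d_nuc[cyto] + d_edge[cyto]
  dn[cyto] <- ifelse(denom > 0, d_nuc[cyto] / denom, 0.5)
  dn
}

#' Partition the cytoplasm into perinuclear and peripheral bands
#'
#' The perinuclear (PN) band is the set of cytoplasmic pixels with normalized
#' radial coordinate below `f_pn`; the peripheral (PE) band those above
#' `1 - f_pe`. Band fractions are relative distances, identical for every
#' cell whatever its size or shape.
#'
#' @param radial_map output of [normalized_radial_coordinate()].
#' @param f_pn,f_pe band fractions in `(0, 0.5]`.
#' @return `RegionPartition`: list with logical masks `pn`, `pe`, the band
#'   fractions, pixel counts, and `valid` (FALSE when either band is empty).
#' @export
define_regions <- function(radial_map, f_pn = 0.25, f_pe = 0.25) {
  if (f_pn <= 0 || f_pn > 0.5 || f_pe <= 0 || f_pe > 0.5)
    stop("band fractions must lie in (0, 0.5]", call. = FALSE)
  pn <- !is.na(radial_map) & radial_map < f_pn
  pe <- !is.na(radial_map) & radial_map > 1 - f_pe
  structure(list(pn = pn, pe = pe, f_pn = f_pn, f_pe = f_pe,
                 n_pn = sum(pn), n_pe = sum(pe),
                 valid = any(pn) && any(pe)),
            class = "RegionPartition")
}

#' ER expansion ratio of one cell
#'
#' Mean ER intensity over the peripheral band divided by the mean over the
#' perinuclear band. A ratio above 1 indicates peripheral redistribution
#' (ER expansion); the measure is invariant under multiplication of the ER
#' channel by any positive constant.
#'
#' @param er_channel 2D ER intensity matrix.
#' @param partition a `RegionPartition`.
#' @return the ratio, or `NA` (with a `"reason"` attribute) when a band is
#'   empty or the perinuclear mean is zero.
#' @export
expansion_ratio <- function(er_channel, partition) {
  er <- as_matrix(er_channel)
  if (!inherits(partition, "RegionPartition"))
    stop("partition must be a RegionPartition", call. = FALSE)
  if (!partition$valid)
    return(structure(NA_real_, reason = "empty band"))
  pn_mean <- mean(er[partition$pn])
  pe_mean <- mean(er[partition$pe])
  if (pn_mean == 0) return(structure(NA_real_, reason = "zero perinuclear mean"))
  pe_mean / pn_mean
}

#' Matched filters for 1-px ridge and hole texture
#'
#' Zero-mean 3x3 kernels: second-derivative line detectors at 0, 45, 90 and
#' 135 degrees matching 1-px-wide bright ridges, and a 4-neighbor
#' center-surround (dark-center) kernel matching 1-px holes. All kernels sum
#' to zero so a flat image scores exactly zero. The hole kernel uses the
#' 4-connected surround and a gain of 1/2.5, chosen so that a 1-px dark pit
#' scores higher on the hole channel than the incidental positive line
#' responses its neighborhood produces on the ridge channel, while a 1-px
#' bright line still scores higher on the ridge channel (the full 8-surround
#' kernel admits no gain with both properties).
#'
#' @return list with `ridges` (list of 4 matrices) and `hole` (matrix).
#' @export
texture_kernels <- function() {
  h <- matrix(c(-1, -1, -1, 2, 2, 2, -1, -1, -1), 3, 3, byrow = TRUE) / 6
  d1 <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3, byrow = TRUE) / 6
  list(ridges = list(deg0 = h, deg45 = d1, deg90 = t(h),
                     deg135 = d1[, 3:1]),
       hole = matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3) / 2.5)
}

#' Ridge and hole texture scores of one cell
#'
#' Per-pixel ridge response is the maximum over the four oriented line
#' kernels of the convolution with the ER channel; the hole response uses the
#' center-surround kernel. Each score is the mean positive response over the
#' cell mask normalized by the cell's mean ER intensity, making both
#' dimensionless and invariant to intensity scaling.
#'
#' @param er_channel 2D ER intensity matrix.
#' @param cell_mask logical matrix selecting the cell's pixels.
#' @return named numeric `c(ridge_score=, hole_score=)`.
#' @export
texture_scores <- function(er_channel, cell_mask) {
  er <- as_matrix(er_channel)
  mask <- as_matrix(cell_mask) != 0
  if (!any(mask)) stop("empty cell mask", call. = FALSE)
  mu <- mean(er[mask])
  if (mu <= 0) return(c(ridge_score = 0, hole_score = 0))
  k <- texture_kernels()
  resp <- lapply(k$ridges, function(kr)
    as_matrix(EBImage::filter2(er, kr, boundary = 0)))
  ridge <- Reduce(pmax, resp)
  hole <- as_matrix(EBImage::filter2(er, k$hole, boundary = 0))
  c(ridge_score = mean(pmax(ridge[mask], 0)) / mu,
    hole_score = mean(pmax(hole[mask], 0)) / mu)
}

#' Whole-cell moment-based shape features
#'
#' @param cell_mask,nucleus_mask logical matrices for one cell.
#' @return named numeric: `area` (px^2), `eccentricity` (0 for a circle),
#'   `major_axis` (full moment-based major axis, px), and
#'   `nucleus_cell_ratio` (nucleus area / cell area).
#' @export
shape_features <- function(cell_mask, nucleus_mask = NULL) {
  cm <- as_matrix(cell_mask) != 0
  if (!any(cm)) stop("empty cell mask", call. = FALSE)
  m <- EBImage::computeFeatures.moment(matrix(as.integer(cm), nrow(cm)))
  nuc_area <- if (is.null(nucleus_mask)) NA_real_
              else sum(as_matrix(nucleus_mask) != 0)
  c(area = sum(cm),
    eccentricity = unname(m[1L, "m.eccentricity"]),
    major_axis = unname(m[1L, "m.majoraxis"]),
    nucleus_cell_ratio = nuc_area / sum(cm))
}

#' Per-cell ER and shape feature table for one field
#'
#' Runs steps (3) and (4) of the pipeline — radial band definition and
#' feature gathering — for every segmented cell of a field, given matched
#' nuclei and cell label maps and QC flags.
#'
#' @param field `FieldImage` (or named list of channel matrices).
#' @param nuclei,cells `LabelMap`s from the segmentation stage.
#' @param qc optional data.frame from [qc_filter()]; merged into the output.
#' @param f_pn,f_pe band fractions passed to [define_regions()].
#' @param er_channel name of the ER channel.
#' @return data.frame, one row per cell label: expansion ratio, ridge/hole
#'   scores, shape features, `feature_valid` (FALSE for degenerate cells,
#'   e.g. cytoplasm too thin to hold both bands) and QC columns when given.
#' @export
compute_cell_features <- function(field, nuclei, cells, qc = NULL,
                                  f_pn = 0.25, f_pe = 0.25,
                                  er_channel = "er") {
  er <- as_matrix(if (inherits(field, "FieldImage"))
    field$channels[[er_channel]] else field[[er_channel]])
  nlab <- as_matrix(nuclei); clab <- as_matrix(cells)
  n <- max(clab)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cm_full <- clab == i
    if (!any(cm_full)) next
    bb <- mask_bbox(cm_full, pad = 2L)
    cm <- cm_full[bb$r, bb$c]
    nm <- (nlab == i)[bb$r, bb$c] & cm
    erc <- er[bb$r, bb$c]
    feat <- c(expansion_ratio = NA_real_, ridge_score = NA_real_,
              hole_score = NA_real_)
    valid <- FALSE
    if (any(nm) && any(cm & !nm)) {
      dn <- tryCatch(normalized_radial_coordinate(cm, nm),
                     error = function(e) NULL)
      if (!is.null(dn)) {
        part <- define_regions(dn, f_pn, f_pe)
        if (part$valid) {
          xr <- expansion_ratio(erc, part)
          if (!is.na(xr)) {
            tx <- texture_scores(erc, cm)
            feat <- c(expansion_ratio = as.numeric(xr),
                      ridge_score = unname(tx["ridge_score"]),
                      hole_score = unname(tx["hole_score"]))
            valid <- TRUE
          }
        }
      }
    }
    shp <- shape_features(cm, if (any(nm)) nm else NULL)
    rows[[i]] <- data.frame(label = i, t(feat), t(shp),
                            feature_valid = valid)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(label = integer(0), expansion_ratio = numeric(0),
                      ridge_score = numeric(0), hole_score = numeric(0),
                      area = numeric(0), eccentricity = numeric(0),
                      major_axis = numeric(0), nucleus_cell_ratio = numeric(0),
                      feature_valid = logical(0))
  if (!is.null(qc)) {
    qc <- qc[, setdiff(names(qc), "area"), drop = FALSE]  # same as shape area
    out <- merge(qc, out, by = "label", all = TRUE)
  }
  out
}
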
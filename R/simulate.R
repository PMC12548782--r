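#' Specification of a synthetic imaging field
#'
#' Builds and validates the parameter set for one simulated multi-channel
#' fluorescence field. The generator renders epithelial-like cells as smooth
#' star-convex blobs, each with one elliptical nucleus, and paints the ER
#' channel as two piecewise-constant radial bands — a perinuclear (PN) and a
#' peripheral (PE) band at fixed proportional distances between the nuclear
#' boundary and the cell edge — so the true expansion ratio of every cell is
#' known exactly. Optional overlays add 1-px curvilinear ridges (tubule-like
#' texture), 1-px dark holes, rectangular protrusions, and diffraction-limited
#' spots; optional border-clipped and defocused cells exercise the QC stage.
#'
#' @param image_shape integer(2), field size in pixels (rows, cols).
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param n_cells number of cells to place (rejection-sampled, non-overlapping).
#' @param nucleus_axes_range range of nucleus ellipse semi-axes, px.
#' @param cell_radius_range range of cell base radii, px.
#' @param er_peripheral_fraction fraction in `[0,1]` of ER intensity allocated
#'   to the peripheral band; the painted PE:PN intensity ratio is
#'   `er_peripheral_fraction / (1 - er_peripheral_fraction)`.
#' @param pn_band_fraction,pe_band_fraction band widths as fractions of the
#'   normalized nucleus-to-edge distance, each in `(0, 0.5]`.
#' @param ridge_density,hole_density number of ridge polylines / hole pixels
#'   painted per cell.
#' @param protrusion_specs `NULL`, a data.frame with columns `length`, `angle`
#'   (degrees), `width` (px) applied to every cell, or a list of such
#'   data.frames, one per cell.
#' @param spot_count diffraction-limited spots per cell (scalar or per-cell
#'   vector) painted into the spot channel.
#' @param n_border_cells,n_defocused_cells numbers of cells deliberately
#'   clipped by the field edge / blurred with a Gaussian of `blur_sigma`.
#' @param blur_sigma Gaussian sigma (px) applied to defocused cells.
#' @param noise named numeric `c(poisson_scale=, gaussian_sd=)`; both zero
#'   disables noise. Poisson noise is applied to the signal first (scaled by
#'   `poisson_scale` counts per photon), then additive Gaussian read noise.
#' @param background constant background offset (counts) added to every
#'   channel before noise.
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return An object of class `FieldSpec` (a validated list).
#' @seealso [generate_field()]
#' @export
field_spec <- function(image_shape = c(768L, 768L),
                       pixel_size = 0.65,
                       n_cells = 25L,
                       nucleus_axes_range = c(9, 14),
                       cell_radius_range = c(30, 42),
                       er_peripheral_fraction = 0.5,
                       pn_band_fraction = 0.25,
                       pe_band_fraction = 0.25,
                       ridge_density = 0L,
                       hole_density = 0L,
                       protrusion_specs = NULL,
                       spot_count = 0L,
                       n_border_cells = 0L,
                       n_defocused_cells = 0L,
                       blur_sigma = 3,
                       noise = c(poisson_scale = 4, gaussian_sd = 25),
                       background = 300,
                       seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells),
    nucleus_axes_range = as.numeric(nucleus_axes_range),
    cell_radius_range = as.numeric(cell_radius_range),
    er_peripheral_fraction = er_peripheral_fraction,
    pn_band_fraction = pn_band_fraction, pe_band_fraction = pe_band_fraction,
    ridge_density = as.integer(ridge_density),
    hole_density = as.integer(hole_density),
    protrusion_specs = protrusion_specs,
    spot_count = as.integer(spot_count),
    n_border_cells = as.integer(n_border_cells),
    n_defocused_cells = as.integer(n_defocused_cells),
    blur_sigma = blur_sigma,
    noise = c(poisson_scale = unname(noise["poisson_scale"]),
              gaussian_sd = unname(noise["gaussian_sd"])),
    background = background, seed = as.integer(seed)
  )
  validate_field_spec(spec)
  class(spec) <- "FieldSpec"
  spec
}

validate_field_spec <- function(s) {
  if (length(s$image_shape) != 2L || any(s$image_shape < 16L))
    stop("image_shape must be two integers >= 16", call. = FALSE)
  if (s$er_peripheral_fraction < 0 || s$er_peripheral_fraction > 1)
    stop("er_peripheral_fraction must be in [0, 1]", call. = FALSE)
  for (f in c("pn_band_fraction", "pe_band_fraction"))
    if (s[[f]] <= 0 || s[[f]] > 0.5)
      stop(sprintf("%s must be in (0, 0.5]", f), call. = FALSE)
  counts <- c(s$n_cells, s$ridge_density, s$hole_density, s$spot_count,
              s$n_border_cells, s$n_defocused_cells)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (s$n_border_cells + s$n_defocused_cells > s$n_cells)
    stop("n_border_cells + n_defocused_cells exceeds n_cells", call. = FALSE)
  if (any(s$noise < 0) || anyNA(s$noise))
    stop("noise components must be non-negative numbers", call. = FALSE)
  if (!is.null(s$protrusion_specs)) {
    pl <- s$protrusion_specs
    if (is.data.frame(pl)) pl <- list(pl)
    ok <- all(vapply(pl, function(p)
      is.data.frame(p) && all(c("length", "angle", "width") %in% names(p)),
      logical(1)))
    if (!ok)
      stop("protrusion_specs entries need columns length, angle, width",
           call. = FALSE)
  }
  invisible(s)
}

# intensity levels (16-bit counts)
.SIM <- list(er_base = 20000, er_nuc_frac = 0.15, dna = 26000, cyto = 12000,
             ridge_gain = 0.8, hole_keep = 0.1, spot_amp = 25000,
             spot_sigma = 1.2)

#' Generate one synthetic field with ground truth
#'
#' Renders the field described by a [field_spec()] and returns the image stack
#' together with exhaustive machine-readable ground truth. Noise is applied
#' only after all ground-truth quantities are recorded, so the true PN/PE band
#' means (and hence the true expansion ratio, their quotient) are exact for
#' the noise-free image.
#'
#' @param spec a `FieldSpec`.
#' @return A list with elements
#' \describe{
#'   \item{field}{`FieldImage`: named channel matrices (`dna`, `er`, `cyto`,
#'     `spots`), `pixel_size`, `shape`.}
#'   \item{truth}{`GroundTruth`: per-cell table (`cells`), true nucleus/cell
#'     label matrices (`nuclei`, `cell_labels`), radial band code matrix
#'     (`band_map`: 1 = PN, 2 = inter-band, 3 = PE, 4 = nucleus), protrusion
#'     and spot tables.}
#' }
#' @export
generate_field <- function(spec) {
  validate_field_spec(spec)
  with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  nr <- spec$image_shape[1L]; nc <- spec$image_shape[2L]
  chan_names <- c("dna", "er", "cyto", "spots")
  ideal <- rendered <- lapply(chan_names, function(x) matrix(0, nr, nc))
  names(ideal) <- names(rendered) <- chan_names
  nuclei_map <- cell_map <- matrix(0L, nr, nc)
  band_map <- matrix(0L, nr, nc)

  n <- spec$n_cells
  empty_cells <- data.frame(
    label = integer(0), row = numeric(0), col = numeric(0),
    area_cell = integer(0), area_nucleus = integer(0),
    border = logical(0), defocused = logical(0),
    pn_mean = numeric(0), pe_mean = numeric(0),
    expansion_ratio = numeric(0), n_spots = integer(0),
    n_protrusions = integer(0))
  empty_prot <- data.frame(cell = integer(0), length = numeric(0),
                           angle = numeric(0), width = numeric(0),
                           area = integer(0))
  empty_spot <- data.frame(cell = integer(0), row = numeric(0),
                           col = numeric(0))

  if (n == 0L) {
    for (ch in chan_names) {
      rendered[[ch]] <- rendered[[ch]] + spec$background
      rendered[[ch]] <- apply_noise(rendered[[ch]], spec$noise)
    }
    return(list(
      field = new_field_image(rendered, spec$pixel_size),
      truth = structure(list(cells = empty_cells, nuclei = nuclei_map,
                             cell_labels = cell_map, band_map = band_map,
                             protrusions = empty_prot, spots = empty_spot),
                        class = "GroundTruth")))
  }

  # per-cell protrusion specs
  plist <- spec$protrusion_specs
  if (is.null(plist)) plist <- rep(list(NULL), n)
  else if (is.data.frame(plist)) plist <- rep(list(plist), n)
  else if (length(plist) != n)
    stop("protrusion_specs list must have one entry per cell", call. = FALSE)

  radii <- stats::runif(n, spec$cell_radius_range[1], spec$cell_radius_range[2])
  arm_reach <- vapply(plist, function(p)
    if (is.null(p) || nrow(p) == 0) 0 else max(p$length + p$width), numeric(1))
  reach <- radii * 1.14 + arm_reach + 2

  is_border <- seq_len(n) <= spec$n_border_cells
  is_defoc  <- seq_len(n) > spec$n_border_cells &
               seq_len(n) <= spec$n_border_cells + spec$n_defocused_cells

  centers <- place_cells(nr, nc, reach, radii, is_border)

  cells_df <- empty_cells[rep(1L, 0L), ]
  prot_rows <- list(); spot_rows <- list()

  for (i in seq_len(n)) {
    cv <- render_cell(spec, center = centers[i, ], radius = radii[i],
                      arms = plist[[i]], reach = reach[i])
    # clip canvas to field
    rr <- cv$row0 + seq_len(nrow(cv$mask)) - 1L
    cc <- cv$col0 + seq_len(ncol(cv$mask)) - 1L
    keep_r <- rr >= 1L & rr <= nr; keep_c <- cc >= 1L & cc <= nc
    fr <- rr[keep_r]; fc <- cc[keep_c]

    sub <- function(m) m[keep_r, keep_c, drop = FALSE]
    msk <- sub(cv$mask); nmsk <- sub(cv$nucleus); bnd <- sub(cv$bands)
    if (!any(msk)) next
    cell_map[fr, fc][msk] <- i
    nuclei_map[fr, fc][nmsk] <- i
    band_map[fr, fc][msk] <- bnd[msk]

    canv <- lapply(cv$channels, sub)
    blur_canv <- canv
    if (is_defoc[i])
      blur_canv <- lapply(canv, function(m)
        as_matrix(EBImage::gblur(m, sigma = spec$blur_sigma)))
    for (ch in chan_names) {
      ideal[[ch]][fr, fc] <- ideal[[ch]][fr, fc] + canv[[ch]]
      rendered[[ch]][fr, fc] <- rendered[[ch]][fr, fc] + blur_canv[[ch]]
    }

    # ground-truth band means from the clipped, pre-blur, pre-noise paint
    er <- canv$er
    pn_px <- er[msk & bnd == 1L]; pe_px <- er[msk & bnd == 3L]
    pn_mean <- if (length(pn_px)) mean(pn_px) + spec$background else NA_real_
    pe_mean <- if (length(pe_px)) mean(pe_px) + spec$background else NA_real_
    exp_ratio <- if (!is.na(pn_mean) && pn_mean > 0) pe_mean / pn_mean
                 else NA_real_

    # spots painted directly into the field spot channel
    k <- if (length(spec$spot_count) == n) spec$spot_count[i]
         else spec$spot_count[1L]
    if (k > 0L) {
      pos <- sample_spot_positions(msk & !nmsk, k, min_sep = 7)
      for (j in seq_len(nrow(pos))) {
        prow <- fr[1L] + pos[j, 1L] - 1L; pcol <- fc[1L] + pos[j, 2L] - 1L
        stamp_spot(ideal$spots, prow, pcol) -> ideal$spots
        stamp_spot(rendered$spots, prow, pcol) -> rendered$spots
        spot_rows[[length(spot_rows) + 1L]] <-
          data.frame(cell = i, row = prow, col = pcol)
      }
    } else pos <- matrix(0, 0, 2)

    if (nrow(cv$protrusions)) {
      pr <- cv$protrusions; pr$cell <- i
      prot_rows[[length(prot_rows) + 1L]] <-
        pr[, c("cell", "length", "angle", "width", "area")]
    }

    cells_df <- rbind(cells_df, data.frame(
      label = i, row = centers[i, 1L], col = centers[i, 2L],
      area_cell = sum(msk), area_nucleus = sum(nmsk),
      border = is_border[i], defocused = is_defoc[i],
      pn_mean = pn_mean, pe_mean = pe_mean, expansion_ratio = exp_ratio,
      n_spots = nrow(pos), n_protrusions = nrow(cv$protrusions)))
  }

  for (ch in chan_names) {
    ideal[[ch]] <- ideal[[ch]] + spec$background
    rendered[[ch]] <- round(rendered[[ch]] + spec$background)
    rendered[[ch]] <- apply_noise(rendered[[ch]], spec$noise)
  }

  truth <- structure(list(
    cells = cells_df, nuclei = nuclei_map, cell_labels = cell_map,
    band_map = band_map,
    protrusions = if (length(prot_rows)) do.call(rbind, prot_rows)
                  else empty_prot,
    spots = if (length(spot_rows)) do.call(rbind, spot_rows) else empty_spot),
    class = "GroundTruth")

  list(field = new_field_image(rendered, spec$pixel_size), truth = truth)
}

new_field_image <- function(channels, pixel_size) {
  structure(list(channels = channels, pixel_size = pixel_size,
                 shape = dim(channels[[1L]])), class = "FieldImage")
}

#' @export
print.FieldImage <- function(x, ...) {
  cat(sprintf("FieldImage %d x %d px (%.2f um/px), channels: %s\n",
              x$shape[1], x$shape[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.FieldSpec <- function(x, ...) {
  cat(sprintf(
    "FieldSpec: %d cells on %d x %d px, ER peripheral fraction %.2f, seed %d\n",
    x$n_cells, x$image_shape[1], x$image_shape[2],
    x$er_peripheral_fraction, x$seed))
  invisible(x)
}

# Rejection-sample non-overlapping cell centers; border cells are forced to
# straddle a field edge. Errors when the field cannot hold the request.
place_cells <- function(nr, nc, reach, radii, is_border) {
  n <- length(reach)
  centers <- matrix(NA_real_, n, 2L)
  max_tries <- 400L * n
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf(
          "field capacity exceeded: cannot place %d cells of reach <= %.0f px in %d x %d px",
          n, max(reach), nr, nc), call. = FALSE)
      if (is_border[i]) {
        edge <- sample.int(4L, 1L)
        d <- stats::runif(1, 0.2, 0.6) * radii[i]
        cand <- switch(edge,
          c(d, stats::runif(1, reach[i], nc - reach[i])),
          c(nr - d, stats::runif(1, reach[i], nc - reach[i])),
          c(stats::runif(1, reach[i], nr - reach[i]), d),
          c(stats::runif(1, reach[i], nr - reach[i]), nc - d))
      } else {
        lo <- reach[i] + 2
        if (nr - lo < lo || nc - lo < lo)
          stop("field capacity exceeded: cell reach larger than field",
               call. = FALSE)
        cand <- c(stats::runif(1, lo, nr - lo), stats::runif(1, lo, nc - lo))
      }
      ok <- TRUE
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        dd <- sqrt((centers[prev, 1L] - cand[1L])^2 +
                   (centers[prev, 2L] - cand[2L])^2)
        ok <- all(dd > reach[prev] + reach[i])
      }
      if (ok) { centers[i, ] <- cand; break }
    }
  }
  centers
}

# Render one cell on its own canvas. Returns masks, painted channels, the
# band code map and the realized protrusion table (canvas coordinates).
render_cell <- function(spec, center, radius, arms, reach) {
  half <- ceiling(reach) + 3L +
    if (spec$n_defocused_cells > 0) ceiling(3 * spec$blur_sigma) else 0L
  side <- 2L * half + 1L
  cx <- half + 1L
  row0 <- as.integer(round(center[1L])) - half
  col0 <- as.integer(round(center[2L])) - half

  rowg <- matrix(seq_len(side), side, side)
  colg <- matrix(seq_len(side), side, side, byrow = TRUE)
  dy <- rowg - cx; dx <- colg - cx
  rad <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  # star-convex boundary: radius modulated by low-order harmonics
  kh <- 2:4
  amp <- stats::runif(3, 0, 0.04)
  ph  <- stats::runif(3, 0, 2 * pi)
  rb <- radius * (1 + amp[1] * cos(kh[1] * theta + ph[1]) +
                      amp[2] * cos(kh[2] * theta + ph[2]) +
                      amp[3] * cos(kh[3] * theta + ph[3]))
  body <- rad <= rb

  prot_rows <- data.frame(length = numeric(0), angle = numeric(0),
                          width = numeric(0), area = integer(0))
  mask <- body
  if (!is.null(arms) && nrow(arms)) {
    for (j in seq_len(nrow(arms))) {
      a <- arms$angle[j] * pi / 180
      u <- c(-sin(a), cos(a))              # (row, col) direction, y-up angles
      v <- c(cos(a), sin(a))
      r0 <- radius * (1 + amp[1] * cos(kh[1] * atan2(u[1], u[2]) + ph[1]) +
                          amp[2] * cos(kh[2] * atan2(u[1], u[2]) + ph[2]) +
                          amp[3] * cos(kh[3] * atan2(u[1], u[2]) + ph[3]))
      t <- dy * u[1L] + dx * u[2L]
      s <- dy * v[1L] + dx * v[2L]
      armpix <- t >= r0 - 1.5 & t <= r0 + arms$length[j] &
                abs(s) <= arms$width[j] / 2
      area <- sum(armpix & !body)
      mask <- mask | armpix
      prot_rows <- rbind(prot_rows, data.frame(
        length = arms$length[j], angle = arms$angle[j],
        width = arms$width[j], area = area))
    }
  }

  # nucleus: ellipse at the cell center
  ax <- stats::runif(1, spec$nucleus_axes_range[1], spec$nucleus_axes_range[2])
  bx <- stats::runif(1, spec$nucleus_axes_range[1], spec$nucleus_axes_range[2])
  an <- max(ax, bx); bn <- min(ax, bx)
  an <- min(an, 0.6 * radius)              # keep nucleus well inside the cell
  bn <- min(bn, an)
  phi <- stats::runif(1, 0, pi)
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  nucleus <- (xr / an)^2 + (yr / bn)^2 <= 1
  nucleus <- nucleus & body

  # normalized radial coordinate over the cytoplasm (same half-pixel
  # convention as the measurement path)
  d_nuc <- pmax(dist_to_mask(nucleus) - 0.5, 0)
  d_edge <- pmax(dist_to_complement(mask) - 0.5, 0)
  cyto <- mask & !nucleus
  dn <- matrix(NA_real_, side, side)
  denom <- d_nuc[cyto] + d_edge[cyto]
  dn[cyto] <- ifelse(denom > 0, d_nuc[cyto] / denom, 0.5)

  bands <- matrix(0L, side, side)
  bands[nucleus] <- 4L
  bands[cyto] <- 2L
  bands[cyto & dn < spec$pn_band_fraction] <- 1L
  bands[cyto & dn > 1 - spec$pe_band_fraction] <- 3L

  p <- spec$er_peripheral_fraction
  i_pe <- round(2 * p * .SIM$er_base)
  i_pn <- round(2 * (1 - p) * .SIM$er_base)
  er <- matrix(0, side, side)
  er[bands == 4L] <- round(.SIM$er_nuc_frac * .SIM$er_base)
  er[bands == 1L] <- i_pn
  er[bands == 2L] <- .SIM$er_base
  er[bands == 3L] <- i_pe

  # texture overlays: 1-px random-walk ridges, 1-px dark holes
  if (spec$ridge_density > 0L) {
    cyto_idx <- which(cyto, arr.ind = TRUE)
    for (k in seq_len(spec$ridge_density)) {
      start <- cyto_idx[sample.int(nrow(cyto_idx), 1L), ]
      pts <- ridge_walk(start, n_steps = sample(10:22, 1L), cyto)
      if (nrow(pts))
        er[pts] <- er[pts] + round(.SIM$ridge_gain * .SIM$er_base)
    }
  }
  if (spec$hole_density > 0L) {
    cyto_idx <- which(cyto, arr.ind = TRUE)
    pick <- cyto_idx[sample.int(nrow(cyto_idx),
                                min(spec$hole_density, nrow(cyto_idx))), ,
                     drop = FALSE]
    er[pick] <- round(.SIM$hole_keep * er[pick])
  }

  dna <- matrix(0, side, side); dna[nucleus] <- .SIM$dna
  cyt <- matrix(0, side, side); cyt[mask] <- .SIM$cyto
  spots <- matrix(0, side, side)

  list(mask = mask, nucleus = nucleus, bands = bands,
       channels = list(dna = dna, er = er, cyto = cyt, spots = spots),
       protrusions = prot_rows, row0 = row0, col0 = col0)
}

# 1-px-wide random-walk polyline constrained to `allowed` pixels.
ridge_walk <- function(start, n_steps, allowed) {
  pos <- as.numeric(start)
  dir <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_integer_, n_steps, 2L)
  m <- 0L
  for (s in seq_len(n_steps)) {
    dir <- dir + stats::rnorm(1, 0, 0.25)
    pos <- pos + c(sin(dir), cos(dir))
    pr <- round(pos)
    if (pr[1L] < 1 || pr[2L] < 1 || pr[1L] > nrow(allowed) ||
        pr[2L] > ncol(allowed) || !allowed[pr[1L], pr[2L]]) break
    m <- m + 1L
    pts[m, ] <- pr
  }
  unique(pts[seq_len(m), , drop = FALSE])
}

# Greedy sampling of k spot positions inside `allowed` with minimum pairwise
# separation; relaxes to unconstrained sampling if the region is too crowded.
sample_spot_positions <- function(allowed, k, min_sep = 5) {
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, 0, 2))
  chosen <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(chosen) < k && tries < 200L * k) {
    tries <- tries + 1L
    cand <- idx[sample.int(nrow(idx), 1L), ]
    if (nrow(chosen) == 0L ||
        all(sqrt((chosen[, 1] - cand[1])^2 +
                 (chosen[, 2] - cand[2])^2) >= min_sep))
      chosen <- rbind(chosen, cand)
  }
  while (nrow(chosen) < k)
    chosen <- rbind(chosen, idx[sample.int(nrow(idx), 1L), ])
  unname(chosen)
}

# Additive Gaussian PSF stamp for one diffraction-limited spot.
stamp_spot <- function(img, row, col) {
  s <- .SIM$spot_sigma
  ext <- 3L
  rr <- (row - ext):(row + ext); cc <- (col - ext):(col + ext)
  keep_r <- rr >= 1L & rr <= nrow(img); keep_c <- cc >= 1L & cc <= ncol(img)
  rr <- rr[keep_r]; cc <- cc[keep_c]
  g <- outer(rr - row, cc - col,
             function(a, b) exp(-(a^2 + b^2) / (2 * s^2)))
  img[rr, cc] <- img[rr, cc] + round(.SIM$spot_amp * g)
  img
}

# Poisson shot noise (scaled) followed by Gaussian read noise; clipped to the
# 16-bit range and rounded to integer counts.
apply_noise <- function(img, noise) {
  s <- noise[["poisson_scale"]]; g <- noise[["gaussian_sd"]]
  x <- img
  if (s > 0) x <- matrix(stats::rpois(length(x), x / s) * s, nrow(x), ncol(x))
  if (g > 0) x <- x + matrix(stats::rnorm(length(x), 0, g), nrow(x), ncol(x))
  round(pmin(pmax(x, 0), 65535))
}
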
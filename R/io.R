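#' Write a simulated field and its ground truth to disk
#'
#' The image stack goes to a multi-page 16-bit TIFF (one page per channel)
#' with a JSON sidecar recording the channel order and pixel size; the ground
#' truth goes to CSV tables plus 16-bit label TIFFs. The round trip through
#' [read_fixture()] is lossless for integer intensities in `[0, 65535]`.
#'
#' @param field a `FieldImage` from [generate_field()].
#' @param truth the matching `GroundTruth` (optional, `NULL` to skip).
#' @param path output directory, created if missing.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(field, truth, path) {
  if (!inherits(field, "FieldImage")) stop("field must be a FieldImage")
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  write_field_tiff(field$channels, file.path(path, "field.tif"))
  jsonlite::write_json(
    list(channels = names(field$channels), pixel_size = field$pixel_size,
         shape = field$shape, bits_per_sample = 16L),
    file.path(path, "channels.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    utils::write.csv(truth$cells, file.path(path, "truth_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$protrusions,
                     file.path(path, "truth_protrusions.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$spots, file.path(path, "truth_spots.csv"),
                     row.names = FALSE)
    write_field_tiff(list(truth$nuclei, truth$cell_labels, truth$band_map),
                     file.path(path, "truth_labels.tif"))
  }
  invisible(path)
}

write_field_tiff <- function(mats, file) {
  pages <- lapply(mats, function(m) as_matrix(m) / 65535)
  ok <- tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  if (!isTRUE(ok > 0))
    stop(sprintf("failed to write TIFF '%s'", file), call. = FALSE)
  invisible(file)
}

read_field_tiff <- function(file) {
  if (!file.exists(file))
    stop(sprintf("TIFF file not found: '%s'", file), call. = FALSE)
  lapply(tiff::readTIFF(file, all = TRUE), function(m) round(m * 65535))
}

#' Read a field fixture written by [write_fixture()]
#'
#' @param path fixture directory.
#' @return A list with `field` (a `FieldImage`) and, when the truth files are
#'   present, `truth` (cell/protrusion/spot tables and label matrices).
#' @export
read_fixture <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "channels.json"),
                              simplifyVector = TRUE)
  pages <- read_field_tiff(file.path(path, "field.tif"))
  names(pages) <- meta$channels
  field <- new_field_image(pages, meta$pixel_size)
  out <- list(field = field)
  tc <- file.path(path, "truth_cells.csv")
  if (file.exists(tc)) {
    labs <- read_field_tiff(file.path(path, "truth_labels.tif"))
    out$truth <- structure(list(
      cells = utils::read.csv(tc),
      nuclei = matrix(as.integer(labs[[1L]]), nrow(labs[[1L]])),
      cell_labels = matrix(as.integer(labs[[2L]]), nrow(labs[[2L]])),
      band_map = matrix(as.integer(labs[[3L]]), nrow(labs[[3L]])),
      protrusions = utils::read.csv(file.path(path, "truth_protrusions.csv")),
      spots = utils::read.csv(file.path(path, "truth_spots.csv"))),
      class = "GroundTruth")
  }
  out
}
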
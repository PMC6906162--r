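#' Write a grayscale image to TIFF
#'
#' Integer modes (8/16-bit) store whole-number intensities losslessly up to
#' the bit depth. Float mode stores 32-bit IEEE floats; because the TIFF
#' writer encodes values in `[0, 1]`, float images are divided by a scale
#' (their maximum by default) that is recorded in a JSON sidecar
#' (`<file>.json`) and re-applied on read.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param bits 8, 16, or 32 (32 = float).
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path, bits = 16) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("write_image_tiff: non-finite values")
  if (bits %in% c(8, 16)) {
    maxv <- 2^bits - 1
    img <- round(image)
    if (any(img < 0 | img > maxv))
      stop(sprintf("write_image_tiff: values outside [0, %d] for %d-bit output",
                   maxv, bits))
    tiff::writeTIFF(img / maxv, path, bits.per.sample = as.integer(bits),
                    compression = "none", reduce = FALSE)
  } else if (bits == 32) {
    scale <- max(image, 1e-12)
    tiff::writeTIFF(image / scale, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(list(scale = scale, sample_format = "float"),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else stop("write_image_tiff: bits must be 8, 16 or 32")
  invisible(path)
}

#' Read a grayscale TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path; a `<path>.json` sidecar, if present, supplies the
#'   float scale.
#' @return numeric matrix in original intensity units.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("read_image_tiff: file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    # float image stored in [0, 1]; rescale by the sidecar factor
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * meta$scale
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
  }
  storage.mode(img) <- "double"
  img
}

#' Read co-registered channel images into a stack
#'
#' @param paths named character vector of single-plane grayscale TIFF/PNG
#'   paths; names among DAPI, Hoechst, CD31, EF5, EdU.
#' @param pixel_size_um physical pixel size shared by all channels.
#' @return a [channel_stack()]; mismatched dimensions raise an error naming
#'   both shapes.
#' @export
read_channels <- function(paths, pixel_size_um = 1) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("read_channels: paths must be named by channel")
  imgs <- lapply(paths, function(p) {
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      img <- png::readPNG(p)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img * 255
    } else read_image_tiff(p)
  })
  dims <- vapply(imgs, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) > 1)
    stop("read_channels: channel dimensions differ: ",
         paste(sprintf("%s=%s", names(dims), dims), collapse = ", "))
  grid <- pixel_grid(ncol(imgs[[1]]), nrow(imgs[[1]]), pixel_size_um)
  channel_stack(grid, imgs)
}

#' Write phantom/pipeline outputs to a directory
#'
#' Writes one 16-bit grayscale TIFF per channel, the oxygen field as a
#' 32-bit float TIFF, the necrosis mask as an 8-bit TIFF, truth tables
#' (vessels, cells) as CSV, and the resolved configuration as JSON.
#'
#' @param phantom list with `channels` and `truth` from [make_phantom()].
#' @param out_dir output directory (created if needed).
#' @param config the resolved configuration list.
#' @return `out_dir`, invisibly.
#' @export
write_phantom_outputs <- function(phantom, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ch <- phantom$channels
  for (nm in names(ch$channels)) {
    img <- pmin(ch$channels[[nm]], 65535)
    write_image_tiff(img, file.path(out_dir, paste0(nm, ".tif")), bits = 16)
  }
  tr <- phantom$truth
  write_image_tiff(tr$oxygen, file.path(out_dir, "oxygen.tif"), bits = 32)
  write_image_tiff(matrix(as.numeric(tr$necrosis_mask) * 255,
                          nrow(tr$necrosis_mask)),
                   file.path(out_dir, "necrosis.tif"), bits = 8)
  write.csv(tr$vessels, file.path(out_dir, "truth_vessels.csv"),
            row.names = FALSE)
  write.csv(tr$cells, file.path(out_dir, "truth_cells.csv"),
            row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
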
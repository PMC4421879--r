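# TIFF-stack + JSON-sidecar I/O.  Physical float volumes are stored as
# 32-bit float pages after an affine rescale to [0, 1]; the slope and
# intercept live in the sidecar (the r-tiff writer only guarantees float
# storage inside the unit interval).  Count stacks are 16-bit unsigned
# with a recorded scale.

#' Write a 3-D array as a multi-page TIFF with a JSON sidecar
#'
#' @param grid 3-D numeric array (pages along the third dimension)
#' @param path output .tif path; the sidecar is written next to it as
#'   `<path>.json`
#' @param meta named list of extra metadata for the sidecar
#' @param bits 32 (float, rescaled) or 16 (unsigned counts)
#' @return the path, invisibly
#' @export
writeVolumeTiff <- function(grid, path, meta = list(), bits = 32L) {
  stopifnot(length(dim(grid)) == 3L)
  rng <- range(grid)
  if (bits == 32L) {
    slope <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    scaled <- (grid - rng[1]) / slope
    meta$slope <- slope; meta$intercept <- rng[1]
  } else {
    slope <- if (rng[2] > 0) rng[2] else 1
    scaled <- grid / slope
    meta$slope <- slope; meta$intercept <- 0
  }
  pages <- lapply(seq_len(dim(grid)[3]), function(z) scaled[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none", reduce = FALSE)
  meta$dim <- dim(grid)
  meta$bits <- bits
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TIFF volume written by [writeVolumeTiff()]
#'
#' @param path .tif path with its `.json` sidecar
#' @return list `grid` (3-D array) and `meta` (sidecar list)
#' @export
readVolumeTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  grid <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  grid <- grid * meta$slope + meta$intercept
  list(grid = grid, meta = meta)
}

#' Write a density phantom to disk
#'
#' Density stack (32-bit float TIFF, g cm^-3) plus a sidecar carrying
#' voxel size, medium density, Z/M and the label stack file name.
#'
#' @param phantom a [DensityPhantom-class]
#' @param path .tif path
#' @return the path, invisibly
#' @export
writePhantom <- function(phantom, path) {
  stopifnot(is(phantom, "DensityPhantom"))
  labPath <- sub("\\.tiff?$", "", path)
  labPath <- paste0(labPath, "_labels.tif")
  writeVolumeTiff(phantom@grid, path,
                  meta = list(unit = "g/cm^3",
                              voxel_size_mm = phantom@voxelSize,
                              medium_density = phantom@mediumDensity,
                              z_over_m = phantom@zOverM,
                              labels_file = basename(labPath)))
  writeVolumeTiff(phantom@labels + 0, labPath,
                  meta = list(unit = "label", voxel_size_mm =
                                phantom@voxelSize), bits = 16L)
  invisible(path)
}

#' Read a density phantom written by [writePhantom()]
#'
#' @param path .tif path
#' @return a [DensityPhantom-class]
#' @export
readPhantom <- function(path) {
  d <- readVolumeTiff(path)
  labPath <- file.path(dirname(path), d$meta$labels_file)
  lab <- readVolumeTiff(labPath)
  new("DensityPhantom", grid = d$grid,
      voxelSize = d$meta$voxel_size_mm,
      mediumDensity = d$meta$medium_density,
      zOverM = d$meta$z_over_m,
      labels = array(as.integer(round(lab$grid)), dim = dim(lab$grid)))
}
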
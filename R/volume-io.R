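## Volume I/O: multi-page 32-bit float TIFF with a YAML sidecar carrying
## the channel axis, voxel size and intensity scale. Planes are written
## z-within-channel (all z of channel 1, then channel 2, ...). Intensities
## are stored scaled to [0, 1]; the scale factor lives in the sidecar so
## the round trip is lossless to float32 precision.

#' Write / read an ImageVolume as TIFF
#'
#' `writeVolumeTiff()` stores a multi-channel 3D volume as a multi-page
#' 32-bit float TIFF plus a YAML sidecar (`<file>.yaml`) recording axis
#' order, voxel size (micrometers), channel names and the intensity scale.
#' `readVolumeTiff()` reverses it.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param file Path to the `.tif` file; the sidecar is written next to it.
#' @return `writeVolumeTiff()` returns `file` invisibly;
#'   `readVolumeTiff()` returns an \linkS4class{ImageVolume}.
#' @examples
#' v <- ImageVolume(array(runif(4 * 8 * 8), c(4, 8, 8)))
#' f <- file.path(tempdir(), "vol.tif")
#' writeVolumeTiff(v, f)
#' v2 <- readVolumeTiff(f)
#' max(abs(imageData(v2) - imageData(v)))
#' @export
writeVolumeTiff <- function(volume, file) {
  stopifnot(is(volume, "ImageVolume"))
  d <- dim(volume@data)
  mx <- max(volume@data, 1e-12)
  planes <- vector("list", d[1L] * d[4L])
  k <- 1L
  for (ch in seq_len(d[4L])) {
    for (z in seq_len(d[1L])) {
      planes[[k]] <- volume@data[z, , , ch] / mx
      k <- k + 1L
    }
  }
  tiff::writeTIFF(planes, file, bits.per.sample = 32L, compression = "none")
  meta <- list(
    axes = "ZYX per channel, planes ordered z-within-channel",
    shape_zyx = as.integer(d[1:3]),
    n_channels = as.integer(d[4L]),
    channel_names = as.list(volume@channelNames),
    voxel_size_um_zyx = as.numeric(volume@voxelSize),
    intensity_scale = mx)
  yaml::write_yaml(meta, paste0(file, ".yaml"))
  invisible(file)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yaml"))
  planes <- tiff::readTIFF(file, all = TRUE)
  d <- as.integer(meta$shape_zyx)
  nch <- as.integer(meta$n_channels)
  arr <- array(0, c(d, nch))
  k <- 1L
  for (ch in seq_len(nch)) {
    for (z in seq_len(d[1L])) {
      arr[z, , , ch] <- planes[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  ImageVolume(arr, voxelSize = as.numeric(meta$voxel_size_um_zyx),
              channelNames = unlist(meta$channel_names))
}
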
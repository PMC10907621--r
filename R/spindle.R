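#' Locate spindle poles from the pole channel
#'
#' Segments the pole (CEP192-role) channel with the same threshold
#' machinery as the kinetochore channel and returns the intensity-weighted
#' centroids of the two brightest above-threshold components as a
#' \linkS4class{SpindleFrame}. With more than two candidates the two
#' brightest are used and the frame is flagged multipolar (with a
#' warning); fewer than two is an error.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param channel Pole channel name or index (default \code{"pole"}).
#' @param qc A \code{\link{qcConfig}} supplying threshold, connectivity
#'   and minimum component size. Otsu thresholding is the default here
#'   since pole blobs are bright and well separated.
#' @return A \linkS4class{SpindleFrame} (poles ordered lexicographically).
#' @export
locatePoles <- function(volume, channel = "pole",
                        qc = qcConfig(threshold_method = "otsu",
                                      min_voxels = 8L)) {
  stopifnot(is(volume, "ImageVolume"))
  seg <- segmentSpots(volume, channel, qc, cell_id = "poles")
  spots <- seg$spots
  if (nrow(spots) < 2L)
    stop("fewer than two pole candidates found in channel '", channel, "'",
         call. = FALSE)
  img <- imageData(volume, channel)
  idx <- which(seg$labels > 0L)
  brightness <- rowsum(img[idx], seg$labels[idx])[, 1L]
  ord <- order(brightness, decreasing = TRUE)
  multipolar <- nrow(spots) > 2L
  if (multipolar)
    warning(nrow(spots), " pole candidates; using the two brightest ",
            "(multipolar flag set)", call. = FALSE)
  top2 <- spots[ord[1:2], ]
  SpindleFrame(as.numeric(top2[1L, c("z_um", "y_um", "x_um")]),
               as.numeric(top2[2L, c("z_um", "y_um", "x_um")]),
               multipolar = multipolar)
}

#' Signed position of kinetochores along the spindle axis
#'
#' Scalar projection of \code{centroid - midline} onto the pole--pole
#' axis unit vector: the signed distance (micrometers) of each spot from
#' the midline, measured along the axis only (distance to the
#' perpendicular bisector plane of the poles). The sign is arbitrary but
#' consistent within a cell.
#'
#' @param spots Spot table with \code{z_um}/\code{y_um}/\code{x_um}
#'   columns, or a numeric matrix/vector of micrometer coordinates.
#' @param frame A \linkS4class{SpindleFrame}.
#' @return Numeric vector of signed axis positions (micrometers).
#' @export
axisPosition <- function(spots, frame) {
  stopifnot(is(frame, "SpindleFrame"))
  if (is.data.frame(spots))
    spots <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  spots <- matrix(spots, ncol = 3L)
  centered <- sweep(spots, 2L, spindleMidpoint(frame))
  as.vector(centered %*% spindleAxis(frame))
}

#' Classify axis positions as central or polar
#'
#' Kinetochores at most \code{cutoff} micrometers from the midline (along
#' the spindle axis) are central; beyond it they are polar.
#'
#' @param position Signed axis positions from \code{\link{axisPosition}}.
#' @param cutoff Micrometer cutoff (default 5).
#' @return Character vector, \code{"central"} or \code{"polar"}.
#' @examples
#' classifyRegion(c(0, -5, 5.01))
#' @export
classifyRegion <- function(position, cutoff = 5) {
  ifelse(abs(position) <= cutoff, "central", "polar")
}

#' Percent of cells with a SAC-positive kinetochore per spindle region
#'
#' For each spindle region (central/polar), the percentage of cells
#' containing at least one SAC-positive kinetochore in that region.
#'
#' @param spots Spot table carrying \code{cell_id}, a \code{region}
#'   column (from \code{\link{classifyRegion}}) and a SAC-positive call
#'   column.
#' @param positive_col Name of the logical SAC call column (default
#'   \code{"sac_positive_p99"}).
#' @param cells Optional character vector of cell ids defining the
#'   denominator (e.g. all QC-passing cells, including cells without any
#'   positive spot); defaults to the cells present in \code{spots}.
#' @return data.frame with \code{region}, \code{n_cells},
#'   \code{n_cells_positive} and \code{percent}.
#' @export
regionPositiveFraction <- function(spots, positive_col = "sac_positive_p99",
                                   cells = NULL) {
  if (!positive_col %in% names(spots))
    stop("column '", positive_col, "' not found", call. = FALSE)
  if ("qc_pass" %in% names(spots)) spots <- spots[spots$qc_pass, ,
                                                  drop = FALSE]
  cells <- cells %||% unique(spots$cell_id)
  if (length(cells) == 0L) stop("zero cells", call. = FALSE)
  regions <- c("central", "polar")
  out <- lapply(regions, function(rg) {
    pos <- spots[spots$region == rg & spots[[positive_col]], , drop = FALSE]
    npos <- length(intersect(cells, unique(pos$cell_id)))
    data.frame(region = rg, n_cells = length(cells),
               n_cells_positive = npos,
               percent = 100 * npos / length(cells),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
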
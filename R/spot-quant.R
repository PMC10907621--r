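#' Quality-control configuration for kinetochore quantification
#'
#' @param iqr_multiplier Tukey fence multiplier for the spot-volume and
#'   cell-count filters (default 1.5).
#' @param sac_percentiles Percentiles of the vehicle-control SAC-signal
#'   distribution used to call SAC-positive kinetochores (subset of
#'   90/95/99 by convention).
#' @param pole_exclusion_radius Kinetochores whose centroid lies within
#'   this distance (micrometers) of a spindle-pole centroid are flagged as
#'   pole-coincident (default 1.0).
#' @param connectivity 3D neighborhood for segmentation, 26 (default) or 6.
#' @param threshold_method \code{"fixed"} (use \code{threshold}),
#'   \code{"otsu"}, or \code{"robust"} (median + 5 MAD-based sd of the
#'   channel, suited to sparse foregrounds where Otsu collapses).
#' @param threshold Fixed segmentation threshold (intensity units);
#'   required when \code{threshold_method = "fixed"}.
#' @param min_voxels Minimum component size in voxels (default 10; smaller
#'   components are treated as noise specks, well below the ~25 voxels a
#'   dim diffraction-limited spot covers at a quarter-amplitude threshold).
#' @param volume_rule \code{"tukey_upper"} (default: oversize means volume
#'   above Q3 + m*IQR, targeting merged objects) or \code{"tukey_two_sided"}.
#' @return A list of class \code{"QCConfig"}.
#' @export
qcConfig <- function(iqr_multiplier = 1.5, sac_percentiles = c(90, 95, 99),
                     pole_exclusion_radius = 1.0, connectivity = 26L,
                     threshold_method = c("fixed", "otsu", "robust"),
                     threshold = NULL, min_voxels = 10L,
                     volume_rule = c("tukey_upper", "tukey_two_sided")) {
  stopifnotScalar(iqr_multiplier, "iqr_multiplier", positive = TRUE)
  if (any(sac_percentiles <= 0 | sac_percentiles >= 100))
    stop("'sac_percentiles' must lie in (0, 100)", call. = FALSE)
  cfg <- list(iqr_multiplier = iqr_multiplier,
              sac_percentiles = sort(sac_percentiles),
              pole_exclusion_radius = pole_exclusion_radius,
              connectivity = as.integer(connectivity),
              threshold_method = match.arg(threshold_method),
              threshold = threshold, min_voxels = as.integer(min_voxels),
              volume_rule = match.arg(volume_rule))
  class(cfg) <- "QCConfig"
  cfg
}

#' Segment kinetochore spots in a 3D channel
#'
#' Thresholds the chosen channel (fixed value or Otsu) and extracts
#' connected components under the configured 3D neighborhood. Each
#' component becomes one draft spot record with its intensity-weighted
#' centroid and volume in physical units.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param channel Channel name or index to segment (e.g.
#'   \code{"reference"}).
#' @param qc A \code{\link{qcConfig}}; supplies threshold, connectivity
#'   and the minimum component size.
#' @param cell_id Identifier stored in the output table (default
#'   \code{"cell1"}).
#' @return A list with \code{labels} (integer 3D array, 0 = background)
#'   and \code{spots}, a data.frame with one row per component:
#'   \code{cell_id}, \code{spot_id}, centroids \code{z_um}/\code{y_um}/
#'   \code{x_um}, \code{voxel_count}, \code{volume_um3} and
#'   \code{saturated} (all voxels at the channel maximum). An empty
#'   segmentation yields a 0-row table.
#' @examples
#' syn <- makeKinetochoreVolume(synthConfig(seed = 1, n_kinetochores = 8,
#'                                          image_shape = c(20, 120, 90)))
#' qc <- qcConfig(threshold = attr(syn$truth, "suggested_threshold"))
#' seg <- segmentSpots(syn$volume, "reference", qc)
#' nrow(seg$spots)
#' @export
segmentSpots <- function(volume, channel, qc, cell_id = "cell1") {
  stopifnot(is(volume, "ImageVolume"), inherits(qc, "QCConfig"))
  img <- imageData(volume, channel)
  thr <- switch(qc$threshold_method,
    fixed = {
      if (is.null(qc$threshold))
        stop("fixed threshold_method requires a 'threshold' value",
             call. = FALSE)
      qc$threshold
    },
    otsu = otsuThreshold(img),
    robust = median(img) + 5 * stats::mad(img))
  labels <- labelComponents3D(img > thr, qc$connectivity)

  if (qc$min_voxels > 1L && max(labels) > 0L) {
    counts <- tabulate(labels[labels > 0L])
    keep <- which(counts >= qc$min_voxels)
    remap <- integer(length(counts))
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }

  n <- max(labels)
  vs <- voxelSize(volume)
  if (n == 0L) {
    spots <- data.frame(cell_id = character(0), spot_id = integer(0),
                        z_um = numeric(0), y_um = numeric(0),
                        x_um = numeric(0), voxel_count = integer(0),
                        volume_um3 = numeric(0), saturated = logical(0))
    return(list(labels = labels, spots = spots))
  }

  idx <- which(labels > 0L)
  lab <- labels[idx]
  val <- img[idx]
  d <- dim(img)
  i0 <- idx - 1L
  z <- (i0 %% d[1L]) * vs[1L]
  r <- i0 %/% d[1L]
  y <- (r %% d[2L]) * vs[2L]
  x <- (r %/% d[2L]) * vs[3L]

  wsum <- rowsum(val, lab)[, 1L]
  counts <- tabulate(lab, n)
  img_max <- max(img)
  spots <- data.frame(
    cell_id = cell_id, spot_id = seq_len(n),
    z_um = rowsum(val * z, lab)[, 1L] / wsum,
    y_um = rowsum(val * y, lab)[, 1L] / wsum,
    x_um = rowsum(val * x, lab)[, 1L] / wsum,
    voxel_count = counts,
    volume_um3 = counts * prod(vs),
    saturated = as.vector(rowsum(as.numeric(val >= img_max), lab)[, 1L] ==
                            counts),
    stringsAsFactors = FALSE)
  if (any(spots$saturated))
    warning("saturated component(s) detected", call. = FALSE)
  list(labels = labels, spots = spots)
}

#' Estimate the per-voxel background of a channel
#'
#' The background is the median signal of the non-kinetochore area over
#' the entire z-stack: the median of every voxel lying outside all
#' labeled regions.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param labels Integer label array from \code{\link{segmentSpots}}
#'   (aligned with the volume).
#' @param channel Channel name or index to measure.
#' @return Scalar background per voxel (intensity units).
#' @export
estimateBackground <- function(volume, labels, channel) {
  stopifnot(is(volume, "ImageVolume"))
  img <- imageData(volume, channel)
  if (!identical(dim(img), dim(labels)))
    stop("'labels' must be aligned with the volume", call. = FALSE)
  outside <- img[labels == 0L]
  if (length(outside) == 0L)
    stop("no unlabeled voxels: cannot estimate background", call. = FALSE)
  median(outside)
}

#' Quantify background-corrected spot intensities
#'
#' For each segmented spot and each requested channel, sums the raw voxel
#' intensities over the spot's labeled region and subtracts
#' \code{background * voxel_count}. Corrected integrals are clamped at 0
#' with a flag.
#'
#' @param spots Draft spot table from \code{\link{segmentSpots}}.
#' @param volume The \linkS4class{ImageVolume}.
#' @param labels Label array from \code{\link{segmentSpots}}.
#' @param background Named numeric vector of per-voxel backgrounds, one
#'   per requested channel (see \code{\link{estimateBackground}}).
#' @param channels Channels to quantify (default: names of
#'   \code{background}).
#' @return The spot table with, per channel \code{<ch>}, columns
#'   \code{raw_<ch>}, \code{corrected_<ch>}, \code{mean_corrected_<ch>}
#'   and \code{clamped_<ch>}.
#' @export
quantifySpots <- function(spots, volume, labels, background,
                          channels = names(background)) {
  stopifnot(is(volume, "ImageVolume"))
  if (is.null(channels))
    stop("'background' must be named by channel", call. = FALSE)
  n <- nrow(spots)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  for (ch in channels) {
    img <- imageData(volume, ch)
    if (!identical(dim(img), dim(labels)))
      stop("channel/shape mismatch for channel ", ch, call. = FALSE)
    raw <- numeric(n)
    if (n > 0L && length(idx) > 0L) {
      sums <- rowsum(img[idx], lab)
      raw[as.integer(rownames(sums))] <- sums[, 1L]
    }
    corrected <- raw - background[[ch]] * spots$voxel_count
    clamped <- corrected < 0
    corrected[clamped] <- 0
    spots[[paste0("raw_", ch)]] <- raw
    spots[[paste0("corrected_", ch)]] <- corrected
    spots[[paste0("mean_corrected_", ch)]] <- corrected / spots$voxel_count
    spots[[paste0("clamped_", ch)]] <- clamped
  }
  spots
}

#' Flag oversized and pole-coincident spots
#'
#' Applies the spot-level quality-control filters: a spot is
#' \code{oversize} when its volume exceeds the Tukey fence
#' Q3 + m*IQR of the spot-volume distribution (merged kinetochores
#' segment as single large objects), and \code{pole_coincident} when its
#' centroid lies within the pole exclusion radius of a spindle-pole
#' centroid. Flags are added, never rows removed; \code{qc_pass}
#' summarizes them.
#'
#' @param spots Spot table (needs \code{volume_um3} and centroid columns).
#' @param qc A \code{\link{qcConfig}}.
#' @param pole_positions Matrix with one pole per row (micrometers,
#'   z/y/x), a \linkS4class{SpindleFrame}, or \code{NULL} to skip the
#'   pole filter.
#' @return The table with logical columns \code{oversize},
#'   \code{pole_coincident} and \code{qc_pass}. The volume distribution is
#'   computed over the table as given (one experiment/batch); with fewer
#'   than 4 spots the size filter is skipped with a warning.
#' @export
qcFilterSpots <- function(spots, qc, pole_positions = NULL) {
  stopifnot(inherits(qc, "QCConfig"))
  n <- nrow(spots)
  oversize <- rep(FALSE, n)
  if (n >= 4L) {
    q <- quantile(spots$volume_um3, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    hi <- q[2L] + qc$iqr_multiplier * iqr
    oversize <- spots$volume_um3 > hi
    if (qc$volume_rule == "tukey_two_sided")
      oversize <- oversize | spots$volume_um3 < q[1L] - qc$iqr_multiplier * iqr
  } else if (n > 0L) {
    warning("fewer than 4 spots: size filter skipped", call. = FALSE)
  }

  pole_coincident <- rep(FALSE, n)
  if (!is.null(pole_positions) && n > 0L) {
    if (is(pole_positions, "SpindleFrame"))
      pole_positions <- rbind(poleA(pole_positions), poleB(pole_positions))
    pole_positions <- matrix(pole_positions, ncol = 3L)
    cent <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
    for (k in seq_len(nrow(pole_positions))) {
      dists <- sqrt(rowSums(
        (cent - matrix(pole_positions[k, ], n, 3L, byrow = TRUE))^2))
      pole_coincident <- pole_coincident | dists <= qc$pole_exclusion_radius
    }
  }
  spots$oversize <- oversize
  spots$pole_coincident <- pole_coincident
  spots$qc_pass <- !oversize & !pole_coincident
  spots
}

#' Flag cells with aberrant kinetochore numbers
#'
#' A cell is a count outlier when its number of QC-passing kinetochores
#' lies outside \code{[Q1 - m*IQR, Q3 + m*IQR]} of the per-cell count
#' distribution (two-sided: both missed and doubled complements are
#' aberrant).
#'
#' @param spots Spot table with \code{cell_id} and, if present, the
#'   \code{qc_pass} column from \code{\link{qcFilterSpots}} (all spots
#'   count otherwise).
#' @param qc A \code{\link{qcConfig}}.
#' @return A data.frame with one row per cell: \code{cell_id},
#'   \code{kinetochore_count}, \code{count_outlier}. With fewer than 4
#'   cells the filter is skipped with a warning (no cell flagged).
#' @export
qcFilterCells <- function(spots, qc) {
  stopifnot(inherits(qc, "QCConfig"))
  pass <- if ("qc_pass" %in% names(spots)) spots$qc_pass else
    rep(TRUE, nrow(spots))
  counts <- table(factor(spots$cell_id[pass],
                         levels = unique(spots$cell_id)))
  out <- data.frame(cell_id = names(counts),
                    kinetochore_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (nrow(out) >= 4L) {
    q <- quantile(out$kinetochore_count, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    out$count_outlier <-
      out$kinetochore_count < q[1L] - qc$iqr_multiplier * iqr |
      out$kinetochore_count > q[2L] + qc$iqr_multiplier * iqr
  } else {
    warning("fewer than 4 cells: count filter skipped", call. = FALSE)
    out$count_outlier <- FALSE
  }
  out
}

#' Call SAC-positive kinetochores against a reference condition
#'
#' A kinetochore is SAC-positive at percentile p when its corrected SAC
#' channel intensity is strictly greater than the p-th percentile (linear
#' interpolation between order statistics) of the corrected SAC intensity
#' over all QC-passing spots of the reference (vehicle-control, e.g.
#' DMSO) condition.
#'
#' @param spots Spot table to classify (needs the corrected SAC column).
#' @param reference Reference-condition spot table, quantified with the
#'   same channel and correction.
#' @param percentiles Percentiles to call (default 90/95/99).
#' @param channel SAC channel name (column \code{corrected_<channel>}).
#' @return \code{spots} with one logical column
#'   \code{sac_positive_p<percentile>} per requested percentile; the
#'   thresholds are attached as attribute \code{sac_thresholds}.
#' @export
classifySacPositive <- function(spots, reference, percentiles = c(90, 95, 99),
                                channel = "sac") {
  col <- paste0("corrected_", channel)
  if (!nrow(reference)) stop("empty reference table", call. = FALSE)
  if (!col %in% names(reference) || !col %in% names(spots))
    stop("column '", col, "' missing; run quantifySpots first",
         call. = FALSE)
  ref <- reference
  if ("qc_pass" %in% names(ref)) ref <- ref[ref$qc_pass, , drop = FALSE]
  if (!nrow(ref)) stop("no QC-passing reference spots", call. = FALSE)
  thresholds <- setNames(
    quantile(ref[[col]], percentiles / 100, names = FALSE, type = 7),
    paste0("p", percentiles))
  for (p in seq_along(percentiles)) {
    spots[[paste0("sac_positive_p", percentiles[p])]] <-
      spots[[col]] > thresholds[p]
  }
  attr(spots, "sac_thresholds") <- thresholds
  spots
}

#' Per-cell summaries of kinetochore signal
#'
#' Summarizes QC-passing spots per cell: mean corrected intensity per
#' channel, cumulative (summed) corrected intensity per cell, and
#' SAC-positive counts at each called percentile. Cells with zero passing
#' spots are omitted with a message.
#'
#' @param spots Quantified, QC-flagged (and optionally SAC-classified)
#'   spot table.
#' @param channels Channels to summarize (default: every channel with a
#'   \code{corrected_*} column).
#' @return A data.frame, one row per cell, with columns \code{cell_id},
#'   \code{n_spots}, \code{mean_corrected_<ch>}, \code{cumulative_<ch>}
#'   and \code{n_sac_positive_p<percentile>} where SAC calls are present.
#' @export
summarizeCells <- function(spots, channels = NULL) {
  if ("qc_pass" %in% names(spots)) spots <- spots[spots$qc_pass, ,
                                                  drop = FALSE]
  if (is.null(channels)) {
    channels <- sub("^corrected_", "",
                    grep("^corrected_", names(spots), value = TRUE))
  }
  all_cells <- unique(spots$cell_id)
  split_spots <- split(spots, factor(spots$cell_id, levels = all_cells))
  kept <- vapply(split_spots, nrow, integer(1)) > 0L
  if (any(!kept))
    message(sum(!kept), " cell(s) with zero QC-passing spots omitted")
  split_spots <- split_spots[kept]
  sac_cols <- grep("^sac_positive_p", names(spots), value = TRUE)
  rows <- lapply(split_spots, function(df) {
    row <- data.frame(cell_id = df$cell_id[1L], n_spots = nrow(df),
                      stringsAsFactors = FALSE)
    for (ch in channels) {
      v <- df[[paste0("corrected_", ch)]]
      row[[paste0("mean_corrected_", ch)]] <- mean(v)
      row[[paste0("cumulative_", ch)]] <- sum(v)
    }
    for (sc in sac_cols)
      row[[sub("^sac_positive_", "n_sac_positive_", sc)]] <- sum(df[[sc]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SAC-response defect score from condition-mean signals
#'
#' Positions a treatment's kinetochore signal between the vehicle control
#' and the full checkpoint response induced by spindle collapse:
#' \deqn{defect = (S_{treated} - S_{DMSO}) /
#'   (S_{Nocodazole} - S_{DMSO}) \times 100}
#' A value of 100 means the treatment induced the full nocodazole-level
#' response; values outside \code{[0, 100]} are possible.
#'
#' @param signal_treated,signal_dmso,signal_nocodazole Condition-mean
#'   signals (arbitrary units).
#' @return Percent defect (scalar).
#' @examples
#' defectScore(1.5, 1.0, 2.0)  # 50
#' @export
defectScore <- function(signal_treated, signal_dmso, signal_nocodazole) {
  stopifnotScalar(signal_treated, "signal_treated")
  stopifnotScalar(signal_dmso, "signal_dmso")
  stopifnotScalar(signal_nocodazole, "signal_nocodazole")
  denom <- signal_nocodazole - signal_dmso
  if (denom == 0)
    stop("zero denominator: nocodazole and DMSO signals are equal",
         call. = FALSE)
  (signal_treated - signal_dmso) / denom * 100
}
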
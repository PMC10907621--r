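#' Configuration for the synthetic kinetochore volume generator
#'
#' Bundles the imaging geometry, spot model and artifact rates used by
#' \code{\link{makeKinetochoreVolume}}. Defaults emulate fixed-cell
#' widefield imaging of a metaphase cell: 0.2-um z-sections, ~65-nm
#' lateral pixels, kinetochores scattered through a metaphase-plate slab
#' between two spindle poles.
#'
#' @param seed Integer; fixes every random draw of the generator.
#' @param voxel_size Voxel size in micrometers, order (z, y, x).
#' @param image_shape Volume shape in voxels (z, y, x).
#' @param n_kinetochores Number of kinetochore objects to plant (46 by
#'   default, a near-diploid metaphase complement).
#' @param spot_sigma Lateral PSF sigma of a kinetochore spot in
#'   micrometers; the axial sigma is \code{sigma_z_factor} times larger
#'   (widefield axial elongation).
#' @param sigma_z_factor Axial-to-lateral sigma ratio (default 2.5).
#' @param plate_half_thickness Half-thickness of the metaphase-plate slab
#'   along the spindle (y) axis, micrometers.
#' @param spindle_half_length Pole-to-midline distance, micrometers.
#' @param plate_radius_x,plate_radius_z Lateral plate radii, micrometers.
#' @param snr Peak spot amplitude divided by the background noise standard
#'   deviation \code{sqrt(background + read_noise_sd^2)}.
#' @param background Mean camera background (counts).
#' @param read_noise_sd Additive Gaussian read-noise sd (counts).
#' @param intensity_cv Lognormal coefficient of variation of per-spot
#'   amplitudes.
#' @param sac_relative_amplitude SAC (MAD1-role) channel amplitude of a
#'   baseline spot relative to the reference channel amplitude.
#' @param sac_positive_rate Fraction of spots planted with elevated SAC
#'   signal.
#' @param sac_positive_scale Fold-increase of SAC amplitude on those spots.
#' @param artifact_rates Named list with fractions \code{fused_pair}
#'   (merged double-intensity spots), \code{pole_coincident} (spots planted
#'   on a spindle pole) and \code{aberrant_count} (probability that the
#'   cell carries a doubled kinetochore complement).
#' @param min_distance Minimum center-to-center distance (micrometers)
#'   enforced by rejection sampling between planted objects; fused-pair
#'   partners are exempt, and the axial (z) separation is measured in
#'   units of the axial sigma so the exclusion zone matches the
#'   anisotropic PSF. Defaults to \code{6 * spot_sigma}, wide enough that
#'   distinct spots stay resolvable at segmentation thresholds down to a
#'   quarter of the peak amplitude without the inter-spot saddle
#'   breaching it.
#' @param noise Logical; \code{FALSE} produces a noiseless volume
#'   (signal + constant background) for exactness checks.
#' @return A list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(seed = 1L,
                        voxel_size = c(0.2, 0.065, 0.065),
                        image_shape = c(36L, 200L, 140L),
                        n_kinetochores = 46L,
                        spot_sigma = 0.1,
                        sigma_z_factor = 2.5,
                        plate_half_thickness = 0.9,
                        spindle_half_length = 5,
                        plate_radius_x = 3.5,
                        plate_radius_z = 2.2,
                        snr = 10,
                        background = 100,
                        read_noise_sd = 5,
                        intensity_cv = 0.15,
                        sac_relative_amplitude = 0.5,
                        sac_positive_rate = 0,
                        sac_positive_scale = 5,
                        artifact_rates = list(fused_pair = 0,
                                              pole_coincident = 0,
                                              aberrant_count = 0),
                        min_distance = NULL,
                        noise = TRUE) {
  rates <- list(fused_pair = 0, pole_coincident = 0, aberrant_count = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop("artifact rates must be in [0, 1]", call. = FALSE)
  stopifnotScalar(snr, "snr", positive = TRUE)
  stopifnotScalar(spot_sigma, "spot_sigma", positive = TRUE)
  cfg <- list(seed = as.integer(seed), voxel_size = as.numeric(voxel_size),
              image_shape = as.integer(image_shape),
              n_kinetochores = as.integer(n_kinetochores),
              spot_sigma = spot_sigma, sigma_z_factor = sigma_z_factor,
              plate_half_thickness = plate_half_thickness,
              spindle_half_length = spindle_half_length,
              plate_radius_x = plate_radius_x,
              plate_radius_z = plate_radius_z,
              snr = snr, background = background,
              read_noise_sd = read_noise_sd,
              intensity_cv = intensity_cv,
              sac_relative_amplitude = sac_relative_amplitude,
              sac_positive_rate = sac_positive_rate,
              sac_positive_scale = sac_positive_scale,
              artifact_rates = rates,
              min_distance = min_distance %||% (6 * spot_sigma),
              noise = isTRUE(noise))
  class(cfg) <- "SynthConfig"
  cfg
}

## Add an anisotropic Gaussian of peak `amp` at micrometer position `pos`
## to 3D array `arr`; returns list(arr, integral) where integral is the
## planted (window-truncated) integrated intensity.
addGaussianSpot <- function(arr, pos, amp, sigma_um, voxel_size,
                            extent = 4) {
  d <- dim(arr)
  ctr <- pos / voxel_size            # 0-based voxel coordinates
  sig <- sigma_um / voxel_size       # sigma in voxels per axis
  lo <- pmax(0L, floor(ctr - extent * sig))
  hi <- pmin(d - 1L, ceiling(ctr + extent * sig))
  if (any(lo > hi)) return(list(arr = arr, integral = 0))
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  gz <- exp(-((zi - ctr[1L])^2) / (2 * sig[1L]^2))
  gy <- exp(-((yi - ctr[2L])^2) / (2 * sig[2L]^2))
  gx <- exp(-((xi - ctr[3L])^2) / (2 * sig[3L]^2))
  g <- amp * (gz %o% gy %o% gx)
  arr[zi + 1L, yi + 1L, xi + 1L] <-
    arr[zi + 1L, yi + 1L, xi + 1L] + g
  list(arr = arr, integral = sum(g))
}

#' Generate a synthetic 3-channel kinetochore volume with ground truth
#'
#' Plants anisotropic 3D Gaussian kinetochore spots around a
#' metaphase-plate geometry in a reference channel (CENP-A/BUBR1 role) and
#' a SAC channel (MAD1 role), plus two pole blobs in a pole channel
#' (CEP192 role). Spots are placed by rejection sampling with a minimum
#' center distance; planted artifacts (merged "fused-pair" spots,
#' pole-coincident spots, aberrant kinetochore complements) are recorded in
#' the returned ground-truth table. Noise is Poisson shot noise on
#' signal-plus-background with additive Gaussian read noise.
#'
#' @param config A \code{\link{synthConfig}} list.
#' @return A list with elements:
#' \describe{
#'   \item{volume}{\linkS4class{ImageVolume} with channels
#'     \code{reference}, \code{sac}, \code{pole}.}
#'   \item{truth}{data.frame, one row per planted object: \code{spot_id},
#'     \code{class} (\code{normal}/\code{fused_pair}/\code{pole_coincident}),
#'     centroid \code{z_um}/\code{y_um}/\code{x_um}, planted integrated
#'     intensities \code{true_ref}/\code{true_sac}, and \code{sac_high}.
#'     Attributes carry the pole positions (\code{poles}, micrometers),
#'     \code{background}, \code{noise_sd}, a \code{suggested_threshold}
#'     for segmentation, the \code{aberrant_count} cell flag and the
#'     config echo.}
#' }
#' @examples
#' cfg <- synthConfig(seed = 1, n_kinetochores = 10,
#'                    image_shape = c(20, 120, 90))
#' out <- makeKinetochoreVolume(cfg)
#' nrow(out$truth)
#' @export
makeKinetochoreVolume <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withSeed(config$seed, makeKinetochoreVolumeImpl(config))
}

makeKinetochoreVolumeImpl <- function(config) {
  vs <- config$voxel_size
  d <- config$image_shape
  extent_um <- (d - 1) * vs
  center <- extent_um / 2

  aberrant <- runif(1) < config$artifact_rates$aberrant_count
  n <- config$n_kinetochores * if (aberrant) 2L else 1L
  n_fused <- round(config$artifact_rates$fused_pair * n)
  n_pole <- round(config$artifact_rates$pole_coincident * n)
  n_normal <- n - n_fused - n_pole
  if (n_normal < 0) stop("artifact rates exceed the spot budget")

  poles <- rbind(
    center + c(0, -config$spindle_half_length, 0),
    center + c(0, config$spindle_half_length, 0))

  ## --- placement by rejection sampling --------------------------------
  samplePlate <- function() {
    for (i in 1:1000) {
      y <- center[2L] + runif(1, -1, 1) * config$plate_half_thickness
      z <- center[1L] + runif(1, -1, 1) * config$plate_radius_z
      x <- center[3L] + runif(1, -1, 1) * config$plate_radius_x
      if (((z - center[1L]) / config$plate_radius_z)^2 +
          ((x - center[3L]) / config$plate_radius_x)^2 <= 1)
        return(c(z, y, x))
    }
    stop("plate sampling failed")
  }
  placed <- matrix(numeric(0), 0, 3)
  ## PSF-anisotropic exclusion: z separations count in axial-sigma units
  scale <- c(1 / config$sigma_z_factor, 1, 1)
  placeOne <- function() {
    for (try in 1:1000) {
      p <- samplePlate()
      if (nrow(placed) == 0L ||
          min(sqrt(rowSums(sweep(placed - matrix(p, nrow(placed), 3,
                                                 byrow = TRUE),
                                 2L, scale, `*`)^2))) >=
            config$min_distance)
        return(p)
    }
    stop("placement failure: could not satisfy the minimum spot distance ",
         "after 1000 retries (overcrowded configuration)", call. = FALSE)
  }

  classes <- c(rep("normal", n_normal), rep("fused_pair", n_fused),
               rep("pole_coincident", n_pole))
  centers <- vector("list", n)
  for (i in seq_len(n)) {
    if (classes[i] == "pole_coincident") {
      pole <- poles[sample.int(2L, 1L), ]
      centers[[i]] <- pole + runif(3, -0.2, 0.2)
    } else {
      p <- placeOne()
      placed <- rbind(placed, p)
      centers[[i]] <- p
    }
  }

  ## --- amplitudes ------------------------------------------------------
  noise_sd <- sqrt(config$background + config$read_noise_sd^2)
  amp0 <- config$snr * noise_sd
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  ref_amp <- amp0 * rlnorm(n, -sdlog^2 / 2, sdlog)
  sac_high <- runif(n) < config$sac_positive_rate
  sac_amp <- amp0 * config$sac_relative_amplitude *
    rlnorm(n, -sdlog^2 / 2, sdlog) *
    ifelse(sac_high, config$sac_positive_scale, 1)

  sigma <- c(config$sigma_z_factor * config$spot_sigma, config$spot_sigma,
             config$spot_sigma)

  ref <- array(0, d); sac <- array(0, d); pol <- array(0, d)
  true_ref <- numeric(n); true_sac <- numeric(n)
  centroid <- matrix(0, n, 3)

  for (i in seq_len(n)) {
    if (classes[i] == "fused_pair") {
      ## two merged spots separated by ~2 lateral sigma within the plate
      theta <- runif(1, 0, 2 * pi)
      offset <- config$spot_sigma * c(0, sin(theta), cos(theta))
      sub <- list(centers[[i]] - offset, centers[[i]] + offset)
      amps_r <- ref_amp[i] * c(1, rlnorm(1, -sdlog^2 / 2, sdlog))
      amps_s <- sac_amp[i] * c(1, rlnorm(1, -sdlog^2 / 2, sdlog))
    } else {
      sub <- list(centers[[i]])
      amps_r <- ref_amp[i]; amps_s <- sac_amp[i]
    }
    for (j in seq_along(sub)) {
      res <- addGaussianSpot(ref, sub[[j]], amps_r[j], sigma, vs)
      ref <- res$arr; true_ref[i] <- true_ref[i] + res$integral
      res <- addGaussianSpot(sac, sub[[j]], amps_s[j], sigma, vs)
      sac <- res$arr; true_sac[i] <- true_sac[i] + res$integral
    }
    w <- amps_r / sum(amps_r)
    centroid[i, ] <- Reduce(`+`, Map(`*`, sub, w))
  }

  pole_sigma <- rep(0.4, 3)
  for (k in 1:2)
    pol <- addGaussianSpot(pol, poles[k, ], 10 * amp0, pole_sigma, vs)$arr

  addNoise <- function(signal) {
    if (!config$noise) return(signal + config$background)
    lam <- signal + config$background
    noisy <- array(rpois(length(lam), lam), d) +
      array(rnorm(length(lam), 0, config$read_noise_sd), d)
    noisy
  }
  vol <- array(0, c(d, 3L))
  vol[, , , 1L] <- addNoise(ref)
  vol[, , , 2L] <- addNoise(sac)
  vol[, , , 3L] <- addNoise(pol)

  truth <- data.frame(
    spot_id = seq_len(n), class = classes,
    z_um = centroid[, 1L], y_um = centroid[, 2L], x_um = centroid[, 3L],
    true_ref = true_ref, true_sac = true_sac, sac_high = sac_high,
    stringsAsFactors = FALSE)
  attr(truth, "poles") <- poles
  attr(truth, "background") <- config$background
  attr(truth, "noise_sd") <- noise_sd
  attr(truth, "suggested_threshold") <- config$background + 0.25 * amp0
  attr(truth, "aberrant_count") <- aberrant
  attr(truth, "config") <- config

  list(volume = ImageVolume(vol, voxelSize = vs,
                            channelNames = c("reference", "sac", "pole")),
       truth = truth)
}
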
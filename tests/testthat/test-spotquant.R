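## spot table stub for QC/classification rule tests
spotStub <- function(volumes = NULL, sac = NULL, cell = "c1",
                     z = 0, y = 0, x = 0) {
  n <- max(length(volumes), length(sac), length(z), length(y), length(x))
  df <- data.frame(cell_id = rep_len(cell, n), spot_id = seq_len(n),
                   z_um = rep_len(z, n), y_um = rep_len(y, n),
                   x_um = rep_len(x, n),
                   voxel_count = 10L, stringsAsFactors = FALSE)
  df$volume_um3 <- if (is.null(volumes)) 1 else volumes
  if (!is.null(sac)) df$corrected_sac <- sac
  df
}

test_that("segmentation recovers well-separated planted spots", {
  out <- makeKinetochoreVolume(synthConfig(seed = 21))
  qc <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
  seg <- segmentSpots(out$volume, "reference", qc)
  expect_equal(nrow(seg$spots), 46)
  ## centroids land on the planted positions
  d <- vapply(seq_len(nrow(out$truth)), function(i) {
    min(sqrt((seg$spots$z_um - out$truth$z_um[i])^2 +
             (seg$spots$y_um - out$truth$y_um[i])^2 +
             (seg$spots$x_um - out$truth$x_um[i])^2))
  }, numeric(1))
  expect_lt(max(d), 0.15)
})

test_that("an all-zero volume yields an empty spot table", {
  vol <- ImageVolume(array(0, c(8, 16, 16)))
  seg <- segmentSpots(vol, 1L, qcConfig(threshold = 0.5))
  expect_equal(nrow(seg$spots), 0L)
})

test_that("a planted fused pair segments as one oversized component", {
  cfg <- synthConfig(seed = 22, n_kinetochores = 20,
                     artifact_rates = list(fused_pair = 0.05))
  pipe <- runSpotPipeline(cfg, channels = "reference")
  expect_equal(sum(pipe$truth$class == "fused_pair"), 1L)
  fused_row <- pipe$truth$matched_spot[pipe$truth$class == "fused_pair"]
  singles <- pipe$spots$volume_um3[-fused_row]
  ratio <- pipe$spots$volume_um3[fused_row] / median(singles)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
  expect_true(pipe$spots$oversize[fused_row])
})

test_that("background estimation matches its definition", {
  ## uniform background, no spots
  vol <- ImageVolume(array(7.5, c(6, 10, 10)))
  labels <- array(0L, c(6, 10, 10))
  expect_identical(estimateBackground(vol, labels, 1L), 7.5)

  ## spot brightness cannot leak into the background estimate
  img <- array(7.5, c(6, 10, 10))
  img[3, 5, 5] <- 1e6
  labels[3, 5, 5] <- 1L
  expect_identical(estimateBackground(ImageVolume(img), labels, 1L), 7.5)

  ## noisy synthetic volume: within 2% of the planted background
  out <- makeKinetochoreVolume(synthConfig(seed = 23, n_kinetochores = 20,
                                           image_shape = c(24L, 140L, 100L)))
  qc <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
  seg <- segmentSpots(out$volume, "reference", qc)
  bg <- estimateBackground(out$volume, seg$labels, "reference")
  expect_lt(abs(bg - attr(out$truth, "background")) /
              attr(out$truth, "background"), 0.02)

  expect_error(estimateBackground(vol, array(1L, c(6, 10, 10)), 1L),
               "no unlabeled")
})

test_that("noiseless corrected integrals equal planted amplitudes exactly", {
  cfg <- synthConfig(seed = 24, n_kinetochores = 5, noise = FALSE,
                     min_distance = 1.5)
  out <- makeKinetochoreVolume(cfg)
  qc <- qcConfig(threshold = cfg$background + 1e-9,
                 min_voxels = 10L)
  seg <- segmentSpots(out$volume, "reference", qc)
  expect_equal(nrow(seg$spots), 5L)
  sp <- quantifySpots(seg$spots, out$volume, seg$labels,
                      c(reference = cfg$background))
  m <- vapply(seq_len(5L), function(i) {
    which.min((sp$z_um - out$truth$z_um[i])^2 +
              (sp$y_um - out$truth$y_um[i])^2 +
              (sp$x_um - out$truth$x_um[i])^2)
  }, integer(1))
  expect_equal(sp$corrected_reference[m], out$truth$true_ref,
               tolerance = 1e-9)  # summation order roundoff only
})

test_that("correction is linear in the background estimate", {
  out <- makeKinetochoreVolume(synthConfig(seed = 25, n_kinetochores = 8,
                                           image_shape = c(24L, 140L, 100L)))
  qc <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
  seg <- segmentSpots(out$volume, "reference", qc)
  sp1 <- quantifySpots(seg$spots, out$volume, seg$labels, c(reference = 50))
  sp2 <- quantifySpots(seg$spots, out$volume, seg$labels, c(reference = 100))
  expect_equal(sp1$corrected_reference - sp2$corrected_reference,
               50 * sp1$voxel_count, tolerance = 1e-12)

  ## a pure-background spot corrects to zero
  img <- array(3, c(6, 8, 8))
  labels <- array(0L, c(6, 8, 8)); labels[2:4, 3:5, 3:5] <- 1L
  stub <- data.frame(cell_id = "c", spot_id = 1L, z_um = 0, y_um = 0,
                     x_um = 0, voxel_count = sum(labels == 1L),
                     volume_um3 = 1)
  got <- quantifySpots(stub, ImageVolume(img, channelNames = "ch"),
                       labels, c(ch = 3))
  expect_identical(got$corrected_ch, 0)
})

test_that("background and integration match a voxel-loop oracle", {
  cfg <- synthConfig(seed = 26, n_kinetochores = 3,
                     image_shape = c(16L, 32L, 32L),
                     plate_half_thickness = 0.4, plate_radius_x = 0.7,
                     plate_radius_z = 0.7, spindle_half_length = 0.8)
  out <- makeKinetochoreVolume(cfg)
  qc <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
  seg <- segmentSpots(out$volume, "reference", qc)
  img <- imageData(out$volume, "reference")
  bg <- estimateBackground(out$volume, seg$labels, "reference")
  expect_equal(bg, bruteBackground(img, seg$labels), tolerance = 1e-12)
  sp <- quantifySpots(seg$spots, out$volume, seg$labels,
                      c(reference = bg))
  for (i in seq_len(nrow(sp)))
    expect_equal(sp$corrected_reference[i],
                 max(bruteIntegrate(img, seg$labels, i, bg), 0),
                 tolerance = 1e-12)
})

test_that("oversize flagging follows the one-sided Tukey rule", {
  tab <- spotStub(volumes = c(1, 1, 1, 1, 1, 3))
  got <- qcFilterSpots(tab, qcConfig())
  expect_identical(got$oversize, c(rep(FALSE, 5), TRUE))
  ## flags only, never deletions; QC is idempotent
  expect_equal(nrow(got), 6L)
  expect_identical(qcFilterSpots(got, qcConfig())$oversize, got$oversize)

  expect_warning(qcFilterSpots(spotStub(volumes = c(1, 5)), qcConfig()),
                 "size filter skipped")
})

test_that("pole-coincident spots are flagged by centroid distance", {
  tab <- spotStub(volumes = rep(1, 5), z = c(0, 0, 0, 0, 2),
                  y = c(0, 1.5, 3, 9, 5), x = 0)
  poles <- rbind(c(0, 0, 0), c(0, 9, 0))
  got <- qcFilterSpots(tab, qcConfig(), poles)
  expect_identical(got$pole_coincident, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("aberrant kinetochore counts are flagged two-sided", {
  tab <- spotStub(volumes = rep(1, 46 * 9 + 92),
                  cell = c(rep(paste0("c", 1:9), each = 46),
                           rep("c10", 92)))
  got <- qcFilterCells(tab, qcConfig())
  expect_identical(got$count_outlier,
                   c(rep(FALSE, 9), TRUE))

  same <- spotStub(volumes = rep(1, 46 * 5),
                   cell = rep(paste0("c", 1:5), each = 46))
  expect_false(any(qcFilterCells(same, qcConfig())$count_outlier))

  expect_warning(qcFilterCells(spotStub(volumes = rep(1, 6),
                                        cell = rep(c("a", "b", "c"), 2)),
                               qcConfig()),
                 "count filter skipped")

  ## planted aberrant complements (doubled and halved) are caught
  set.seed(31)
  counts <- c(46 + sample(-2:2, 18, replace = TRUE), 92, 23)
  tab2 <- spotStub(volumes = rep(1, sum(counts)),
                   cell = rep(sprintf("c%02d", seq_along(counts)), counts))
  got2 <- qcFilterCells(tab2, qcConfig())
  expect_true(all(got2$count_outlier[19:20]))
  expect_false(any(got2$count_outlier[1:18]))
})

test_that("SAC-positive calling hits the nominal reference tail", {
  ref <- spotStub(sac = as.numeric(1:100))
  ref$qc_pass <- TRUE
  got <- classifySacPositive(ref, ref, percentiles = 95)
  expect_equal(sum(got$sac_positive_p95), 5L)

  ## identical sample and reference: positive fraction matches the tail
  got90 <- classifySacPositive(ref, ref, percentiles = c(90, 99))
  expect_equal(sum(got90$sac_positive_p90), 10L)
  expect_equal(sum(got90$sac_positive_p99), 1L)

  ## planted high-signal spots well above threshold are all recalled
  set.seed(32)
  treated <- spotStub(sac = c(rlnorm(80, 0, 0.2),
                              5 * quantile(1:100, 0.95) * rlnorm(20, 0, 0.1)))
  calls <- classifySacPositive(treated, ref, percentiles = 95)
  expect_true(all(calls$sac_positive_p95[81:100]))

  expect_error(classifySacPositive(ref, ref[0, ], percentiles = 95),
               "empty reference")
})

test_that("per-cell summaries aggregate only QC-passing spots", {
  tab <- spotStub(sac = c(2, 4, 6))
  tab$corrected_ref <- c(2, 4, 6)
  tab$qc_pass <- TRUE
  s <- summarizeCells(tab, channels = "ref")
  expect_equal(s$mean_corrected_ref, 4)
  expect_equal(s$cumulative_ref, 12)

  ## doubling spot count at equal signal doubles cumulative, not mean
  tab2 <- spotStub(sac = rep(c(2, 4, 6), 2))
  tab2$corrected_ref <- rep(c(2, 4, 6), 2)
  tab2$qc_pass <- TRUE
  s2 <- summarizeCells(tab2, channels = "ref")
  expect_equal(s2$mean_corrected_ref, 4)
  expect_equal(s2$cumulative_ref, 24)

  ## flagged spots drop out
  tab$qc_pass <- c(TRUE, TRUE, FALSE)
  s3 <- summarizeCells(tab, channels = "ref")
  expect_equal(s3$mean_corrected_ref, 3)
  expect_equal(s3$cumulative_ref, 6)
})

test_that("the SAC defect score interpolates between control conditions", {
  expect_equal(defectScore(2.0, 1.0, 2.0), 100)
  expect_equal(defectScore(1.0, 1.0, 2.0), 0)
  expect_equal(defectScore(1.5, 1.0, 2.0), 50)
  expect_error(defectScore(1.5, 1.0, 1.0), "denominator")
})
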
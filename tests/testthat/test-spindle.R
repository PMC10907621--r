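test_that("pole localization recovers planted pole centroids", {
  out <- makeKinetochoreVolume(synthConfig(seed = 41, n_kinetochores = 10,
                                           noise = FALSE))
  frame <- locatePoles(out$volume)
  poles <- attr(out$truth, "poles")
  ## match found poles to planted poles by proximity
  found <- rbind(poleA(frame), poleB(frame))
  found <- found[order(found[, 2]), ]
  poles <- poles[order(poles[, 2]), ]
  expect_lt(max(abs(found - poles)), 0.02)
  expect_equal(spindleLength(frame), 10, tolerance = 1e-3)
  expect_false(isMultipolar(frame))
})

test_that("multipolar volumes warn and use the two brightest poles", {
  img <- array(0, c(16, 60, 60, 1))
  vol0 <- ImageVolume(img[, , , 1], voxelSize = c(0.2, 0.1, 0.1),
                      channelNames = "pole")
  add <- function(v, pos, amp) {
    mitoquant:::addGaussianSpot(v, pos, amp, c(0.4, 0.3, 0.3),
                                c(0.2, 0.1, 0.1))$arr
  }
  a <- add(array(0, c(16, 60, 60)), c(1.5, 1.0, 3.0), 100)
  a <- add(a, c(1.5, 5.0, 3.0), 90)
  a <- add(a, c(1.5, 3.0, 1.0), 50)   # dim extra pole
  vol <- ImageVolume(a, voxelSize = c(0.2, 0.1, 0.1), channelNames = "pole")
  qc <- qcConfig(threshold = 5)
  expect_warning(frame <- locatePoles(vol, "pole", qc), "multipolar")
  expect_true(isMultipolar(frame))
  expect_equal(spindleLength(frame), 4, tolerance = 0.05)

  empty <- ImageVolume(array(0, c(8, 16, 16)), channelNames = "pole")
  expect_error(locatePoles(empty, "pole", qc), "fewer than two")
})

test_that("axis positions are signed projections from the midline", {
  frame <- SpindleFrame(c(2, 1, 5), c(2, 11, 5))  # axis along y, length 10
  expect_equal(axisPosition(c(2, 6, 5), frame), 0)
  expect_equal(abs(axisPosition(c(2, 1, 5), frame)), 5)
  ## perpendicular offsets do not contribute
  expect_equal(axisPosition(c(2, 6, 8), frame), 0)
  expect_equal(abs(axisPosition(c(0, 1, 9), frame)), 5)
})

test_that("positions and regions are rigid-motion invariant", {
  set.seed(42)
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  colnames(pts) <- c("z_um", "y_um", "x_um")
  pA <- c(1, 2, 3); pB <- c(7, 8, 4)
  frame <- SpindleFrame(pA, pB)
  pos <- axisPosition(pts, frame)

  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  shift <- c(3, -2, 5)
  rot <- function(p) as.vector(R %*% p) + shift
  ptsR <- t(apply(pts, 1, rot))
  frameR <- SpindleFrame(rot(pA), rot(pB))
  posR <- axisPosition(ptsR, frameR)
  ## sign convention may flip with the lexicographic pole ordering
  expect_equal(abs(posR), abs(pos), tolerance = 1e-10)
  expect_identical(classifyRegion(posR), classifyRegion(pos))
})

test_that("the central/polar partition respects the 5-um cutoff", {
  expect_identical(classifyRegion(c(0, 5, -5, 5.01, -7)),
                   c("central", "central", "central", "polar", "polar"))
  ## exhaustive and exclusive
  pos <- seq(-8, 8, by = 0.25)
  rg <- classifyRegion(pos)
  expect_true(all(rg %in% c("central", "polar")))
})

test_that("region positive fractions count cells, not spots", {
  spots <- data.frame(
    cell_id = rep(sprintf("c%02d", 1:10), each = 2),
    region = rep(c("central", "polar"), 10),
    sac_positive_p99 = FALSE)
  ## cells 1 and 2 each get one polar positive; cell 1 two of them
  spots$sac_positive_p99[spots$cell_id %in% c("c01", "c02") &
                           spots$region == "polar"] <- TRUE
  got <- regionPositiveFraction(spots)
  expect_equal(got$percent[got$region == "polar"], 20)
  expect_equal(got$percent[got$region == "central"], 0)

  expect_error(regionPositiveFraction(spots[0, ], cells = character(0)),
               "zero cells")
})
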
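## Independent brute-force oracles used to validate the package's
## implementations on small instances.

## Flood-fill connected-component labeling by BFS over an explicit
## neighbor scan: O(n * 27) but transparent.
bruteLabels3D <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextlab <- 0L
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1L, ]
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || lab[z, y, x] > 0L) next
    nextlab <- nextlab + 1L
    queue <- list(c(z, y, x))
    lab[z, y, x] <- nextlab
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        nb <- v + c(offs$dz[k], offs$dy[k], offs$dx[k])
        if (any(nb < 1L) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextlab
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

## Voxel-loop background + integration oracle.
bruteBackground <- function(img, labels) {
  vals <- c()
  d <- dim(img)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1]))
    if (labels[z, y, x] == 0L) vals <- c(vals, img[z, y, x])
  median(vals)
}

bruteIntegrate <- function(img, labels, id, background) {
  tot <- 0; nvox <- 0L
  d <- dim(img)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1]))
    if (labels[z, y, x] == id) {
      tot <- tot + img[z, y, x]; nvox <- nvox + 1L
    }
  tot - background * nvox
}

## Dense lattice search over the two-phase decay parameters; returns the
## minimum RSS on the grid.
gridTwoPhaseRSS <- function(times, values,
                            f_grid = seq(0, 1, by = 0.05),
                            t_grid = exp(seq(log(0.2), log(60),
                                             length.out = 40))) {
  best <- Inf
  for (f in f_grid) for (tf in t_grid) for (ts in t_grid) {
    if (tf > ts) next
    pred <- f * 2^(-times / tf) + (1 - f) * 2^(-times / ts)
    rss <- sum((values - pred)^2)
    if (rss < best) best <- rss
  }
  best
}

## Dense lattice search for the 4PL model (responses vs doses).
grid4PLRSS <- function(doses, responses) {
  rng <- range(responses)
  pad <- 0.2 * diff(rng)
  best <- Inf
  for (bottom in seq(rng[1] - pad, rng[1] + pad, length.out = 9))
    for (top in seq(rng[2] - pad, rng[2] + pad, length.out = 9))
      for (ic50 in exp(seq(log(min(doses)), log(max(doses)),
                           length.out = 25)))
        for (hill in c(seq(0.2, 4, by = 0.2), -seq(0.2, 4, by = 0.2))) {
          pred <- bottom + (top - bottom) / (1 + (doses / ic50)^hill)
          rss <- sum((responses - pred)^2)
          if (rss < best) best <- rss
        }
  best
}

## Two-sided Fisher p-value by enumeration over the hypergeometric
## support of the 2x2 table with fixed margins.
enumFisherP <- function(tab) {
  m <- sum(tab[1, ])          # hits
  n <- sum(tab[2, ])          # non-hits
  k <- sum(tab[, 1])          # in-set
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Shared spot-pipeline runner: generate one synthetic cell, segment,
## quantify, QC, and match each ground-truth object to its nearest
## detected component.
runSpotPipeline <- function(cfg, channels = c("reference", "sac")) {
  out <- makeKinetochoreVolume(cfg)
  qc <- qcConfig(threshold = attr(out$truth, "suggested_threshold"))
  seg <- segmentSpots(out$volume, "reference", qc,
                      cell_id = paste0("cell", cfg$seed))
  bg <- vapply(channels, function(ch)
    estimateBackground(out$volume, seg$labels, ch), numeric(1))
  spots <- quantifySpots(seg$spots, out$volume, seg$labels, bg)
  frame <- locatePoles(out$volume)
  spots <- qcFilterSpots(spots, qc, frame)
  truth <- out$truth
  ## nearest component for every truth object (truth-oriented matching)
  cent <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  truth$matched_spot <- apply(
    as.matrix(truth[, c("z_um", "y_um", "x_um")]), 1L,
    function(p) which.min(colSums((t(cent) - p)^2)))
  ## and nearest truth object for every component
  spots$matched_truth <- apply(cent, 1L, function(p)
    which.min(colSums((t(as.matrix(
      truth[, c("z_um", "y_um", "x_um")])) - p)^2)))
  list(volume = out$volume, truth = truth, spots = spots, labels = seg$labels,
       frame = frame, qc = qc, background = bg)
}
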
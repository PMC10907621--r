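## 3D connected-component labeling of a binary mask under 6- or
## 26-connectivity. Foreground voxels become graph vertices, edges join
## neighboring foreground voxels, and components are extracted with
## igraph. Returns an integer array of labels (0 = background); labels are
## renumbered deterministically by the smallest linear voxel index they
## contain, so the labeling is reproducible across platforms.

neighborOffsets <- function(connectivity = 26L) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (connectivity == 6L)
    g <- g[abs(g$dz) + abs(g$dy) + abs(g$dx) == 1L, ]
  else if (connectivity != 26L)
    stop("connectivity must be 6 or 26", call. = FALSE)
  ## half-neighborhood: each unordered voxel pair visited once
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) |
    (g$dz == 0 & g$dy == 0 & g$dx > 0)
  as.matrix(g[keep, , drop = FALSE])
}

labelComponents3D <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stop("'mask' must be a 3D array", call. = FALSE)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)

  nz <- d[1L]; ny <- d[2L]
  ## 0-based coordinates from linear indices (column-major, z fastest)
  i0 <- idx - 1L
  z <- i0 %% nz
  r <- i0 %/% nz
  y <- r %% ny
  x <- r %/% ny

  offs <- neighborOffsets(as.integer(connectivity))
  from <- integer(0); to <- integer(0)
  pos <- seq_along(idx)
  for (k in seq_len(nrow(offs))) {
    zn <- z + offs[k, 1L]; yn <- y + offs[k, 2L]; xn <- x + offs[k, 3L]
    ok <- zn >= 0L & zn < d[1L] & yn >= 0L & yn < d[2L] &
      xn >= 0L & xn < d[3L]
    if (!any(ok)) next
    nbr_lin <- zn[ok] + nz * (yn[ok] + ny * xn[ok]) + 1L
    m <- match(nbr_lin, idx)
    hit <- !is.na(m)
    from <- c(from, pos[ok][hit])
    to <- c(to, m[hit])
  }

  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  ## renumber components by their smallest member voxel index
  first_idx <- vapply(split(idx, comp), min, numeric(1))
  relabel <- match(seq_along(first_idx), order(first_idx))
  labels[idx] <- relabel[comp]
  labels
}
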
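# Low-level 3D raster operations shared by segmentation, surface extraction
# and texture code. Arrays are (z, y, x). EBImage's morphology/labelling is
# 2D, so the 3D variants are implemented here with vectorized shifts and
# frontier-based flood fill.

# separable 3D Gaussian blur; sigma in voxels per axis (dz, dy, dx order)
gaussian_blur3d <- function(arr, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  d <- dim(arr)
  blur_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dim(a)[axis]
    # replicate-pad along the axis, then weighted sum of shifted slabs
    idx_pad <- c(rep(1L, half), seq_len(n), rep(n, half))
    ap <- switch(axis, a[idx_pad, , , drop = FALSE],
                 a[, idx_pad, , drop = FALSE],
                 a[, , idx_pad, drop = FALSE])
    out <- array(0, dim = dim(a))
    for (j in seq_along(k)) {
      sl <- seq_len(n) + (j - 1L)
      out <- out + k[j] * switch(axis, ap[sl, , , drop = FALSE],
                                 ap[, sl, , drop = FALSE],
                                 ap[, , sl, drop = FALSE])
    }
    out
  }
  arr <- blur_axis(arr, 1L, sigma[1])
  arr <- blur_axis(arr, 2L, sigma[2])
  arr <- blur_axis(arr, 3L, sigma[3])
  arr
}

# neighbour offsets as a matrix (dz, dy, dx); 6- or 26-connectivity
neighbour_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

# flood fill over TRUE voxels of `mask` starting from linear-index seeds;
# returns a logical array of reached voxels. Vectorized frontier BFS.
flood3d <- function(mask, seeds, connectivity = 26L) {
  d <- dim(mask)
  nzy <- d[1] * d[2]
  offs <- neighbour_offsets(connectivity)
  lin_offs <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * nzy
  visited <- logical(length(mask))
  seeds <- seeds[mask[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    # subscripts of the frontier, for boundary guards
    f0 <- frontier - 1L
    z <- f0 %% d[1]
    y <- (f0 %/% d[1]) %% d[2]
    x <- f0 %/% nzy
    nxt <- integer(0)
    for (j in seq_len(nrow(offs))) {
      zz <- z + offs[j, 1]; yy <- y + offs[j, 2]; xx <- x + offs[j, 3]
      ok <- zz >= 0 & zz < d[1] & yy >= 0 & yy < d[2] & xx >= 0 & xx < d[3]
      cand <- frontier[ok] + lin_offs[j]
      cand <- cand[mask[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  array(visited, dim = d)
}

# connected components (26-connectivity); returns list(sizes, labels array)
label_components3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  remaining <- which(mask)
  lab <- 0L
  sizes <- integer(0)
  while (length(remaining)) {
    lab <- lab + 1L
    comp <- flood3d(mask & (labels == 0L), remaining[1], connectivity = 26L)
    labels[comp] <- lab
    sizes[lab] <- sum(comp)
    remaining <- remaining[labels[remaining] == 0L]
  }
  list(sizes = sizes, labels = labels)
}

# fill interior cavities: background not reachable from the border
# (6-connectivity on background) becomes foreground
fill_holes3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  # all border voxels as seeds
  idx <- array(seq_along(mask), dim = d)
  border <- c(idx[c(1, d[1]), , ], idx[, c(1, d[2]), ], idx[, , c(1, d[3])])
  reached <- flood3d(bg, unique(border[bg[border]]), connectivity = 6L)
  mask | (bg & !reached)
}

# binary dilation/erosion with a 3x3x3 box (26-neighbourhood) via shifts
shift3d <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  zs <- seq_len(d[1]); ys <- seq_len(d[2]); xs <- seq_len(d[3])
  src_z <- zs - dz; src_y <- ys - dy; src_x <- xs - dx
  okz <- src_z >= 1 & src_z <= d[1]
  oky <- src_y >= 1 & src_y <= d[2]
  okx <- src_x >= 1 & src_x <= d[3]
  out[zs[okz], ys[oky], xs[okx]] <- a[src_z[okz], src_y[oky], src_x[okx]]
  out
}

dilate3d <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out | shift3d(mask, dz, dy, dx, fill = FALSE)
  }
  out
}

erode3d <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out & shift3d(mask, dz, dy, dx, fill = TRUE)
  }
  out
}

# morphological closing, 1-voxel radius
close3d <- function(mask) erode3d(dilate3d(mask))
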
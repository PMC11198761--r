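# Internal numerical helpers.

# Partial derivative of a 3D array along one axis, central differences in
# the interior and one-sided at the grid edges; h in physical units (mm).
.gradientAxis <- function(a, h, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("grid must have >= 3 voxels per axis")
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  g <- ap
  g[2:(n - 1), , ] <- (ap[3:n, , , drop = FALSE] -
                       ap[1:(n - 2), , , drop = FALSE]) / (2 * h)
  g[1, , ] <- (ap[2, , ] - ap[1, , ]) / h
  g[n, , ] <- (ap[n, , ] - ap[n - 1, , ]) / h
  aperm(g, order(perm))
}

# 1D Gaussian kernel truncated at 3 sigma (sigma in voxels).
.gaussKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-((-r):r)^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigmaMM in mm per axis
# (scalar recycled), replicate-padding at edges.
.gaussSmooth3d <- function(a, sigmaMM, spacing) {
  sigmaMM <- rep(sigmaMM, length.out = 3)
  for (axis in 1:3) {
    sVox <- sigmaMM[axis] / spacing[axis]
    if (sVox <= 0) next
    k <- .gaussKernel(sVox)
    r <- (length(k) - 1L) %/% 2L
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    padTop <- m[rep(1L, r), , drop = FALSE]
    padBot <- m[rep(d[1], r), , drop = FALSE]
    mp <- rbind(padTop, m, padBot)
    out <- matrix(0, nrow = d[1], ncol = ncol(m))
    for (o in seq_along(k))
      out <- out + k[o] * mp[o:(o + d[1] - 1L), , drop = FALSE]
    a <- aperm(array(out, d), order(perm))
  }
  a
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Physical voxel-center coordinate arrays for a grid (0-based index * spacing).
.coordArrays <- function(gridShape, spacing) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  xs <- (seq_len(nx) - 1) * spacing[1]
  ys <- (seq_len(ny) - 1) * spacing[2]
  zs <- (seq_len(nz) - 1) * spacing[3]
  list(
    x = array(rep(xs, times = ny * nz), dim = gridShape),
    y = array(rep(rep(ys, each = nx), times = nz), dim = gridShape),
    z = array(rep(zs, each = nx * ny), dim = gridShape))
}

# Logical 3D array of mask voxels with at least one face-neighbor outside
# the mask (voxels on the volume edge count their missing neighbor as
# outside).
.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  shifted <- function(axis, step) {
    out <- array(FALSE, d)
    n <- d[axis]
    src <- seq_len(n) + step
    ok <- src >= 1L & src <= n
    idxTo <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idxFrom <- idxTo
    idxTo[[axis]] <- which(ok)
    idxFrom[[axis]] <- src[ok]
    out <- do.call(`[<-`, c(list(out), idxTo,
      list(do.call(`[`, c(list(mask), idxFrom, list(drop = FALSE))))))
    out
  }
  nOutside <- array(0L, d)
  for (axis in 1:3) for (step in c(-1L, 1L))
    nOutside <- nOutside + !shifted(axis, step)
  mask & (nOutside > 0L)
}
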
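# Low-level 3D morphology used by vessel segmentation: separable Gaussian
# smoothing, exact Euclidean distance transform (separable lower-envelope
# algorithm), 26-connected component labelling, and geodesic centerline
# extraction. All operate on plain 3D arrays.

# separable Gaussian smoothing with replicate padding; sigma in voxels
gauss_smooth3d <- function(a, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigma[ax]))
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

conv_axis <- function(a, k, ax) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(a, perm)
  dm <- dim(b)
  n <- dm[1]
  r <- (length(k) - 1L) / 2L
  m <- matrix(b, nrow = n)
  # replicate-pad then filter
  mp <- rbind(m[rep(1, r), , drop = FALSE], m,
              m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
  }
  aperm(array(out, dm), order(perm))
}

# exact squared Euclidean distance transform of a binary array:
# distance (in voxels) from TRUE voxels to the nearest FALSE voxel
edt_squared <- function(mask) {
  INF <- 1e18
  d <- array(ifelse(mask, INF, 0), dim = dim(mask))
  for (ax in 1:3) d <- edt_axis(d, ax)
  d
}

edt_axis <- function(d, ax) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- aperm(d, perm)
  dm <- dim(b)
  m <- matrix(b, nrow = dm[1])
  for (col in seq_len(ncol(m))) m[, col] <- edt_1d(m[, col])
  aperm(array(m, dm), order(perm))
}

# 1D squared distance transform (lower envelope of parabolas)
edt_1d <- function(f) {
  n <- length(f)
  if (all(!is.finite(f)) || n == 1) return(f)
  v <- integer(n); zl <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  zl[1] <- -Inf; zl[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= zl[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    zl[k] <- s
    zl[k + 1] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in 1:n) {
    while (zl[k + 1] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 + f[v[k]]
  }
  out
}

# 26-connected component labelling of a logical array; returns an integer
# array of labels (0 = background)
label_components <- function(mask) {
  sh <- dim(mask)
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  nxy <- nx * ny
  lab <- array(0L, sh)
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  # precompute neighbour offsets with boundary-safe checks done via coords
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      iz <- (frontier - 1L) %/% nxy
      rem <- frontier - 1L - iz * nxy
      iy <- rem %/% nx
      ix <- rem - iy * nx
      nbrs <- integer(0)
      for (r in seq_len(nrow(offs))) {
        jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]; jz <- iz + offs[r, 3]
        ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
        if (!any(ok)) next
        cand <- jx[ok] + jy[ok] * nx + jz[ok] * nxy + 1L
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nbrs <- c(nbrs, cand)
        }
      }
      frontier <- unique(nbrs)
    }
  }
  lab
}

# geodesic centerline of one component: BFS from an arbitrary voxel to find
# one endpoint, BFS again for the farthest point, then backtrack the
# shortest path. Returns voxel-index matrix (rows = path, cols ix,iy,iz).
component_centerline <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 1) {
    return(matrix(index_to_ijk(idx, dim(mask)), 1, 3))
  }
  a <- bfs_farthest(mask, idx[1])
  b <- bfs_farthest(mask, a$far)
  path <- b$path
  t(vapply(path, function(i) index_to_ijk(i, dim(mask)), numeric(3)))
}

index_to_ijk <- function(idx, sh) {
  nxy <- sh[1] * sh[2]
  iz <- (idx - 1L) %/% nxy
  rem <- idx - 1L - iz * nxy
  iy <- rem %/% sh[1]
  ix <- rem - iy * sh[1]
  c(ix + 1, iy + 1, iz + 1)
}

# BFS over the 26-neighbourhood from `start`; returns farthest voxel and
# the path back from it
bfs_farthest <- function(mask, start) {
  sh <- dim(mask)
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]; nxy <- nx * ny
  prev <- array(0L, sh)
  dist <- array(-1L, sh)
  dist[start] <- 0L
  frontier <- start
  last <- start
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(frontier)) {
    nxt <- integer(0)
    iz <- (frontier - 1L) %/% nxy
    rem <- frontier - 1L - iz * nxy
    iy <- rem %/% nx
    ix <- rem - iy * nx
    for (r in seq_len(nrow(offs))) {
      jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]; jz <- iz + offs[r, 3]
      ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
      if (!any(ok)) next
      cand <- jx[ok] + jy[ok] * nx + jz[ok] * nxy + 1L
      src <- frontier[ok]
      new <- mask[cand] & dist[cand] < 0L
      if (any(new)) {
        cand <- cand[new]; src <- src[new]
        first <- !duplicated(cand)
        cand <- cand[first]; src <- src[first]
        dist[cand] <- dist[src] + 1L
        prev[cand] <- src
        nxt <- c(nxt, cand)
      }
    }
    frontier <- nxt
    if (length(frontier)) last <- frontier[which.max(dist[frontier])]
  }
  path <- integer(0)
  cur <- last
  while (cur != 0L) {
    path <- c(path, cur)
    if (cur == start) break
    cur <- prev[cur]
  }
  list(far = last, path = rev(path))
}
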
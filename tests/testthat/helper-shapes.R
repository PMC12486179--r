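# Digitized analytic shapes and slow independent oracles used across the
# suite. The oracles deliberately avoid the package's EDT/labelling code
# paths: labelling is a plain R flood fill, erosion survival is explicit
# offset enumeration, and the Euler characteristic is counted cell by
# cell with loops.

ball_mask <- function(radius_mm, h, pad_vox = 4) {
  nh <- ceiling(radius_mm / h) + pad_vox
  n <- 2L * nh + 1L
  ax <- (seq_len(n) - nh - 1) * h
  binary_mask(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= radius_mm^2, h,
              origin = rep(ax[1], 3))
}

slab_mask <- function(thick_mm, h, lateral = 41, pad_vox = 8) {
  nz <- round(thick_mm / h)
  stopifnot(abs(nz * h - thick_mm) < 1e-9)
  m <- array(FALSE, c(lateral, lateral, nz + 2L * pad_vox))
  m[, , pad_vox + seq_len(nz)] <- TRUE
  binary_mask(m, h)
}

cylinder_mask <- function(diam_mm, h, length_vox = 41, pad_vox = 4) {
  nh <- ceiling(diam_mm / 2 / h) + pad_vox
  n <- 2L * nh + 1L
  ax <- (seq_len(n) - nh - 1) * h
  cr2 <- outer(ax^2, ax^2, `+`)
  m <- array(FALSE, c(n, n, length_vox))
  disc <- cr2 <= (diam_mm / 2)^2
  for (k in seq_len(length_vox)) m[, , k] <- disc
  binary_mask(m, h)
}

torus_mask <- function(R_mm, r_mm, h) {
  nh <- ceiling((R_mm + r_mm) / h) + 3
  n <- 2L * nh + 1L
  ax <- (seq_len(n) - nh - 1) * h
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  binary_mask((sqrt(X^2 + Y^2) - R_mm)^2 + Z^2 <= r_mm^2, h)
}

full_roi <- function(mask) binary_mask(array(TRUE, dim(mask$values)),
                                       mask$spacing, mask$origin)

# plain R flood-fill labelling (queue of linear indices)
bfs_label <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  todo <- which(arr)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- matrix(arrayInd(start, d), ncol = 3)
    lab[start] <- cur
    while (nrow(frontier) > 0) {
      nxt <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(frontier, 2, offs[k, ], `+`)))
      ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] &
            nxt[, 2] >= 1 & nxt[, 2] <= d[2] &
            nxt[, 3] >= 1 & nxt[, 3] <= d[3]
      nxt <- nxt[ok, , drop = FALSE]
      lin <- nxt[, 1] + d[1] * (nxt[, 2] - 1L) + d[1] * d[2] * (nxt[, 3] - 1L)
      keep <- arr[lin] & lab[lin] == 0L
      lin <- unique(lin[keep])
      lab[lin] <- cur
      frontier <- matrix(arrayInd(lin, d), ncol = 3)
    }
  }
  lab
}

# brute-force size filter: keep exactly the components in which some voxel
# carries a fully contained ball of radius min_diameter/2 (offsets
# enumerated directly; array exterior counts as background)
oracle_size_filter <- function(arr, h, min_diameter, connectivity = 26) {
  d <- dim(arr)
  r <- min_diameter / 2 * (1 + 1e-7)
  rv <- floor(r / h)
  og <- as.matrix(expand.grid(dx = -rv:rv, dy = -rv:rv, dz = -rv:rv))
  og <- og[sqrt(rowSums(og^2)) * h <= r, , drop = FALSE]
  lab <- bfs_label(arr, connectivity)
  keep <- integer()
  for (v in which(arr)) {
    if (lab[v] %in% keep) next
    pos <- arrayInd(v, d)
    nb <- sweep(og, 2, as.integer(pos), `+`)
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!all(inside)) next
    lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
    if (all(arr[lin])) keep <- c(keep, lab[v])
  }
  arr & (lab %in% keep)
}

# cell-by-cell cubical-complex Euler characteristic (union of closed unit
# cubes; any-incident-foreground rule), written as explicit loops
oracle_euler <- function(arr) {
  d <- dim(arr)
  p <- array(FALSE, d + 2L)
  p[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- arr
  dp <- dim(p)
  nC <- sum(arr)
  nF <- 0L; nE <- 0L; nV <- 0L
  at <- function(i, j, k) p[i, j, k]
  for (i in seq_len(dp[1] - 1L)) for (j in seq_len(dp[2])) for (k in seq_len(dp[3]))
    if (at(i, j, k) || at(i + 1L, j, k)) nF <- nF + 1L
  for (i in seq_len(dp[1])) for (j in seq_len(dp[2] - 1L)) for (k in seq_len(dp[3]))
    if (at(i, j, k) || at(i, j + 1L, k)) nF <- nF + 1L
  for (i in seq_len(dp[1])) for (j in seq_len(dp[2])) for (k in seq_len(dp[3] - 1L))
    if (at(i, j, k) || at(i, j, k + 1L)) nF <- nF + 1L
  for (i in seq_len(dp[1])) for (j in seq_len(dp[2] - 1L)) for (k in seq_len(dp[3] - 1L))
    if (at(i, j, k) || at(i, j + 1L, k) || at(i, j, k + 1L) || at(i, j + 1L, k + 1L))
      nE <- nE + 1L
  for (i in seq_len(dp[1] - 1L)) for (j in seq_len(dp[2])) for (k in seq_len(dp[3] - 1L))
    if (at(i, j, k) || at(i + 1L, j, k) || at(i, j, k + 1L) || at(i + 1L, j, k + 1L))
      nE <- nE + 1L
  for (i in seq_len(dp[1] - 1L)) for (j in seq_len(dp[2] - 1L)) for (k in seq_len(dp[3]))
    if (at(i, j, k) || at(i + 1L, j, k) || at(i, j + 1L, k) || at(i + 1L, j + 1L, k))
      nE <- nE + 1L
  for (i in seq_len(dp[1] - 1L)) for (j in seq_len(dp[2] - 1L)) for (k in seq_len(dp[3] - 1L)) {
    hit <- FALSE
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      if (p[i + a, j + b, k + cc]) hit <- TRUE
    if (hit) nV <- nV + 1L
  }
  as.integer(nV - nE + nF - nC)
}

# brute-force local thickness (largest containing inscribed sphere), same
# boundary convention as the package: distances between voxel centres,
# exterior is background, half-voxel surface offset subtracted
oracle_thickness <- function(arr, h) {
  d <- dim(arr)
  fg <- which(arr)
  bg <- which(!arr)
  co <- function(idx) arrayInd(idx, d)
  fgc <- co(fg)
  # distance to background, including 1-layer virtual exterior
  R <- vapply(seq_along(fg), function(i) {
    v <- fgc[i, ]
    dmin <- min(v - 0, d - v + 1) * h          # to virtual exterior layer
    if (length(bg)) {
      bgc <- co(bg)
      dmin <- min(dmin, sqrt(min(colSums((t(bgc) - v)^2))) * h)
    }
    dmin
  }, 0)
  th <- numeric(length(fg))
  for (i in seq_along(fg)) {
    dv <- sqrt(colSums((t(fgc) - fgc[i, ])^2)) * h
    th[i] <- 2 * max(R[dv <= R + 1e-12])
  }
  out <- array(0, d)
  out[fg] <- th - h
  out
}

# random blobby void mask for oracle-equivalence testing
random_void_mask <- function(n = 32, h = 0.25, seed = 1) {
  set.seed(seed)
  arr <- array(FALSE, c(n, n, n))
  ax <- seq_len(n) * h
  n_blob <- sample(2:5, 1)
  for (b in seq_len(n_blob)) {
    c0 <- runif(3, 0.25, 0.75) * n * h
    r0 <- runif(1, 0.3, 1.4)
    stretch <- runif(3, 0.6, 1.6)
    D <- outer(outer(((ax - c0[1]) / stretch[1])^2, ((ax - c0[2]) / stretch[2])^2, `+`),
               ((ax - c0[3]) / stretch[3])^2, `+`)
    arr <- arr | (D <= r0^2)
  }
  # sprinkle small voxel clusters that must never survive
  idx <- sample(n^3, 20)
  arr[idx] <- TRUE
  binary_mask(arr, h)
}
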
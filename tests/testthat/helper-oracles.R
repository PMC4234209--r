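# Independent oracles used to validate the package implementations.
# These deliberately use different mechanisms than the package code
# (scatter-based shifts and explicit loops instead of block copies and
# BFS) so agreement is meaningful.

# out[v] <- m[v + d], scatter formulation
oracle_shift <- function(m, d) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  dst <- sweep(idx, 2, as.integer(d), "-")
  keep <- rowSums(dst >= 1) == ncol(dst) &
    rowSums(sweep(dst, 2, dm, "<=")) == ncol(dst)
  if (any(keep)) out[dst[keep, , drop = FALSE]] <- TRUE
  out
}

oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# connected component of `adm` containing `seed`, by iterated dilation
# restricted to the admissible set (fixed-point label propagation)
oracle_component3d <- function(adm, seed, connectivity = 6) {
  reg <- array(FALSE, dim(adm))
  reg[seed[1], seed[2], seed[3]] <- TRUE
  offs <- oracle_offsets(connectivity)
  repeat {
    grown <- reg
    for (t in seq_len(nrow(offs)))
      grown <- grown | oracle_shift(reg, offs[t, ])
    grown <- grown & adm
    if (identical(grown, reg)) return(reg)
    reg <- grown
  }
}

# 8-connected 2D flood fill by explicit queue of pixels
oracle_flood2d <- function(adm, seed) {
  dm <- dim(adm)
  reg <- matrix(FALSE, dm[1], dm[2])
  if (!adm[seed[1], seed[2]]) stop("oracle: seed not admissible")
  queue <- list(seed)
  reg[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      q <- p + c(dr, dc)
      if (any(q < 1) || q[1] > dm[1] || q[2] > dm[2]) next
      if (adm[q[1], q[2]] && !reg[q[1], q[2]]) {
        reg[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  reg
}

# definitional erosion: a voxel survives iff every element offset lands on
# an in-bounds foreground voxel
oracle_erode <- function(m, offsets) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  for (v in which(m)) {
    ijk <- arrayInd(v, dm)
    ok <- TRUE
    for (t in seq_len(nrow(offsets))) {
      p <- ijk + offsets[t, ]
      if (any(p < 1) || any(p > dm) || !m[p[1], p[2], p[3]]) {
        ok <- FALSE
        break
      }
    }
    out[v] <- ok
  }
  out
}

oracle_dilate <- function(m, offsets) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  idx <- which(m, arr.ind = TRUE)
  for (t in seq_len(nrow(offsets))) {
    dst <- sweep(idx, 2, offsets[t, ], "+")
    keep <- rowSums(dst >= 1) == 3 & rowSums(sweep(dst, 2, dm, "<=")) == 3
    if (any(keep)) out[dst[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# piecewise-linear threshold profile evaluated pointwise
oracle_piecewise_linear <- function(xs, ys, xout) {
  vapply(xout, function(x) {
    if (x <= xs[1]) return(ys[1])
    if (x >= xs[length(xs)]) return(ys[length(ys)])
    i <- max(which(xs <= x))
    if (xs[i] == x) return(ys[i])
    t <- (x - xs[i]) / (xs[i + 1] - xs[i])
    ys[i] + t * (ys[i + 1] - ys[i])
  }, 0)
}

# two-way ICC(A,1) from explicit cell-level sums of squares
oracle_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  mu <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - mu)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - mu)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + mu)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# parametric UV-sphere triangle mesh of radius r centred at the origin
uv_sphere <- function(r, n_theta = 40, n_phi = 80, centre = c(0, 0, 0)) {
  verts <- matrix(0, 2 + (n_theta - 1) * n_phi, 3)
  verts[1, ] <- c(0, 0, r)
  row <- 1L
  for (i in seq_len(n_theta - 1)) {
    th <- pi * i / n_theta
    for (j in seq_len(n_phi) - 1L) {
      ph <- 2 * pi * j / n_phi
      row <- row + 1L
      verts[row, ] <- r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    }
  }
  verts[row + 1L, ] <- c(0, 0, -r)
  bottom <- row + 1L
  ring <- function(i) 1L + (i - 1L) * n_phi + seq_len(n_phi)
  faces <- list()
  r1 <- ring(1)
  for (j in seq_len(n_phi))
    faces[[length(faces) + 1]] <- c(1L, r1[j], r1[j %% n_phi + 1L])
  for (i in seq_len(n_theta - 2)) {
    a <- ring(i); b <- ring(i + 1)
    for (j in seq_len(n_phi)) {
      jn <- j %% n_phi + 1L
      faces[[length(faces) + 1]] <- c(a[j], b[j], b[jn])
      faces[[length(faces) + 1]] <- c(a[j], b[jn], a[jn])
    }
  }
  rl <- ring(n_theta - 1)
  for (j in seq_len(n_phi))
    faces[[length(faces) + 1]] <- c(bottom, rl[j %% n_phi + 1L], rl[j])
  surface_mesh(sweep(verts, 2, centre, "+"), do.call(rbind, faces))
}

# random blobby logical array: thresholded smoothed uniform noise
random_mask <- function(dims, fill = 0.5) {
  arr <- array(runif(prod(dims)), dims)
  k <- array(0, dims)
  for (d in list(c(0,0,0), c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                 c(0,0,1), c(0,0,-1)))
    k <- k + condyseg:::shift3(arr, d, fill = 0.5)
  k / 7 > quantile(k / 7, 1 - fill)
}

# digital ellipsoid mask (voxel centres inside the ellipsoid)
ellipsoid_mask <- function(dims, centre_vox, semi_vox,
                           spacing = c(0.4, 0.4, 0.4)) {
  idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
  inside <- ((idx$i - centre_vox[1]) / semi_vox[1])^2 +
    ((idx$j - centre_vox[2]) / semi_vox[2])^2 +
    ((idx$k - centre_vox[3]) / semi_vox[3])^2 <= 1
  binary_mask(array(inside, dims), spacing)
}

# closed-form head-plus-neck solid volume for equal in-plane semi-axes
# (cylinder of radius r from the head centre down to -L along the axial
# axis, unioned with the ellipsoid (a, b, b))
phantom_solid_volume <- function(a, b, r, L) {
  stopifnot(r < b, L > a)
  x1 <- a * sqrt(1 - r^2 / b^2)
  ell <- 4 / 3 * pi * a * b * b
  # cylinder outside the ellipsoid: full disc below x = -a, plus the
  # annulus between disc and ellipse cross-section on [-a, -x1]
  seg <- integrate(function(x) pi * r^2 - pi * b^2 * (1 - x^2 / a^2),
                   -a, -x1)$value
  ell + pi * r^2 * (L - a) + seg
}

# random grow_3d test case: random intensities, random annotation axis,
# 1-3 random slice thresholds, seed voxel forced admissible
random_grow3d_case <- function(maxdim = 20) {
  dm <- sample(4:maxdim, 3, replace = TRUE)
  img <- array(sample(0:255, prod(dm), replace = TRUE), dm)
  ax <- sample(1:3, 1)
  ns <- sample(1:3, 1)
  slices <- sort(sample(seq_len(dm[ax]), ns))
  thr <- runif(ns, 60, 200)
  inplane <- setdiff(1:3, ax)
  seed_rc <- c(sample(seq_len(dm[inplane[1]]), 1),
               sample(seq_len(dm[inplane[2]]), 1))
  anns <- Map(function(s, t) slice_annotation(s, seed_rc, t), slices, thr)
  a <- annotation_set(ax, anns, voi(c(1, 1, 1), dm))
  seed <- seed_voxel(a)
  img[seed[1], seed[2], seed[3]] <- 255  # guarantee admissibility
  conn <- sample(c(6L, 26L), 1)
  list(volume = image_volume(img), ann = a, seed = seed, conn = conn,
       axis = ax, slices = slices, thr = thr, dm = dm)
}
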
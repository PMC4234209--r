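#' Triangle surface mesh
#'
#' Vertices in mm coordinates and 1-based vertex index triples.  Faces are
#' oriented with outward normals when produced by [extract_surface()].
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), nrow = nrow(as.matrix(faces)))
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(vertices) < 4L) stop("mesh needs at least 4 vertices", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.2f mm^2, enclosed volume %.2f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x), mesh_volume(x)))
  invisible(x)
}

#' Mask volume in cubic millimetres
#'
#' Foreground voxel count times the voxel volume — the condylar volume
#' measure used for the rater-agreement statistics.
#'
#' @param mask a [binary_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$spacing)
}

# cross products of triangle edges, n x 3
tri_cross <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  cr <- tri_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Volume enclosed by a closed mesh (mm^3)
#'
#' Signed divergence-theorem sum over triangles; the absolute value is
#' returned so vertex winding does not matter for closed surfaces.
#' @param mesh a [surface_mesh()].
#' @return Enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  cr <- tri_cross(mesh)
  abs(sum(rowSums(a * cr)) / 6)
}

# exposed-face quads of a binary array; corner ids are 0-based corner
# lattice indices flattened with strides (n0+1, n1+1, n2+1)
cuberille_quads <- function(m) {
  dm <- dim(m)
  s <- c(1, dm[1] + 1, (dm[1] + 1) * (dm[2] + 1))
  corner_id <- function(ci, cj, ck) ci * s[1] + cj * s[2] + ck * s[3]
  quads <- vector("list", 6)
  qi <- 0L
  # For a face with outward normal +axis, quad corners are ordered
  # p, p+u, p+u+v, p+v with u x v = +axis (right-handed); -axis reversed.
  face_defs <- list(
    list(d = c(1L, 0L, 0L),  plane = 1L),
    list(d = c(-1L, 0L, 0L), plane = 1L),
    list(d = c(0L, 1L, 0L),  plane = 2L),
    list(d = c(0L, -1L, 0L), plane = 2L),
    list(d = c(0L, 0L, 1L),  plane = 3L),
    list(d = c(0L, 0L, -1L), plane = 3L))
  uv <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))  # u,v axes giving +normal
  for (fd in face_defs) {
    d <- fd$d
    expo <- m & !shift3(m, d)
    idx <- which(expo, arr.ind = TRUE)
    if (!nrow(idx)) next
    ax <- fd$plane
    pos <- d[ax] > 0L
    # base corner (0-based): on `ax` the plane is i (pos) or i-1 (neg);
    # on the other two axes the lower corner is index-1
    base <- idx - 1L
    if (pos) base[, ax] <- base[, ax] + 1L
    u <- uv[[ax]][1]; v <- uv[[ax]][2]
    eu <- ev <- c(0L, 0L, 0L)
    eu[u] <- 1L; ev[v] <- 1L
    p1 <- base
    p2 <- sweep(base, 2, eu, "+")
    p3 <- sweep(base, 2, eu + ev, "+")
    p4 <- sweep(base, 2, ev, "+")
    q <- cbind(corner_id(p1[, 1], p1[, 2], p1[, 3]),
               corner_id(p2[, 1], p2[, 2], p2[, 3]),
               corner_id(p3[, 1], p3[, 2], p3[, 3]),
               corner_id(p4[, 1], p4[, 2], p4[, 3]))
    if (!pos) q <- q[, c(1, 4, 3, 2), drop = FALSE]
    qi <- qi + 1L
    quads[[qi]] <- q
  }
  do.call(rbind, quads[seq_len(qi)])
}

#' Extract the surface mesh of a binary mask
#'
#' The iso-surface of the 0/1 voxel grid is extracted as the exact voxel
#' boundary: every voxel face separating foreground from background becomes
#' two triangles with outward orientation, with vertices on the voxel
#' corner lattice (`origin + corner_index * spacing`).  The unsmoothed mesh
#' is watertight and encloses exactly [mask_volume_mm3()].  Optional
#' Taubin low-shrinkage smoothing (lambda = 0.5, mu = -0.53 per iteration)
#' relaxes the staircase while approximately preserving volume; all meshes
#' that are compared with each other should use the same setting.
#'
#' @param mask a non-empty [binary_mask()].
#' @param smooth_iterations number of Taubin iterations (default 10; 0
#'   returns the raw voxel boundary).
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mask, smooth_iterations = 10L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("cannot extract a surface from an empty mask",
                            call. = FALSE)
  q <- cuberille_quads(mask$data)
  ids <- sort(unique(as.vector(q)))
  lookup <- match(as.vector(q), ids)
  qm <- matrix(lookup, nrow(q), 4)
  dm <- dim(mask$data)
  n0 <- dm[1] + 1; n1 <- dm[2] + 1
  ck <- ids %/% (n0 * n1)
  rem <- ids %% (n0 * n1)
  cj <- rem %/% n0
  ci <- rem %% n0
  verts <- cbind(mask$origin[1] + ci * mask$spacing[1],
                 mask$origin[2] + cj * mask$spacing[2],
                 mask$origin[3] + ck * mask$spacing[3])
  faces <- rbind(qm[, c(1, 2, 3), drop = FALSE],
                 qm[, c(1, 3, 4), drop = FALSE])
  mesh <- surface_mesh(verts, faces)
  if (smooth_iterations > 0L)
    mesh <- taubin_smooth(mesh, smooth_iterations)
  mesh
}

#' Taubin low-shrinkage mesh smoothing
#'
#' Alternates an inward Laplacian step (`lambda`) with an outward one
#' (`mu`, negative, slightly larger in magnitude), which smooths the
#' surface without the systematic shrinkage of plain Laplacian smoothing.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of lambda/mu pairs.
#' @param lambda,mu Taubin parameters; defaults 0.5 / -0.53.
#' @return The smoothed [surface_mesh()].
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  nv <- nrow(mesh$vertices)
  deg <- tabulate(edges[, 1], nbins = nv)
  W <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2],
                            x = 1 / deg[edges[, 1]], dims = c(nv, nv))
  p <- mesh$vertices
  for (it in seq_len(iterations)) {
    p <- p + lambda * (as.matrix(W %*% p) - p)
    p <- p + mu * (as.matrix(W %*% p) - p)
  }
  surface_mesh(p, mesh$faces)
}

#' Sample points on a mesh surface
#'
#' Returns all vertices plus, for each triangle, `ceiling(area * density)`
#' deterministic low-discrepancy barycentric samples, so the sample set is
#' reproducible without a random stream.
#'
#' @param mesh a [surface_mesh()].
#' @param samples_per_mm2 additional face-sample density (0 = vertices
#'   only).
#' @return Numeric matrix of sample points (rows), mm.
#' @export
sample_mesh_points <- function(mesh, samples_per_mm2 = 4) {
  pts <- mesh$vertices
  if (samples_per_mm2 > 0) {
    cr <- tri_cross(mesh)
    areas <- sqrt(rowSums(cr^2)) / 2
    nf <- ceiling(areas * samples_per_mm2 - 1e-9)
    nf[areas <= 0] <- 0L
    tot <- sum(nf)
    if (tot > 0) {
      fidx <- rep(seq_along(nf), nf)
      sid <- sequence(nf)
      nrep <- nf[fidx]
      u <- (sid - 0.5) / nrep
      v <- (sid * 0.61803398874989) %% 1
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]
      v[flip] <- 1 - v[flip]
      a <- mesh$vertices[mesh$faces[fidx, 1], , drop = FALSE]
      b <- mesh$vertices[mesh$faces[fidx, 2], , drop = FALSE]
      c_ <- mesh$vertices[mesh$faces[fidx, 3], , drop = FALSE]
      pts <- rbind(pts, a + u * (b - a) + v * (c_ - a))
    }
  }
  pts
}

#' Write a mesh as binary little-endian PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.ply` file.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "wb"); on.exit(close(con))
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("element vertex %d", nrow(mesh$vertices)),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "little")
  f0 <- t(mesh$faces) - 1L
  for (i in seq_len(ncol(f0))) {
    writeBin(as.raw(3L), con)
    writeBin(f0[, i], con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a PLY mesh (binary little-endian or ascii)
#'
#' Supports the x/y/z + triangular-face subset written by
#' [write_mesh_ply()].
#'
#' @param path `.ply` file.
#' @return A [surface_mesh()].
#' @export
read_mesh_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated PLY header", call. = FALSE)
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)))
  if (binary) {
    verts <- matrix(readBin(con, "double", nv * 3L, size = 4L,
                            endian = "little"), nv, 3, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1L))
      if (cnt != 3L) stop("only triangular PLY faces are supported",
                          call. = FALSE)
      faces[i, ] <- readBin(con, "integer", 3L, size = 4L,
                            endian = "little") + 1L
    }
  } else {
    txt <- readLines(con)
    vl <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    verts <- do.call(rbind, lapply(vl, function(x) as.numeric(x[1:3])))
    fl <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(x) as.integer(x[2:4]) + 1L))
  }
  surface_mesh(verts, faces)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output `.stl` file.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  cr <- tri_cross(mesh)
  nrm <- cr / pmax(sqrt(rowSums(cr^2)), 1e-30)
  con <- file(path, "w"); on.exit(close(con))
  cat("solid mask\n", file = con)
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    cat(sprintf("facet normal %g %g %g\n outer loop\n", nrm[i, 1],
                nrm[i, 2], nrm[i, 3]), file = con)
    for (j in 1:3)
      cat(sprintf("  vertex %g %g %g\n", v[f[i, j], 1], v[f[i, j], 2],
                  v[f[i, j], 3]), file = con)
    cat(" endloop\nendfacet\n", file = con)
  }
  cat("endsolid mask\n", file = con)
  invisible(path)
}
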
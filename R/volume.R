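#' @useDynLib condyseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx quantile median rnorm runif dnorm
#' @importFrom utils modifyList
NULL

AXES <- c(axial = 1L, coronal = 2L, sagittal = 3L)

axis_index <- function(axis) {
  if (is.numeric(axis)) {
    ax <- as.integer(axis)
    if (!ax %in% 1:3) stop("axis must be 1, 2 or 3", call. = FALSE)
    return(ax)
  }
  ax <- AXES[match.arg(as.character(axis), names(AXES))]
  unname(ax)
}

#' Image volume container
#'
#' A 3D scalar intensity grid together with its voxel spacing (mm), the mm
#' position of the first voxel and the anatomical role of each array axis.
#' Voxel `(i,j,k)` (1-based) occupies the mm box
#' `origin + ((i,j,k) - 1) * spacing` to `origin + (i,j,k) * spacing`.
#' Axis roles follow the package convention: axis 1 indexes axial slices,
#' axis 2 coronal, axis 3 sagittal; volumes stored differently can be
#' re-mapped with [aperm()] at load time.
#'
#' @param data 3D numeric array of intensities (arbitrary units; CBCT grey
#'   values are used as read, without Hounsfield calibration).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#'   CBCT condyle protocols typically use 0.4 mm isotropic voxels.
#' @param origin numeric length-3, mm offset of the corner of voxel (1,1,1).
#' @param axis_roles character length-3 naming the role of each axis.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(0.4, 0.4, 0.4),
                         origin = c(0, 0, 0),
                         axis_roles = c("axial", "coronal", "sagittal")) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 axis_roles = axis_roles),
            class = "image_volume")
}

#' Binary segmentation mask
#'
#' A 3D logical grid aligned with an [image_volume()]: same shape, spacing
#' and origin as the volume (or VOI) it annotates.
#'
#' @param data 3D logical array (coerced with `> 0` if numeric).
#' @inheritParams image_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  if (!is.logical(data)) {
    storage.mode(data) <- "double"
    data <- data > 0
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.1f mm^3)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              sum(x$data) * prod(x$spacing)))
  invisible(x)
}

#' Volume of interest
#'
#' An axis-aligned (in array coordinates) box of voxels, given by 1-based
#' inclusive corner indices, used to restrict the region-growing search.
#'
#' @param lo,hi integer length-3, inclusive first and last voxel indices per
#'   axis; `1 <= lo <= hi <= shape`.
#' @return An object of class `voi`.
#' @export
voi <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L)
    stop("lo and hi must have length 3", call. = FALSE)
  if (any(lo < 1L)) stop("VOI lo must be >= 1", call. = FALSE)
  if (any(hi < lo)) stop("VOI hi must be >= lo on every axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "voi")
}

#' Full-extent VOI of a volume or mask
#' @param x an `image_volume` or `binary_mask`.
#' @return A [voi()] spanning the whole grid.
#' @export
full_voi <- function(x) voi(c(1L, 1L, 1L), dim(x$data))

check_voi_bounds <- function(v, shape) {
  bad <- which(v$hi > shape)
  if (length(bad))
    stop(sprintf("VOI exceeds volume bounds on axis %s (hi %s > shape %s)",
                 paste(bad, collapse = ","),
                 paste(v$hi[bad], collapse = ","),
                 paste(shape[bad], collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

#' Crop a volume or mask to a VOI
#'
#' Returns an exact sub-grid copy; the origin is shifted by
#' `(lo - 1) * spacing` so mm coordinates of retained voxels are unchanged.
#'
#' @param x an `image_volume` or `binary_mask`.
#' @param v a [voi()] within bounds.
#' @return Object of the same class as `x`, with shape `hi - lo + 1`.
#' @export
crop_voi <- function(x, v) {
  stopifnot(inherits(v, "voi"))
  check_voi_bounds(v, dim(x$data))
  sub <- x$data[v$lo[1]:v$hi[1], v$lo[2]:v$hi[2], v$lo[3]:v$hi[3],
                drop = FALSE]
  origin <- x$origin + (v$lo - 1) * x$spacing
  if (inherits(x, "image_volume"))
    image_volume(sub, x$spacing, origin, x$axis_roles)
  else binary_mask(sub, x$spacing, origin)
}

# shift a 3D array by integer offset d, filling with `fill`;
# out[v] = m[v + d] where defined
shift3 <- function(m, d, fill = FALSE) {
  dm <- dim(m)
  out <- array(fill, dm)
  src_lo <- pmax(1L, 1L + d)
  src_hi <- pmin(dm, dm + d)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - d
  dst_hi <- src_hi - d
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    m[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

# evaluate an expression with a private RNG stream seeded by `seed`,
# restoring the caller's RNG state afterwards
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
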
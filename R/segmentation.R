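#' Per-slice observer annotation
#'
#' One observer input on one slice: a seed voxel inside the structure and
#' the intensity threshold that best outlines it on that slice.  In the
#' interactive protocol the observer places such a seed roughly once every
#' five slices and tunes the threshold until the rendered outline fits the
#' cortical boundary.
#'
#' @param slice 1-based slice index along the annotation axis.
#' @param seed integer length-2, in-plane voxel indices `(r, c)` on the
#'   remaining two axes, in increasing axis order.
#' @param threshold inclusive lower intensity bound for region membership on
#'   this slice (image intensity units).
#' @return An object of class `slice_annotation`.
#' @export
slice_annotation <- function(slice, seed, threshold) {
  slice <- as.integer(slice)
  seed <- as.integer(seed)
  threshold <- as.numeric(threshold)
  if (length(slice) != 1L || is.na(slice) || slice < 1L)
    stop("slice must be a positive integer", call. = FALSE)
  if (length(seed) != 2L || any(is.na(seed)) || any(seed < 1L))
    stop("seed must be two positive in-plane indices", call. = FALSE)
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a finite number", call. = FALSE)
  structure(list(slice = slice, seed = seed, threshold = threshold),
            class = "slice_annotation")
}

#' Ordered annotation set for one region-growing run
#'
#' All observer inputs along one anatomical axis, plus the VOI that bounds
#' the search and the index of the central annotation whose seed initiates
#' the 3D growth.
#'
#' @param axis `"axial"`, `"coronal"` or `"sagittal"` (or 1/2/3).
#' @param annotations list of [slice_annotation()] with strictly increasing
#'   slice indices, all inside `voi`.
#' @param voi a [voi()] bounding the run.
#' @param central_index index into `annotations` of the seed that starts the
#'   3D growth.  Default: the annotation whose slice is closest to the
#'   median annotated slice (ties resolved to the lower slice).
#' @param connectivity 3D neighbourhood, 6 (default) or 26.  Face
#'   connectivity prevents diagonal leakage through the thin condyle-fossa
#'   gap.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(axis, annotations, voi,
                           central_index = NULL, connectivity = 6L) {
  ax <- axis_index(axis)
  if (!length(annotations)) stop("need at least one annotation", call. = FALSE)
  if (!all(vapply(annotations, inherits, TRUE, "slice_annotation")))
    stop("annotations must be slice_annotation objects", call. = FALSE)
  slices <- vapply(annotations, `[[`, 1L, "slice")
  if (any(diff(slices) <= 0))
    stop("annotation slice indices must be strictly increasing",
         call. = FALSE)
  if (!inherits(voi, "voi")) stop("voi must be a voi object", call. = FALSE)
  if (any(slices < voi$lo[ax]) || any(slices > voi$hi[ax]))
    stop("annotated slices must lie inside the VOI", call. = FALSE)
  inplane <- setdiff(1:3, ax)
  for (a in annotations) {
    if (any(a$seed < voi$lo[inplane]) || any(a$seed > voi$hi[inplane]))
      stop(sprintf("seed (%s) on slice %d lies outside the VOI",
                   paste(a$seed, collapse = ","), a$slice), call. = FALSE)
  }
  if (!is.na(connectivity) && !connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (is.null(central_index)) {
    med <- median(slices)
    central_index <- which.min(abs(slices - med))  # ties: lower index/slice
  }
  central_index <- as.integer(central_index)
  if (central_index < 1L || central_index > length(annotations))
    stop("central_index out of range", call. = FALSE)
  structure(list(axis = ax, annotations = annotations, voi = voi,
                 central_index = central_index,
                 connectivity = as.integer(connectivity)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  slices <- vapply(x$annotations, `[[`, 1L, "slice")
  cat(sprintf(
    "<annotation_set> %d annotations on %s slices %s, central slice %d\n",
    length(slices), names(AXES)[x$axis],
    paste(range(slices), collapse = "-"),
    slices[x$central_index]))
  invisible(x)
}

#' Full-volume voxel coordinates of an annotation's seed
#'
#' @param annotations an [annotation_set()].
#' @param index which annotation; default the central one.
#' @return Integer length-3 voxel index `(i, j, k)`.
#' @export
seed_voxel <- function(annotations, index = annotations$central_index) {
  a <- annotations$annotations[[index]]
  v <- integer(3)
  v[annotations$axis] <- a$slice
  v[setdiff(1:3, annotations$axis)] <- a$seed
  v
}

#' 2D seeded region growing
#'
#' Returns the 8-connected in-plane component of
#' `{pixels with intensity >= threshold}` containing the seed.  This is the
#' interactive outline step: re-invoking with an adjusted threshold
#' reproduces the interactive tuning loop as a pure function.
#'
#' @param slice_image 2D numeric matrix of intensities.
#' @param seed integer length-2 `(r, c)` pixel index.
#' @param threshold inclusive lower intensity bound; the seed pixel must
#'   pass it (an observer cannot seed a region it does not belong to).
#' @return Logical matrix, the grown region.
#' @export
grow_2d <- function(slice_image, seed, threshold) {
  slice_image <- as.matrix(slice_image)
  seed <- as.integer(seed)
  if (length(seed) != 2L || any(seed < 1L) || any(seed > dim(slice_image)))
    stop("seed out of slice bounds", call. = FALSE)
  if (slice_image[seed[1], seed[2]] < threshold)
    stop(sprintf(
      "seed intensity %g is below threshold %g: invalid seed/threshold pair",
      slice_image[seed[1], seed[2]], threshold), call. = FALSE)
  adm <- slice_image >= threshold
  dims <- c(dim(slice_image), 1L)
  comp <- cpp_seed_component(as.logical(adm), dims, c(seed, 1L), 26L)
  matrix(comp, nrow(slice_image), ncol(slice_image))
}

#' Trace the boundary of a 2D region
#'
#' Returns the pixels of `mask2d` that touch background (or the grid edge)
#' through a 4-neighbour, ordered by greedy boundary following from the
#' first boundary pixel in row-major order.  The unordered set equals
#' `mask & !erode4(mask)`.
#'
#' @param mask2d logical matrix with at least one `TRUE` pixel.
#' @return Integer matrix with columns `r`, `c`, one row per boundary pixel.
#' @export
trace_outline <- function(mask2d) {
  mask2d <- as.matrix(mask2d)
  if (!any(mask2d)) stop("mask is empty", call. = FALSE)
  nr <- nrow(mask2d); nc <- ncol(mask2d)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask2d
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- which(mask2d & !inner, arr.ind = TRUE)
  colnames(boundary) <- c("r", "c")
  n <- nrow(boundary)
  if (n <= 2L) return(boundary)
  # greedy nearest-neighbour walk; falls back to the nearest remaining
  # pixel when a loop closes (handles holes / multiple boundary loops)
  remaining <- rep(TRUE, n)
  ord <- integer(n)
  cur <- 1L
  for (t in seq_len(n)) {
    ord[t] <- cur
    remaining[cur] <- FALSE
    if (t == n) break
    d <- pmax(abs(boundary[, 1] - boundary[cur, 1]),
              abs(boundary[, 2] - boundary[cur, 2]))
    d[!remaining] <- Inf
    cur <- which.min(d)
  }
  boundary[ord, , drop = FALSE]
}

#' Interpolate per-slice thresholds over a VOI
#'
#' Annotated slices keep their annotated threshold exactly; slices between
#' two annotations get the linear interpolation in slice index; slices
#' outside the annotated range (but inside the VOI) get the nearest
#' endpoint's threshold.  This is the local-threshold profile that makes
#' the 3D growth robust to the intensity drift typical of CBCT.
#'
#' @param annotations an [annotation_set()].
#' @return A data frame of class `threshold_profile` with columns `slice`
#'   and `threshold`, one row per VOI slice along the annotation axis.
#' @export
interpolate_thresholds <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  ax <- annotations$axis
  slices <- annotations$voi$lo[ax]:annotations$voi$hi[ax]
  x <- vapply(annotations$annotations, `[[`, 1L, "slice")
  y <- vapply(annotations$annotations, `[[`, 1, "threshold")
  thr <- if (length(x) == 1L) rep(y, length(slices))
    else approx(x, y, xout = slices, method = "linear", rule = 2)$y
  structure(data.frame(slice = slices, threshold = thr),
            class = c("threshold_profile", "data.frame"),
            axis = ax)
}

#' 3D seeded region growing with locally varying thresholds
#'
#' Builds the interpolated threshold profile from the annotations, forms
#' the admissible set (voxels inside the VOI whose intensity reaches their
#' slice's local threshold) and returns its connected component containing
#' the central seed, embedded in a full-shape mask (`FALSE` outside the
#' VOI).
#'
#' @param volume an [image_volume()].
#' @param annotations an [annotation_set()]; its VOI must fit the volume.
#' @param connectivity 6 or 26; defaults to the annotation set's value.
#' @return A [binary_mask()] the shape of `volume`, with attribute
#'   `"profile"` carrying the threshold profile used.
#' @export
grow_3d <- function(volume, annotations,
                    connectivity = annotations$connectivity) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(annotations, "annotation_set"))
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  v <- annotations$voi
  check_voi_bounds(v, dim(volume$data))
  ax <- annotations$axis
  prof <- interpolate_thresholds(annotations)
  sub <- volume$data[v$lo[1]:v$hi[1], v$lo[2]:v$hi[2], v$lo[3]:v$hi[3],
                     drop = FALSE]
  # local slice index (within VOI) of every voxel along the annotation axis
  thr <- prof$threshold[slice.index(sub, ax)]
  adm <- sub >= thr
  seed_full <- seed_voxel(annotations)
  seed_loc <- seed_full - v$lo + 1L
  sidx <- matrix(seed_loc, 1L)
  if (!adm[sidx])
    stop(sprintf(
      "central seed (%s) intensity %g is below its local threshold %g",
      paste(seed_full, collapse = ","), sub[sidx],
      prof$threshold[seed_full[ax] - v$lo[ax] + 1L]), call. = FALSE)
  comp <- cpp_seed_component(as.logical(adm), dim(sub), seed_loc,
                             as.integer(connectivity))
  full <- array(FALSE, dim(volume$data))
  full[v$lo[1]:v$hi[1], v$lo[2]:v$hi[2], v$lo[3]:v$hi[3]] <-
    array(comp, dim(sub))
  out <- binary_mask(full, volume$spacing, volume$origin)
  attr(out, "profile") <- prof
  out
}
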
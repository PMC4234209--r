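#' Slice-level correction of a segmentation
#'
#' Describes one post-processing edit: a replacement or additive 2D label
#' for a single slice along any anatomical axis, typically produced by
#' re-running [grow_2d()] with a corrected seed/threshold on that slice.
#'
#' @param axis `"axial"`, `"coronal"` or `"sagittal"` (or 1/2/3).
#' @param slice_index 1-based slice index along `axis`.
#' @param new_label logical matrix with the volume's in-plane shape for
#'   that axis.
#' @param mode `"add"` (OR with the existing slice label) or `"replace"`.
#' @return An object of class `slice_correction`.
#' @export
slice_correction <- function(axis, slice_index, new_label,
                             mode = c("add", "replace")) {
  mode <- match.arg(mode)
  new_label <- as.matrix(new_label)
  if (!is.logical(new_label)) new_label <- new_label > 0
  structure(list(axis = axis_index(axis),
                 slice_index = as.integer(slice_index),
                 new_label = new_label, mode = mode),
            class = "slice_correction")
}

slice_of <- function(arr, ax, s) {
  switch(ax, arr[s, , ], arr[, s, ], arr[, , s])
}

`slice_of<-` <- function(arr, ax, s, value) {
  switch(ax,
         arr[s, , ] <- value,
         arr[, s, ] <- value,
         arr[, , s] <- value)
  arr
}

#' Apply a slice correction to a mask
#'
#' `mode = "add"` ORs the new label into the slice; `mode = "replace"`
#' substitutes it.  Every other slice is returned bit-identical.
#'
#' @param mask a [binary_mask()].
#' @param correction a [slice_correction()].
#' @return The corrected [binary_mask()].
#' @export
apply_correction <- function(mask, correction) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(correction, "slice_correction"))
  ax <- correction$axis
  s <- correction$slice_index
  dm <- dim(mask$data)
  if (s < 1L || s > dm[ax])
    stop(sprintf("slice %d out of bounds on axis %d (1..%d)", s, ax, dm[ax]),
         call. = FALSE)
  inplane <- dm[setdiff(1:3, ax)]
  if (!identical(dim(correction$new_label), as.integer(inplane)))
    stop(sprintf("correction label is %s but the in-plane shape is %s",
                 paste(dim(correction$new_label), collapse = "x"),
                 paste(inplane, collapse = "x")), call. = FALSE)
  old <- slice_of(mask$data, ax, s)
  newsl <- if (correction$mode == "add") old | correction$new_label
    else correction$new_label
  out <- mask$data
  slice_of(out, ax, s) <- newsl
  binary_mask(out, mask$spacing, mask$origin)
}

#' Structuring element for binary morphology
#'
#' @param shape `"cube"` (full box), `"cross"` (axis-aligned arms), or
#'   `"ball"` (Euclidean ball of diameter `size`).
#' @param size odd edge length / diameter in voxels.  Size three is the
#'   element used to sever the small condyle-fossa connections while
#'   keeping the number of lost surface voxels negligible.
#' @return An object of class `structuring_element` holding the integer
#'   offsets of the element (centred, symmetric).
#' @export
structuring_element <- function(shape = c("cube", "cross", "ball"),
                                size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("size must be an odd integer >= 1", call. = FALSE)
  r <- (size - 1L) %/% 2L
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  keep <- switch(shape,
    cube = rep(TRUE, nrow(g)),
    cross = (abs(g$di) > 0) + (abs(g$dj) > 0) + (abs(g$dk) > 0) <= 1,
    ball = g$di^2 + g$dj^2 + g$dk^2 <= r^2 + 1e-9)
  offsets <- as.matrix(g[keep, , drop = FALSE])
  structure(list(shape = shape, size = size, offsets = offsets),
            class = "structuring_element")
}

morph_apply <- function(data, element, op) {
  offs <- element$offsets
  acc <- NULL
  for (t in seq_len(nrow(offs))) {
    sh <- shift3(data, offs[t, ], fill = FALSE)
    acc <- if (is.null(acc)) sh else if (op == "erode") acc & sh else acc | sh
  }
  acc
}

#' Binary erosion
#'
#' Voxels outside the grid count as background, so the mask shrinks at the
#' volume border (conservative for structures near the VOI edge).
#'
#' @param mask a [binary_mask()].
#' @param element a [structuring_element()].
#' @return The eroded [binary_mask()].
#' @export
erode_mask <- function(mask, element = structuring_element("cube", 3L)) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(element, "structuring_element"))
  binary_mask(morph_apply(mask$data, element, "erode"),
              mask$spacing, mask$origin)
}

#' Binary dilation
#'
#' @inheritParams erode_mask
#' @return The dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, element = structuring_element("cube", 3L)) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(element, "structuring_element"))
  binary_mask(morph_apply(mask$data, element, "dilate"),
              mask$spacing, mask$origin)
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element.  Opening removes
#' structures thinner than the element — in this protocol, the spurious
#' bright bridges between the condylar head and the glenoid fossa — while
#' leaving compact shapes essentially unchanged.  Opening is
#' anti-extensive (output is a subset of the input), monotone in the mask
#' and idempotent.
#'
#' @inheritParams erode_mask
#' @return The opened [binary_mask()].
#' @export
morphological_open <- function(mask,
                               element = structuring_element("cube", 3L)) {
  dilate_mask(erode_mask(mask, element), element)
}

#' Keep the connected component containing a seed
#'
#' After opening separates the condyle from fossa remnants, only the
#' component holding the (central) seed is retained.
#'
#' @param mask a [binary_mask()].
#' @param seed integer length-3 voxel index; must be foreground.
#' @param connectivity 6 (default) or 26.
#' @return A [binary_mask()] containing only the seed's component.
#' @export
keep_seed_component <- function(mask, seed, connectivity = 6L) {
  stopifnot(inherits(mask, "binary_mask"))
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dim(mask$data)))
    stop("seed out of bounds", call. = FALSE)
  if (!mask$data[seed[1], seed[2], seed[3]])
    stop(sprintf("seed voxel (%s) is not foreground",
                 paste(seed, collapse = ",")), call. = FALSE)
  comp <- cpp_seed_component(as.logical(mask$data), dim(mask$data), seed,
                             as.integer(connectivity))
  binary_mask(array(comp, dim(mask$data)), mask$spacing, mask$origin)
}

#' Read slice corrections from JSON
#'
#' The file is a JSON list of corrections
#' `{axis, slice, mode, shape: [nr, nc], runs: [[start, length], ...]}`
#' where `runs` run-length-encodes the `TRUE` pixels of the in-plane label
#' in column-major order (1-based start offsets).
#'
#' @param path JSON file.
#' @return List of [slice_correction()] objects.
#' @export
read_corrections <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(lst, function(x) {
    unknown <- setdiff(names(x), c("axis", "slice", "mode", "shape", "runs"))
    if (length(unknown))
      stop(sprintf("unknown correction keys: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    shape <- as.integer(unlist(x$shape))
    lab <- logical(prod(shape))
    for (run in x$runs) {
      st <- as.integer(run[[1]]); len <- as.integer(run[[2]])
      lab[st:(st + len - 1L)] <- TRUE
    }
    slice_correction(x$axis, x$slice, matrix(lab, shape[1], shape[2]),
                     x$mode)
  })
}

#' Write slice corrections to JSON
#'
#' @param corrections list of [slice_correction()] objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_corrections <- function(corrections, path) {
  enc <- lapply(corrections, function(x) {
    v <- as.vector(x$new_label)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- Map(function(s, l) c(s, l), starts[r$values], r$lengths[r$values])
    list(axis = names(AXES)[x$axis], slice = x$slice_index, mode = x$mode,
         shape = dim(x$new_label), runs = runs)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
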
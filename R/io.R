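#' Read a 3D image volume
#'
#' Reads DICOM series, NIfTI, or raw binary volumes into an
#' [image_volume()].  Intensities are preserved as stored (after the
#' format's slope/intercept scaling where the format defines one); no
#' Hounsfield-unit calibration is attempted, since absolute HU values are
#' unreliable in CBCT.
#'
#' The raw format is one value per voxel in C order (last array index
#' varying fastest), little-endian, described by a mandatory JSON sidecar
#' `<path>.json` with fields `shape`, `dtype`, `spacing`, `origin`,
#' `order`, `byte_order`.  [write_mask_raw()] produces exactly this layout.
#'
#' @param path file (NIfTI, raw) or directory (DICOM series).
#' @param format one of `"auto"`, `"raw"`, `"nifti"`, `"dicom_series"`.
#'   `"auto"` picks by extension (`.nii`/`.nii.gz` for NIfTI, directory for
#'   DICOM, anything else raw).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "raw", "nifti",
                                         "dicom_series")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read volume: '%s' does not exist", path),
         call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else "raw"
  }
  switch(format,
    raw = read_volume_raw(path),
    nifti = read_volume_nifti(path),
    dicom_series = read_dicom_series(path))
}

raw_sidecar_path <- function(path) paste0(path, ".json")

RAW_DTYPES <- list(
  uint8   = list(what = "integer", size = 1L, signed = FALSE),
  int16   = list(what = "integer", size = 2L, signed = TRUE),
  uint16  = list(what = "integer", size = 2L, signed = FALSE),
  int32   = list(what = "integer", size = 4L, signed = TRUE),
  float32 = list(what = "double",  size = 4L, signed = TRUE),
  float64 = list(what = "double",  size = 8L, signed = TRUE))

read_volume_raw <- function(path) {
  side <- raw_sidecar_path(path)
  if (!file.exists(side))
    stop(sprintf("raw volume '%s' has no JSON sidecar '%s'", path, side),
         call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("shape", "dtype", "spacing")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("raw sidecar '%s' missing fields: %s", side,
                 paste(miss, collapse = ", ")), call. = FALSE)
  shape <- as.integer(meta$shape)
  dt <- RAW_DTYPES[[meta$dtype]]
  if (is.null(dt))
    stop(sprintf("unsupported raw dtype '%s'", meta$dtype), call. = FALSE)
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) != n)
    stop(sprintf("raw volume '%s' truncated: expected %d voxels, got %d",
                 path, n, length(vals)), call. = FALSE)
  # file is C-order (last index fastest); R arrays are column-major
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  origin <- if (!is.null(meta$origin)) as.numeric(meta$origin) else c(0, 0, 0)
  image_volume(arr, as.numeric(meta$spacing), origin)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) {
    dm <- dim(arr)
    if (prod(dm[-(1:3)]) != 1L)
      stop("NIfTI file has more than one 3D frame", call. = FALSE)
    dim(arr) <- dm[1:3]
  }
  pd <- RNifti::pixdim(img)[1:3]
  image_volume(arr, abs(pd), c(0, 0, 0))
}

#' Write a binary mask as a raw binary dataset
#'
#' One byte per voxel (0/1), C order (last index fastest), little-endian,
#' with a JSON sidecar (`<path>.json`) recording shape, dtype, spacing,
#' origin and element order.  [read_volume()] with `format = "raw"` inverts
#' it exactly.  This is the export format used to hand segmentations to
#' downstream surface/model software.
#'
#' @param mask a [binary_mask()].
#' @param path output file; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_mask_raw <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  bytes <- as.raw(as.integer(aperm(mask$data, c(3, 2, 1))))
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot write raw mask to '%s'", path), call. = FALSE)
  on.exit(close(con))
  writeBin(bytes, con)
  meta <- list(shape = dim(mask$data), dtype = "uint8",
               spacing = mask$spacing, origin = mask$origin,
               order = "C", byte_order = "little")
  jsonlite::write_json(meta, raw_sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a raw binary mask
#'
#' Convenience inverse of [write_mask_raw()] returning a [binary_mask()]
#' (voxels `> 0` become foreground).
#' @param path raw file with JSON sidecar.
#' @return A [binary_mask()].
#' @export
read_mask_raw <- function(path) {
  v <- read_volume(path, "raw")
  binary_mask(v$data > 0, v$spacing, v$origin)
}

#' Write a volume as NIfTI
#'
#' @param volume an [image_volume()].
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an annotation set from JSON
#'
#' The config dialect is
#' `{axis, voi: {lo, hi}, annotations: [{slice, seed: [r, c], threshold}],
#'   central_index, connectivity}`
#' with 1-based inclusive indices.  Unknown keys are errors, so typos in
#' threshold names cannot pass silently.
#'
#' @param path JSON file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("axis", "voi", "annotations", "central_index", "connectivity")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop(sprintf("unknown keys in annotation config '%s': %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  anns <- lapply(cfg$annotations, function(a) {
    unknown <- setdiff(names(a), c("slice", "seed", "threshold"))
    if (length(unknown))
      stop(sprintf("unknown annotation keys: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    slice_annotation(a$slice, unlist(a$seed), a$threshold)
  })
  annotation_set(
    axis = cfg$axis,
    annotations = anns,
    voi = voi(unlist(cfg$voi$lo), unlist(cfg$voi$hi)),
    central_index = if (is.null(cfg$central_index)) NULL
      else as.integer(cfg$central_index),
    connectivity = if (is.null(cfg$connectivity)) 6L
      else as.integer(cfg$connectivity))
}

#' Write an annotation set to JSON
#'
#' @param annotations an [annotation_set()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  a <- annotations
  cfg <- list(
    axis = names(AXES)[a$axis],
    voi = list(lo = a$voi$lo, hi = a$voi$hi),
    annotations = lapply(a$annotations, function(x)
      list(slice = x$slice, seed = x$seed, threshold = x$threshold)),
    central_index = a$central_index,
    connectivity = a$connectivity)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
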
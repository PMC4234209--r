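# Minimal DICOM support: explicit-VR little-endian, uncompressed,
# single-frame grayscale slices.  Only the handful of tags needed to
# assemble a volume are parsed; compressed or implicit-VR files are
# rejected with a format error.  Written in-package because no DICOM
# reader is available among the package's R dependencies.

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  off <- 0L
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") {
    off <- 132L
  } else if (length(bytes) > 4 && rawToChar(bytes[1:4]) == "DICM") {
    off <- 4L
  } else {
    stop(sprintf("'%s' is not a DICOM file (missing DICM magic)", path),
         call. = FALSE)
  }
  tags <- list()
  n <- length(bytes)
  while (off + 8 <= n) {
    group <- u16(bytes[off + 1:2])
    elem <- u16(bytes[off + 3:4])
    vr <- rawToChar(bytes[off + 5:6])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf("'%s': implicit-VR or unsupported transfer syntax", path),
           call. = FALSE)
    if (vr %in% LONG_VRS) {
      len <- u32(bytes[off + 9:12])
      hdr <- 12L
    } else {
      len <- u16(bytes[off + 7:8])
      hdr <- 8L
    }
    if (len == 4294967295)
      stop(sprintf("'%s': undefined-length elements are not supported",
                   path), call. = FALSE)
    val_off <- off + hdr
    if (val_off + len > n)
      stop(sprintf("'%s': truncated DICOM element", path), call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    keep <- c("0028,0010", "0028,0011", "0028,0030", "0028,0100",
              "0028,0103", "0028,1052", "0028,1053", "0020,0032",
              "0020,1041", "7fe0,0010")
    if (key %in% keep) {
      val <- bytes[(val_off + 1):(val_off + len)]
      tags[[key]] <- list(vr = vr, raw = val)
    }
    off <- val_off + len
    if (key == "7fe0,0010") break
  }
  get_us <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    u16(t$raw[1:2])
  }
  get_ds <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    as.numeric(strsplit(trimws(rawToChar(t$raw)), "\\\\")[[1]])
  }
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop(sprintf("'%s': missing Rows/Columns", path), call. = FALSE)
  bits <- get_us("0028,0100", 16L)
  if (!bits %in% c(8L, 16L))
    stop(sprintf("'%s': unsupported BitsAllocated %d", path, bits),
         call. = FALSE)
  signed <- identical(get_us("0028,0103", 0L), 1L)
  px <- tags[["7fe0,0010"]]
  if (is.null(px)) stop(sprintf("'%s': missing PixelData", path),
                        call. = FALSE)
  npx <- rows * cols
  vals <- if (bits == 8L) as.integer(px$raw[seq_len(npx)])
    else readBin(px$raw, "integer", npx, size = 2L, signed = signed,
                 endian = "little")
  slope <- get_ds("0028,1053", 1)[1]
  intercept <- get_ds("0028,1052", 0)[1]
  # PixelData is row-major (across columns fastest)
  img <- matrix(vals * slope + intercept, nrow = rows, ncol = cols,
                byrow = TRUE)
  ipp <- get_ds("0020,0032")
  loc <- if (!is.null(ipp)) ipp[3] else get_ds("0020,1041")
  if (is.null(loc))
    stop(sprintf("'%s': no slice position (ImagePositionPatient/SliceLocation)",
                 path), call. = FALSE)
  list(img = img, pixel_spacing = get_ds("0028,0030", c(1, 1)),
       location = loc)
}

read_dicom_series <- function(dirpath) {
  files <- list.files(dirpath, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files))
    files <- list.files(dirpath, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop(sprintf("no DICOM files found in '%s'", dirpath), call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  locs <- vapply(slices, `[[`, 0, "location")
  ord <- order(locs)
  slices <- slices[ord]; locs <- locs[ord]
  shapes <- vapply(slices, function(s) dim(s$img), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("DICOM slices have inconsistent dimensions", call. = FALSE)
  ps <- slices[[1]]$pixel_spacing
  dz <- if (length(slices) > 1L) diff(locs) else ps[1]
  if (length(slices) > 2L) {
    m <- mean(dz)
    if (any(abs(dz - m) > 0.01 * m))
      stop(sprintf(
        "inconsistent DICOM slice spacing (range %.4f-%.4f mm, > 1%% tolerance)",
        min(dz), max(dz)), call. = FALSE)
  }
  dzm <- mean(dz)
  arr <- array(0, c(length(slices), dim(slices[[1]]$img)))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]$img
  image_volume(arr, c(dzm, ps[1], ps[2]),
               c(min(locs) - dzm / 2, 0, 0))
}
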
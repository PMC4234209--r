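# Tiny explicit-VR little-endian DICOM writer for fixtures.

write_test_dicom <- function(path, img, pixel_spacing = c(0.4, 0.4),
                             zpos = 0, slope = 1, intercept = 0,
                             signed = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  ds_raw <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2) c(r, charToRaw(" ")) else r
  }
  short_el <- function(group, elem, vr, value) {
    w16(group); w16(elem)
    writeBin(charToRaw(vr), con)
    w16(length(value))
    writeBin(value, con)
  }
  us_el <- function(group, elem, x) {
    w16(group); w16(elem)
    writeBin(charToRaw("US"), con)
    w16(2L)
    w16(x)
  }
  short_el(0x0020, 0x0032, "DS", ds_raw(sprintf("0\\0\\%g", zpos)))
  us_el(0x0028, 0x0010, nrow(img))
  us_el(0x0028, 0x0011, ncol(img))
  short_el(0x0028, 0x0030, "DS",
           ds_raw(sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])))
  us_el(0x0028, 0x0100, 16L)
  us_el(0x0028, 0x0103, if (signed) 1L else 0L)
  short_el(0x0028, 0x1052, "DS", ds_raw(sprintf("%g", intercept)))
  short_el(0x0028, 0x1053, "DS", ds_raw(sprintf("%g", slope)))
  # PixelData, OW with 4-byte length; values row-major
  w16(0x7fe0); w16(0x0010)
  writeBin(charToRaw("OW"), con)
  writeBin(raw(2), con)
  writeBin(as.integer(2L * length(img)), con, size = 4L, endian = "little")
  writeBin(as.integer(as.vector(t(img))), con, size = 2L,
           endian = "little")
  invisible(path)
}

write_implicit_vr_dicom <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  # implicit VR: tag then 4-byte length, no VR characters
  writeBin(as.integer(c(0x0028, 0x0010)), con, size = 2L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")
  writeBin(8L, con, size = 2L, endian = "little")
  invisible(path)
}
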
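# Byte-level writer for minimal single-frame CT DICOM files (explicit VR
# little endian), used to exercise the package's DICOM series reader
# without shipping binary fixtures. Synthetic data only.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                    endian = "little")

dcm_even <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH", "DA", "TM")) {
    val <- dcm_even(value, pad = if (vr == "UI") as.raw(0) else
      as.raw(0x20))
  } else if (vr == "US") {
    val <- dcm_raw_u16(value)
  } else if (vr == "OW") {
    val <- value                      # raw vector, already even
  } else stop("unsupported VR in test writer: ", vr)
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr == "OW") {
    c(hdr, as.raw(c(0, 0)), dcm_raw_u32(length(val)), val)
  } else {
    c(hdr, dcm_raw_u16(length(val)), val)
  }
}

# Write one slice. `pixels` is a Columns x Rows integer matrix of stored
# values (column-major x,y as used by the package), written row-major.
write_test_dicom <- function(path, pixels, ipp, series_uid = "1.2.3.4",
                             spacing = c(1, 1), slope = 1,
                             intercept = -1024, signed = TRUE,
                             orientation = c(1, 0, 0, 0, 1, 0)) {
  sop_uid <- paste0("1.2.3.4.5.", sub("\\.dcm$", "", basename(path)))
  meta <- c(
    dcm_element(0x0002, 0x0001, "OW", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  # group length element is UL; encode manually
  meta_group_len <- c(dcm_raw_u16(0x0002), dcm_raw_u16(0x0000),
                      charToRaw("UL"), dcm_raw_u16(4),
                      dcm_raw_u32(length(meta)))
  # row-major emission (column index fastest) = column-major of the
  # Columns x Rows matrix
  pix <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS",
                paste(format(ipp, trim = TRUE), collapse = "\\")),
    dcm_element(0x0020, 0x0037, "DS",
                paste(format(orientation, trim = TRUE), collapse = "\\")),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", ncol(pixels)),   # Rows
    dcm_element(0x0028, 0x0011, "US", nrow(pixels)),   # Columns
    dcm_element(0x0028, 0x0030, "DS",
                paste(format(spacing[c(2, 1)], trim = TRUE),
                      collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", as.integer(signed)),
    dcm_element(0x0028, 0x1052, "DS", format(intercept, trim = TRUE)),
    dcm_element(0x0028, 0x1053, "DS", format(slope, trim = TRUE)),
    c(dcm_raw_u16(0x7FE0), dcm_raw_u16(0x0010), charToRaw("OW"),
      as.raw(c(0, 0)), dcm_raw_u32(length(pix)), pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_group_len, meta, ds), con)
  invisible(path)
}

# A small synthetic CT series: nx x ny x nz gradient + recognisable block.
write_test_dicom_series <- function(dir, nx = 12, ny = 10, nz = 5,
                                    spacing = c(1.5, 1.5, 2.5),
                                    slope = 1, intercept = -1024,
                                    series_uid = "1.2.3.4") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz))
    vol[, , k] <- outer(seq_len(nx), seq_len(ny),
                        function(i, j) 10L * i + j) + 100L * k
  for (k in seq_len(nz))
    write_test_dicom(
      file.path(dir, sprintf("slice%02d.dcm", k)),
      pixels = vol[, , k],
      ipp = c(-20, -30, (k - 1) * spacing[3]),
      series_uid = series_uid, spacing = spacing[1:2],
      slope = slope, intercept = intercept)
  # expected HU volume in LPS -> RAS canonical frame
  hu <- vol * slope + intercept
  invisible(list(dir = dir, stored = vol, hu = hu, spacing = spacing,
                 ipp0 = c(-20, -30, 0)))
}
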
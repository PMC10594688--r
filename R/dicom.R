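# Minimal DICOM series reader: uncompressed little-endian Part 10 files
# (implicit or explicit VR), 16-bit stored pixels, one series per
# directory. Stored values are mapped through RescaleSlope/Intercept to
# HU. No installed R package parses DICOM, so the subset needed for CT
# series is implemented here; sequences and compressed transfer syntaxes
# are out of scope.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16 <- function(raw, at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# Parse one file into a list of elements keyed "gggg,eeee" (hex).
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  pos <- 133L
  elems <- list()
  explicit <- TRUE                       # file meta is always explicit LE
  ts <- TS_EXPLICIT_LE
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  meta_done <- FALSE
  while (pos + 7L <= length(raw)) {
    grp <- u16(raw, pos); ele <- u16(raw, pos + 2L)
    if (!meta_done && grp != 0x0002) {
      meta_done <- TRUE
      ts_el <- elems[["0002,0010"]]
      ts <- if (is.null(ts_el)) TS_EXPLICIT_LE else
        sub("\\s+$", "", rawToChar(ts_el[ts_el != as.raw(0)]))
      if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", ts)
      explicit <- ts == TS_EXPLICIT_LE
    }
    if (explicit || grp == 0x0002) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 2^32 - 1)
      stop("undefined-length DICOM elements (sequences) are not supported")
    key <- sprintf("%04x,%04x", grp, ele)
    val_at <- pos + hdr
    if (val_at + len - 1L > length(raw))
      stop("truncated DICOM element ", key, " in ", path)
    if (len > 0)
      elems[[key]] <- raw[val_at:(val_at + len - 1L)]
    else
      elems[[key]] <- raw(0)
    pos <- val_at + len
    if (grp == 0x7fe0 && ele == 0x0010) break
  }
  elems
}

dcm_str <- function(elems, key, required = FALSE) {
  v <- elems[[key]]
  if (is.null(v)) {
    if (required) stop("required DICOM tag (", key, ") missing")
    return(NULL)
  }
  s <- rawToChar(v[v != as.raw(0)])
  sub("\\s+$", "", s)
}

dcm_ds <- function(elems, key, required = FALSE) {
  s <- dcm_str(elems, key, required)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  u16(v, 1L)
}

#' Read a DICOM series as a CT volume
#'
#' Reads every DICOM file in `path`, checks that all slices belong to one
#' series, sorts them along the slice normal, verifies uniform slice
#' spacing, applies RescaleSlope/RescaleIntercept to obtain HU, and
#' reorients the result to the canonical RAS frame.
#'
#' @param path Directory containing the series (`.dcm` files, or all
#'   regular files if none match).
#' @param slice_tol Relative tolerance on slice-spacing uniformity
#'   (default `1e-3`); series exceeding it are rejected.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(path, slice_tol = 1e-3) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files in ", path)
  slices <- lapply(files, parse_dicom_file)

  uid <- vapply(slices, function(e) dcm_str(e, "0020,000e", TRUE), "")
  if (length(unique(uid)) != 1L)
    stop("directory mixes ", length(unique(uid)), " DICOM series")

  first <- slices[[1]]
  rows <- dcm_us(first, "0028,0010"); cols <- dcm_us(first, "0028,0011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns tags")
  bits <- dcm_us(first, "0028,0100")
  if (!identical(bits, 16L)) stop("only 16-bit DICOM pixel data is supported")
  signed <- identical(dcm_us(first, "0028,0103"), 1L)
  psp <- dcm_ds(first, "0028,0030", TRUE)     # row spacing, column spacing
  iop <- dcm_ds(first, "0020,0037")
  if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  ipp <- t(vapply(slices, function(e) dcm_ds(e, "0020,0032", TRUE),
                  numeric(3)))
  z <- drop(ipp %*% normal)
  ord <- order(z)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("duplicate or non-monotone slice positions")
    if (max(abs(dz - mean(dz))) > slice_tol * mean(dz) + 1e-9)
      stop("nonuniform slice spacing (max deviation ",
           signif(max(abs(dz - mean(dz))), 3), " mm)")
    dz <- mean(dz)
  } else dz <- if (!is.null(dcm_ds(first, "0018,0050"))) {
    dcm_ds(first, "0018,0050")
  } else 1

  vol <- array(0, c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    e <- slices[[k]]
    slope <- dcm_ds(e, "0028,1053", TRUE)
    inter <- dcm_ds(e, "0028,1052", TRUE)
    pix <- e[["7fe0,0010"]]
    if (is.null(pix) || length(pix) < 2 * rows * cols)
      stop("missing or short PixelData in slice ", k)
    v <- readBin(pix, "integer", n = rows * cols, size = 2,
                 endian = "little", signed = signed)
    # DICOM pixels are row-major: consecutive values run across a row.
    vol[, , k] <- matrix(v * slope + inter, nrow = cols, ncol = rows)
  }

  # DICOM patient coordinates are LPS; convert direction/origin to RAS.
  lps2ras <- diag(c(-1, -1, 1))
  direction <- lps2ras %*% cbind(row_dir, col_dir, normal)
  origin <- drop(lps2ras %*% ipp[1, ])
  spacing <- c(psp[2], psp[1], dz)          # x = column step, y = row step
  canonicalize_volume(ct_volume(vol, spacing = spacing, origin = origin,
                                orientation = unname(direction)))
}

# If the direction matrix is (numerically) a signed permutation, flip and
# permute array axes so the orientation becomes the identity (RAS).
canonicalize_volume <- function(v) {
  D <- v$orientation
  if (max(abs(abs(D) - round(abs(D)))) > 1e-3) return(v)  # oblique: keep
  a <- v$data; sp <- v$spacing; org <- v$origin
  n <- dim(a)
  for (j in 1:3) {
    p <- which.max(abs(D[, j]))
    if (D[p, j] < 0) {
      idx <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
      idx[[j]] <- rev(idx[[j]])
      a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
      org <- org + D[, j] * sp[j] * (n[j] - 1)
      D[, j] <- -D[, j]
    }
  }
  perm <- apply(abs(D), 2, which.max)
  inv <- order(perm)
  a <- aperm(a, inv)
  ct_volume(a, spacing = sp[inv], origin = org, orientation = D[, inv])
}
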
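# NIfTI input/output. All volumes are reoriented to the RAS axis
# convention on load so that paired scans share one frame; geometry is
# taken from the (re)oriented xform: direction = xform[,1:3] with spacing
# divided out, origin = xform[,4].

#' Read a CT volume from NIfTI or a DICOM series
#'
#' Reads a scalar CT volume and normalises it to the package's canonical
#' representation: axis order reoriented to RAS, values interpreted as
#' Hounsfield units and clamped to \[-1024, 3071\]. DICOM stored values are
#' mapped through RescaleSlope/RescaleIntercept before clamping.
#'
#' @param path Path to a `.nii`/`.nii.gz` file, or a directory containing
#'   one DICOM series.
#' @param format `"nifti"` or `"dicom"`; `"auto"` (default) picks DICOM for
#'   a directory and NIfTI otherwise.
#' @return A [ct_volume()].
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 4)))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(v, f)
#' v2 <- read_volume(f)
#' stopifnot(identical(v$data, v2$data))
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom") return(read_dicom_series(path))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3-D volume: ", path)
  RNifti::orientation(img) <- "RAS"
  geo <- nifti_geometry(img)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  ct_volume(dat, spacing = geo$spacing, origin = geo$origin,
            orientation = geo$orientation)
}

nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("non-positive voxel spacing in NIfTI header")
  list(spacing = sp,
       origin = xf[1:3, 4],
       orientation = sweep(xf[1:3, 1:3], 2, sp, `/`))
}

#' Write a volume, mask or label map to NIfTI
#'
#' CT volumes are stored as 64-bit floats so that write/read round trips
#' are exact; masks and label maps as unsigned 8-bit integers.
#'
#' @param v A `ct_volume`, `lung_mask` or `label_map`.
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (!(is_ct_volume(v) || is_lung_mask(v) || is_label_map(v)))
    stop("'v' must be a ct_volume, lung_mask or label_map")
  dtype <- if (is_ct_volume(v)) "double" else "uint8"
  dat <- if (is_ct_volume(v)) v$data else array(as.integer(v$data), dim(v$data))
  if (dtype == "uint8" && (min(dat) < 0 || max(dat) > 255))
    stop("label codes outside the uint8 range")
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- v$spacing
  aff <- rbind(cbind(sweep(v$orientation, 2, v$spacing, `*`), v$origin),
               c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Load a lung mask and check it against a reference grid
#'
#' Any nonzero stored value becomes `TRUE`; the mask must pass
#' [check_geometry()] against `reference`.
#'
#' @param path NIfTI file containing the mask.
#' @param reference The `ct_volume` the mask indexes.
#' @return A [lung_mask()] on `reference`'s grid.
#' @export
load_mask <- function(path, reference) {
  m <- read_volume(path, format = "nifti")
  if (!check_geometry(m, reference))
    stop("mask geometry does not match the reference volume: ", path)
  lung_mask(m$data != 0, reference)
}
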
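# Core containers: CT volumes, lung masks and label maps share one voxel
# grid model (3-D array + spacing/origin/orientation). Physical coordinates
# follow x = origin + orientation %*% (spacing * i0) with i0 the 0-based
# voxel index, so voxel (1,1,1) in R sits at `origin`.

HU_MIN <- -1024
HU_MAX <- 3071

#' Construct a CT volume in Hounsfield units
#'
#' A `ct_volume` is a 3-D scalar field of Hounsfield units (HU) together
#' with its voxel geometry. Values are clamped to the 12-bit CT range
#' \[-1024, 3071\] on construction; out-of-range values in raw data are
#' scanner padding, not tissue.
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param orientation 3x3 direction matrix mapping voxel axes to physical
#'   axes; must be orthonormal. Identity corresponds to axis-aligned RAS.
#' @return Object of class `ct_volume` with fields `data`, `spacing`,
#'   `origin`, `orientation`.
#' @seealso [lung_mask()], [label_map()], [read_volume()]
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      orientation = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-4)
    stop("'orientation' must be a 3x3 orthonormal matrix")
  storage.mode(data) <- "double"
  structure(
    list(data = clamp_hu(data), spacing = spacing, origin = origin,
         orientation = orientation),
    class = "ct_volume"
  )
}

#' Clamp values to the CT Hounsfield range
#'
#' Restricts values to \[-1024, 3071\], the conventional 12-bit CT range.
#' Idempotent.
#'
#' @param x Numeric vector or array.
#' @return `x` with values outside the range replaced by the nearest bound.
#' @export
clamp_hu <- function(x) {
  x[x < HU_MIN] <- HU_MIN
  x[x > HU_MAX] <- HU_MAX
  x
}

#' Construct a binary lung mask on a CT volume's grid
#'
#' @param data 3-D array; any nonzero value marks a parenchyma voxel.
#' @param grid A `ct_volume` supplying the geometry, or a list with
#'   `spacing`, `origin`, `orientation` fields.
#' @return Object of class `lung_mask` with logical `data` and the grid
#'   geometry copied from `grid`.
#' @export
lung_mask <- function(data, grid) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  geo <- grid_of(grid)
  if (!is.null(dim_of(grid)) && !all(dim(data) == dim_of(grid)))
    stop("mask shape does not match its reference grid")
  structure(
    list(data = array(data != 0, dim(data)), spacing = geo$spacing,
         origin = geo$origin, orientation = geo$orientation),
    class = "lung_mask"
  )
}

#' Construct a label map on a CT volume's grid
#'
#' Label maps carry small nonnegative integer class codes (0 = outside the
#' analysis) plus a legend naming each code.
#'
#' @param data 3-D array of integer codes, 0 meaning "outside analysis".
#' @param grid Geometry source as in [lung_mask()].
#' @param legend Named integer vector or named list mapping class names to
#'   codes; must cover every nonzero code present.
#' @return Object of class `label_map`.
#' @export
label_map <- function(data, grid, legend) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  geo <- grid_of(grid)
  if (!is.null(dim_of(grid)) && !all(dim(data) == dim_of(grid)))
    stop("label map shape does not match its reference grid")
  codes <- as.integer(unlist(legend))
  names(codes) <- names(unlist(legend))
  if (any(is.na(codes)) || is.null(names(codes)) || any(!nzchar(names(codes))))
    stop("'legend' must be a named code mapping")
  present <- sort(unique(as.integer(data[data != 0])))
  if (!all(present %in% codes))
    stop("legend does not cover codes present in the map: ",
         paste(setdiff(present, codes), collapse = ", "))
  d <- array(as.integer(data), dim(data))
  structure(
    list(data = d, spacing = geo$spacing, origin = geo$origin,
         orientation = geo$orientation, legend = codes),
    class = "label_map"
  )
}

grid_of <- function(x) {
  if (is.null(x$spacing)) stop("no grid geometry available")
  list(spacing = x$spacing, origin = x$origin,
       orientation = if (is.null(x$orientation)) diag(3) else x$orientation)
}

dim_of <- function(x) if (is.array(x$data)) dim(x$data) else NULL

is_ct_volume <- function(x) inherits(x, "ct_volume")
is_lung_mask <- function(x) inherits(x, "lung_mask")
is_label_map <- function(x) inherits(x, "label_map")

#' Test whether two volumes share the same grid
#'
#' Compares shape exactly, and spacing, origin and orientation within a
#' relative tolerance of 1e-3 (absolute for quantities of magnitude below
#' 1), so sub-micrometre header noise does not break voxel-wise pairing.
#'
#' @param a,b Objects carrying grid geometry (`ct_volume`, `lung_mask` or
#'   `label_map`).
#' @param tol Relative tolerance, default `1e-3`.
#' @return `TRUE` iff the grids agree.
#' @export
check_geometry <- function(a, b, tol = 1e-3) {
  da <- dim_of(a); db <- dim_of(b)
  if (is.null(da) || is.null(db) || length(da) != length(db) ||
      !all(da == db)) return(FALSE)
  near <- function(x, y) all(abs(x - y) <= tol * pmax(1, abs(x), abs(y)))
  ga <- grid_of(a); gb <- grid_of(b)
  near(ga$spacing, gb$spacing) && near(ga$origin, gb$origin) &&
    near(ga$orientation, gb$orientation)
}

# Physical coordinates (mm) of 1-based voxel indices, n x 3 matrix in, out.
voxel_to_physical <- function(geom, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  i0 <- sweep(idx, 2, c(1, 1, 1))            # to 0-based
  sc <- sweep(i0, 2, geom$spacing, `*`)
  sweep(sc %*% t(geom$orientation), 2, geom$origin, `+`)
}

# Inverse of voxel_to_physical; returns continuous (fractional) 1-based
# voxel indices.
physical_to_voxel <- function(geom, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  rel <- sweep(pts, 2, geom$origin) %*% geom$orientation  # t(R^-1) = R
  sweep(sweep(rel, 2, geom$spacing, `/`), 2, c(1, 1, 1), `+`)
}

# Physical centroid (mm) of a mask's TRUE voxels.
mask_centroid <- function(m) {
  idx <- which(m$data)
  if (length(idx) == 0L) stop("empty mask has no centroid")
  colMeans(voxel_to_physical(m, arrayInd(idx, dim(m$data))))
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%s) mm\n",
              min(x$data), max(x$data),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Lung mask: %d x %d x %d voxels, %d (%.1f%%) in mask\n",
              d[1], d[2], d[3], sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Label map: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(factor(x$data[x$data != 0],
                      levels = x$legend, labels = names(x$legend)))
  for (nm in names(tab))
    cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  invisible(x)
}
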
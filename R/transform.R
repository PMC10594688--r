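# 3-D affine transforms. An affine_transform maps moving-frame physical
# points p (mm) to fixed-frame points via f(p) = M (p - c) + c + t, the
# usual centred parameterisation: rotations/scalings act about `center`
# rather than the scanner origin, which keeps the translation parameters
# well-scaled during optimisation.

#' Construct a 3-D affine transform
#'
#' Maps physical points (mm) by `M (p - center) + center + translation`.
#'
#' @param matrix 3x3 linear part; must be invertible (|det| > 1e-8).
#' @param translation Length-3 translation in mm.
#' @param center Length-3 centre of the linear action in mm.
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(3, 3)) || any(!is.finite(matrix)))
    stop("'matrix' must be a finite 3x3 matrix")
  if (abs(det(matrix)) < 1e-8)
    stop("singular affine transform (|det| < 1e-8)")
  structure(list(matrix = matrix,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' Apply an affine transform to physical points
#'
#' @param t An [affine_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of points in mm.
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  rel <- sweep(pts, 2, t$center)
  sweep(rel %*% t(t$matrix), 2, t$center + t$translation, `+`)
}

#' Invert an affine transform
#'
#' @param t An [affine_transform()].
#' @return The inverse transform (same centre).
#' @export
invert_transform <- function(t) {
  mi <- solve(t$matrix)
  affine_transform(mi, -drop(mi %*% t$translation), t$center)
}

#' Compose two affine transforms
#'
#' Returns the transform applying `b` first, then `a` (`a %after% b` in
#' function-composition order: `compose_transforms(a, b)(p) = a(b(p))`).
#'
#' @param a,b [affine_transform()] objects.
#' @return An [affine_transform()] with `a`'s centre.
#' @export
compose_transforms <- function(a, b) {
  # a(b(p)) = Ma (Mb (p - cb) + cb + tb - ca) + ca + ta
  # rewrite about ca: M = Ma Mb; t chosen so M (p - ca) + ca + t matches.
  M <- a$matrix %*% b$matrix
  p0 <- a$center  # evaluate at p = ca to solve for t
  val <- transform_points(a, transform_points(b, p0))
  affine_transform(M, drop(val) - p0, p0)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("3-D affine transform (moving -> fixed, mm)\n")
  cat("  matrix:\n")
  print(signif(x$matrix, 6))
  cat("  translation:", paste(signif(x$translation, 6), collapse = ", "),
      "\n  center:     ", paste(signif(x$center, 6), collapse = ", "), "\n")
  invisible(x)
}

# Mean displacement (mm) of a transform relative to identity over the
# voxels of a mask; used to measure registration recovery error.
mean_displacement <- function(t, mask) {
  idx <- which(mask$data)
  pts <- voxel_to_physical(mask, arrayInd(idx, dim(mask$data)))
  mean(sqrt(rowSums((transform_points(t, pts) - pts)^2)))
}

# Write/read a transform as plain text: 4 rows of the homogeneous matrix
# followed by the centre.
write_transform <- function(t, path) {
  hom <- rbind(cbind(t$matrix, t$translation), c(0, 0, 0, 1))
  lines <- c("# affine transform: rows of homogeneous matrix (about center), then center (mm)",
             apply(hom, 1, function(r) paste(format(r, digits = 17),
                                             collapse = " ")),
             paste(format(t$center, digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

read_transform <- function(path) {
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l),
                                                        "\\s+")[[1]]))
  hom <- do.call(rbind, vals[1:4])
  affine_transform(hom[1:3, 1:3], hom[1:3, 4], vals[[5]])
}
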
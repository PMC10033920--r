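#' Affine map between total-pixel-matrix and slide coordinates
#'
#' Maps 2D image coordinates (column, row), at sub-pixel resolution, of
#' the total pixel matrix of the highest-resolution image to 3D slide
#' coordinates (x, y, z) in millimeters, and back. The forward map is a
#' single 3x3 homogeneous matrix applied to (column, row, 1); the
#' inverse is computed once at construction and cached.
#'
#' Pixel-center convention: integer coordinate (0, 0) denotes the
#' center of the top-left pixel, and the metadata origin gives that
#' center's slide position. This convention makes pixel-to-slide
#' round trips exact.
#'
#' @slot forward 3x3 homogeneous matrix (column, row, 1) -> (x, y, 1) mm.
#' @slot inverse Cached inverse of `forward`.
#' @slot z_mm Constant z offset of the image plane, mm.
#' @export
setClass("AffineMap", representation(
  forward = "matrix", inverse = "matrix", z_mm = "numeric"
))

setValidity("AffineMap", function(object) {
  if (!all(dim(object@forward) == c(3, 3)))
    return("forward must be a 3x3 matrix")
  if (abs(det(object@forward)) <= 1e-12)
    return("forward matrix is singular")
  if (max(abs(object@inverse %*% object@forward - diag(3))) > 1e-9)
    return("cached inverse does not invert forward within 1e-9")
  TRUE
})

setMethod("show", "AffineMap", function(object) {
  cat("AffineMap (pixel -> slide mm), z =", object@z_mm, "mm\n")
  print(object@forward)
})

#' Build the pixel-to-slide affine map from image metadata
#'
#' The column axis is scaled by the column spacing, the row axis by the
#' row spacing, and the translation is the slide-coordinate position of
#' the center of pixel (0, 0). Per convention the map should be built
#' from the highest-resolution image of a pyramid to keep floating
#' point error minimal; [pyramidAffineMap()] does this for a slide.
#'
#' @param metadata A [SlideImageMetadata-class].
#' @return An [AffineMap-class].
#' @examples
#' # identity orientation, 1 um spacing: pixel (100, 0) lies 0.1 mm
#' # from the origin along x
#' @export
buildPixelToSlide <- function(metadata) {
  o <- metadata@orientation
  row_dir <- o[1:3]   # direction of increasing column index
  col_dir <- o[4:6]   # direction of increasing row index
  if (max(abs(row_dir %*% col_dir)) > 1 - 1e-6)
    dcmStop("degenerate_orientation",
            "orientation direction cosines are parallel")
  dc <- metadata@pixel_spacing_col_mm
  dr <- metadata@pixel_spacing_row_mm
  forward <- matrix(c(
    row_dir[1] * dc, col_dir[1] * dr, metadata@origin_x_mm,
    row_dir[2] * dc, col_dir[2] * dr, metadata@origin_y_mm,
    0,               0,               1
  ), nrow = 3, byrow = TRUE)
  new("AffineMap", forward = forward, inverse = solve(forward),
      z_mm = metadata@origin_z_mm)
}

.as_points <- function(points, ncols) {
  if (is.null(dim(points))) points <- matrix(points, ncol = ncols, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

#' Map image points to 3D slide coordinates
#'
#' @param map An [AffineMap-class].
#' @param points Numeric matrix n x 2 of (column, row) image
#'   coordinates (sub-pixel resolution allowed; points outside the
#'   pixel matrix extrapolate).
#' @return Matrix n x 3 of (x, y, z) slide coordinates in mm, in input
#'   order.
#' @export
pixelToSlide <- function(map, points) {
  p <- .as_points(points, 2L)
  h <- cbind(p, 1) %*% t(map@forward)
  out <- cbind(h[, 1:2, drop = FALSE], map@z_mm)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Map 3D slide coordinates back to image points
#'
#' The z component of each point is validated against the plane offset
#' of the map within 1e-3 mm; points off the plane trigger a
#' plane-mismatch warning but are still projected.
#'
#' @param map An [AffineMap-class].
#' @param points Numeric matrix n x 3 of (x, y, z) mm (or n x 2, z
#'   assumed on-plane).
#' @return Matrix n x 2 of (column, row) image coordinates.
#' @export
slideToPixel <- function(map, points) {
  p <- .as_points(points, 3L)
  if (ncol(p) >= 3) {
    dz <- abs(p[, 3] - map@z_mm)
    if (any(dz > 1e-3))
      dcmWarn("plane_mismatch",
              "%d point(s) lie off the image plane by up to %.3g mm; projecting",
              sum(dz > 1e-3), max(dz))
  }
  h <- cbind(p[, 1:2, drop = FALSE], 1) %*% t(map@inverse)
  out <- h[, 1:2, drop = FALSE]
  colnames(out) <- c("column", "row")
  out
}
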
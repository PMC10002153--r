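#' Pixel-grid conventions
#'
#' Masks are logical matrices of shape `height x width`; images are numeric
#' matrices of the same shape with gray levels in `[0, 1]`. The matrix row
#' index is the image row (origin top-left, rows grow downward, so the
#' "lowest" point of a structure is the one with the largest row), the column
#' index is the image column. Points are length-2 numeric vectors
#' `c(row, col)` in continuous pixel coordinates where the center of pixel
#' `(i, j)` is exactly `(i, j)` (1-based).
#'
#' A positive rotation angle turns the positive column axis toward the
#' positive row axis, i.e. counter-clockwise on screen once the downward row
#' axis is taken into account.
#'
#' @name pixel-conventions
#' @keywords internal
NULL

point_rc <- function(row, col) c(row = as.numeric(row), col = as.numeric(col))

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_image_format(sprintf("%s must be a logical matrix", what))
  }
  invisible(mask)
}

mask_pixels <- function(mask) {
  idx <- which(mask)
  cbind(row = (idx - 1L) %% nrow(mask) + 1L,
        col = (idx - 1L) %/% nrow(mask) + 1L)
}

pixels_to_mask <- function(px, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  keep <- px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2]
  m[cbind(px[keep, 1], px[keep, 2])] <- TRUE
  m
}

#' Barycenter of a binary mask
#'
#' Unweighted centroid of the true-pixel centers.
#'
#' @param mask Logical matrix.
#' @return Named numeric vector `c(row, col)`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' barycenter(m)  # (1.5, 1.5)
#' @export
barycenter <- function(mask) {
  assert_mask(mask)
  px <- mask_pixels(mask)
  if (nrow(px) == 0L) abort_empty_mask()
  point_rc(mean(px[, 1]), mean(px[, 2]))
}

rotation_matrix <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Rotate a point about a center
#'
#' @param p,center Points `c(row, col)`.
#' @param angle_deg Rotation angle in degrees (see [pixel-conventions]).
#' @export
rotate_point <- function(p, angle_deg, center) {
  v <- rotation_matrix(angle_deg) %*% (as.numeric(p) - as.numeric(center))
  point_rc(v[1] + center[1], v[2] + center[2])
}

# Inverse-mapped source coordinates for every output pixel center.
inverse_map <- function(shape, angle_deg, center) {
  rows <- rep(seq_len(shape[1]), times = shape[2])
  cols <- rep(seq_len(shape[2]), each = shape[1])
  R <- rotation_matrix(-angle_deg)
  dr <- rows - center[1]
  dc <- cols - center[2]
  list(row = R[1, 1] * dr + R[1, 2] * dc + center[1],
       col = R[2, 1] * dr + R[2, 2] * dc + center[2])
}

#' Rigidly rotate a mask or a grayscale image
#'
#' The output grid keeps the input shape; content rotated out of frame is
#' dropped. Masks are resampled with nearest-neighbor lookup so labels stay
#' binary; images with bilinear interpolation (out-of-frame reads as 0).
#'
#' @param mask Logical matrix.
#' @param image Numeric matrix in `[0, 1]`.
#' @param angle_deg Finite rotation angle in degrees.
#' @param center Point `c(row, col)`; defaults to the grid center.
#' @return Matrix of the input shape.
#' @export
rotate_region <- function(mask, angle_deg, center = grid_center(mask)) {
  assert_mask(mask)
  stopifnot(is.finite(angle_deg))
  src <- inverse_map(dim(mask), angle_deg, center)
  r <- round(src$row)
  c <- round(src$col)
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  out <- logical(length(r))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  matrix(out, nrow(mask), ncol(mask))
}

#' @rdname rotate_region
#' @export
rotate_image <- function(image, angle_deg, center = grid_center(image)) {
  stopifnot(is.matrix(image), is.numeric(image), is.finite(angle_deg))
  src <- inverse_map(dim(image), angle_deg, center)
  H <- nrow(image); W <- ncol(image)
  r0 <- floor(src$row); c0 <- floor(src$col)
  fr <- src$row - r0;   fc <- src$col - c0
  val <- function(rr, cc) {
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    v <- numeric(length(rr))
    v[ok] <- image[cbind(rr[ok], cc[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1L) +
    fr * (1 - fc) * val(r0 + 1L, c0) +
    fr * fc * val(r0 + 1L, c0 + 1L)
  matrix(out, H, W)
}

grid_center <- function(m) point_rc((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)

normalize_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  if (a <= -180) a + 360 else a
}

#' Vertically align a two-part tooth segmentation
#'
#' Rotates both instance masks, about the midpoint of their barycenters, by
#' the angle that maps the coronal-to-apical barycenter vector onto the
#' downward vertical. After alignment the two barycenters share a column and
#' the coronal (crown) instance lies above the apical instance; a pair whose
#' apical barycenter sits above the coronal one comes out rotated by 180
#' degrees, which enforces the crown-up convention automatically.
#'
#' @param apical,coronal Disjoint, non-empty logical masks of equal shape.
#' @return An object of class `aligned_tooth_masks`: a list with elements
#'   `apical`, `coronal`, `rotation_deg`, `rotation_center`,
#'   `apical_barycenter`, `coronal_barycenter` (the last two are the
#'   analytically rotated input barycenters).
#' @export
align_vertical <- function(apical, coronal) {
  assert_mask(apical, "apical"); assert_mask(coronal, "coronal")
  if (!all(dim(apical) == dim(coronal))) {
    abort_shape_mismatch("apical and coronal masks must share a shape")
  }
  n_overlap <- sum(apical & coronal)
  if (n_overlap > 0L) abort_mask_overlap(n_overlap)
  bc_a <- barycenter(apical)
  bc_c <- barycenter(coronal)
  v <- bc_a - bc_c
  if (sqrt(sum(v^2)) < 1e-9) {
    abort_degenerate_geometry("apical and coronal barycenters coincide")
  }
  angle <- normalize_angle(-atan2(v[["col"]], v[["row"]]) * 180 / pi)
  center <- point_rc((bc_a[1] + bc_c[1]) / 2, (bc_a[2] + bc_c[2]) / 2)
  out <- list(
    apical = if (abs(angle) < 1e-12) apical else rotate_region(apical, angle, center),
    coronal = if (abs(angle) < 1e-12) coronal else rotate_region(coronal, angle, center),
    rotation_deg = angle,
    rotation_center = center,
    apical_barycenter = rotate_point(bc_a, angle, center),
    coronal_barycenter = rotate_point(bc_c, angle, center)
  )
  structure(out, class = "aligned_tooth_masks")
}

#' @export
print.aligned_tooth_masks <- function(x, ...) {
  cat(sprintf(
    "<aligned_tooth_masks> %dx%d, rotation %.2f deg, barycenter column %.2f\n",
    nrow(x$apical), ncol(x$apical), x$rotation_deg, x$apical_barycenter[["col"]]))
  invisible(x)
}
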
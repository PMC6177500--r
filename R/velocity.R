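#' Three-component velocity volume
#'
#' Container for a phase-contrast-like velocity image: a 4D array
#' (x, y, z, component) of velocities in cm/s plus an invertible affine
#' mapping 0-based voxel indices to world millimetre coordinates, the same
#' frame the surface meshes live in.
#'
#' @param data 4D numeric array, last dimension of length 3 (velocity
#'   components along the world x, y, z axes, cm/s).
#' @param affine 4 x 4 voxel-to-mm transform (0-based voxel indices).  If
#'   omitted, built from `spacing` and `origin`.
#' @param spacing voxel size, mm (length 3).
#' @param origin world position of voxel (0,0,0), mm.
#' @param corrected logical flag: has background phase offset correction
#'   been applied?
#' @return an object of class `velocity_image`.
#' @export
velocity_image <- function(data, affine = NULL, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), corrected = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("data must be a 4D array with 3 velocity components")
  if (!all(is.finite(data))) stop("velocity image contains non-finite values")
  if (is.null(affine)) {
    if (any(spacing <= 0)) stop("spacing must be positive")
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(data = data, affine = affine, corrected = corrected),
            class = "velocity_image")
}

#' @export
print.velocity_image <- function(x, ...) {
  d <- dim(x$data)
  sp <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("velocity_image: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              if (isTRUE(x$corrected)) " (offset-corrected)" else ""))
  cat(sprintf("  |v| range 0 .. %.3g cm/s\n",
              max(sqrt(rowSums(matrix(x$data, ncol = 3)^2)))))
  invisible(x)
}

voxel_spacing <- function(img) sqrt(colSums(img$affine[1:3, 1:3]^2))

## world mm -> continuous 0-based voxel coordinates
world_to_voxel <- function(img, points) {
  inv <- solve(img$affine)
  p1 <- cbind(points, 1)
  (p1 %*% t(inv))[, 1:3, drop = FALSE]
}

voxel_to_world <- function(img, ijk0) {
  p1 <- cbind(ijk0, 1)
  (p1 %*% t(img$affine))[, 1:3, drop = FALSE]
}

#' Sample velocity vectors at world coordinates
#'
#' Trilinear interpolation of each velocity component at arbitrary mm
#' positions.  Points outside the grid return `NA` for all components.
#'
#' @param img a [velocity_image()].
#' @param points n x 3 matrix of world coordinates, mm.
#' @return n x 3 matrix of velocities, cm/s (`NA` rows when out of bounds).
#' @export
sample_velocity <- function(img, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  vox <- world_to_voxel(img, points)
  d <- dim(img$data)[1:3]
  inb <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
         vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
         vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  out <- matrix(NA_real_, nrow(points), 3)
  if (!any(inb)) return(out)
  vv <- vox[inb, , drop = FALSE]
  i0 <- floor(vv)
  for (ax in 1:3)  # clamp so points exactly on the far face still have a cell
    i0[, ax] <- pmin(pmax(i0[, ax], 0), d[ax] - 2)
  fr <- vv - i0
  acc <- matrix(0, nrow(i0), 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    for (comp in 1:3)
      acc[, comp] <- acc[, comp] + w * img$data[cbind(idx, comp)]
  }
  out[inb, ] <- acc
  out
}

#' Subtract the background phase offset measured in static tissue
#'
#' Mirrors the standard phase-contrast correction: the mean velocity over a
#' static-tissue voxel mask is subtracted from every component.
#'
#' @param img a [velocity_image()].
#' @param static_mask logical 3D array matching the image grid, `TRUE` in
#'   static tissue (must be non-empty and should be disjoint from the
#'   lumen).
#' @return the corrected [velocity_image()], flagged `corrected`.
#' @export
correct_background_offset <- function(img, static_mask) {
  static_mask <- as.array(static_mask)
  if (!identical(dim(static_mask), dim(img$data)[1:3]))
    stop("static_mask dimensions must match the image grid")
  if (!any(static_mask)) stop("static mask is empty")
  dat <- img$data
  off <- numeric(3)
  for (comp in 1:3) {
    ch <- dat[, , , comp]
    off[comp] <- mean(ch[static_mask])
    dat[, , , comp] <- ch - off[comp]
  }
  out <- velocity_image(dat, affine = img$affine, corrected = TRUE)
  attr(out, "offset_removed") <- off
  out
}

#' Identify static-tissue voxels from the lumen surface
#'
#' Marks voxels whose centres lie at least `margin` mm from every lumen
#' vertex as static tissue.  The grid can be strided for speed; unvisited
#' voxels stay `FALSE`, which only shrinks the mask.
#'
#' @param img a [velocity_image()].
#' @param lumen the lumen [vessel_mesh()].
#' @param margin minimum clearance from the lumen surface, mm.  Must exceed
#'   the largest lumen radius so that interior voxels are excluded.
#' @param stride sample every `stride`-th voxel along each axis.
#' @return logical 3D array.
#' @export
static_tissue_mask <- function(img, lumen, margin = 5, stride = 2L) {
  d <- dim(img$data)[1:3]
  gi <- seq(0L, d[1] - 1L, by = stride)
  gj <- seq(0L, d[2] - 1L, by = stride)
  gk <- seq(0L, d[3] - 1L, by = stride)
  ijk <- as.matrix(expand.grid(i = gi, j = gj, k = gk))
  pts <- voxel_to_world(img, ijk)
  nn <- nearest_neighbor(pts, lumen$vertices)
  keep <- nn$dist >= margin
  mask <- array(FALSE, d)
  mask[ijk[keep, , drop = FALSE] + 1L] <- TRUE
  mask
}

#' Write / read a velocity image as 4D NIfTI
#'
#' The three velocity components (cm/s) are stored along the fourth
#' dimension; the voxel-to-mm affine is stored as the sform.
#'
#' @param img a [velocity_image()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path` invisibly (write); a [velocity_image()] (read).
#' @export
write_velocity_nifti <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_velocity_nifti
#' @export
read_velocity_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = dim(aff))
  velocity_image(array(as.numeric(nii), dim = dim(nii)), affine = aff)
}
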
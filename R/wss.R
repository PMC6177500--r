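#' Sample wall-frame velocities along inward normals
#'
#' For every mesh vertex, velocity vectors are interpolated (trilinearly) at
#' three equidistant points along the inward normal — at the wall, at half
#' the local radius and at the local radius — and rotated into a local wall
#' frame that separates the wall-normal component from the two in-plane
#' components.  The primary in-plane axis is the projection of the velocity
#' at the innermost sample onto the tangent plane; the secondary axis is its
#' cross product with the normal.
#'
#' @param mesh lumen [vessel_mesh()] with inward normals.
#' @param img a [velocity_image()] co-registered with the mesh.
#' @param radius_map local radius per vertex, mm: a diameter
#'   [scalar_map()] (kind `"d"`, halved internally) or a plain numeric
#'   vector of radii.
#' @return an object of class `wall_samples`: list with `distances` (n x 3
#'   mm), `inplane` (two n x 3 matrices of in-plane velocity components,
#'   cm/s), `normal_component` (n x 3), `excluded` (vertex indices with any
#'   sample outside the image).
#' @export
sample_wall_velocities <- function(mesh, img, radius_map) {
  r <- if (inherits(radius_map, "scalar_map") && attr(radius_map, "kind") == "d")
    as.numeric(radius_map) / 2 else as.numeric(radius_map)
  n <- nrow(mesh$vertices)
  if (length(r) != n) stop("one radius per vertex required")
  dist3 <- cbind(0, r / 2, r)
  nrm <- mesh$inward_normals
  v_at <- function(d) sample_velocity(img, mesh$vertices + nrm * d)
  v0 <- v_at(dist3[, 1]); v1 <- v_at(dist3[, 2]); v2 <- v_at(dist3[, 3])
  excluded <- which(!stats::complete.cases(cbind(v0, v1, v2)) | !is.finite(r) | r <= 0)

  ## local frame per vertex: e1 = tangential projection of innermost sample
  tang <- v2 - nrm * rowSums(v2 * nrm)
  tn <- sqrt(rowSums(tang^2))
  weak <- !is.finite(tn) | tn < 1e-9
  tang[!is.finite(tang)] <- 0
  if (any(weak)) {
    ## degenerate (near-zero flow): any tangent axis will do
    ref <- matrix(rep(c(1, 0, 0), each = n), n, 3)
    alt <- matrix(rep(c(0, 1, 0), each = n), n, 3)
    use_alt <- abs(rowSums(ref * nrm)) > 0.9
    ref[use_alt, ] <- alt[use_alt, ]
    tang[weak, ] <- ref[weak, ] - nrm[weak, , drop = FALSE] *
      rowSums(ref[weak, , drop = FALSE] * nrm[weak, , drop = FALSE])
  }
  e1 <- unit_rows(tang)
  e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
              nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
              nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
  proj <- function(v) cbind(rowSums(v * e1), rowSums(v * e2), rowSums(v * nrm))
  p0 <- proj(v0); p1 <- proj(v1); p2 <- proj(v2)
  structure(list(
    distances = dist3,
    inplane_x = cbind(p0[, 1], p1[, 1], p2[, 1]),
    inplane_y = cbind(p0[, 2], p1[, 2], p2[, 2]),
    normal_component = cbind(p0[, 3], p1[, 3], p2[, 3]),
    excluded = excluded, n_vertices = n
  ), class = "wall_samples")
}

#' @export
print.wall_samples <- function(x, ...) {
  cat("wall_samples:", x$n_vertices, "vertices,", length(x$excluded),
      "excluded (outside field of view)\n")
  invisible(x)
}

#' Wall velocity gradient from three samples by smoothing-spline fit
#'
#' Fits, per in-plane component, a quadratic smoothing spline through the
#' three velocity-vs-distance samples and evaluates its derivative at the
#' wall (distance 0).  With three points and zero smoothing this is the
#' unique interpolating quadratic; a positive smoothing parameter penalises
#' curvature (ridge on the quadratic coefficient), shrinking the fit towards
#' the least-squares line.
#'
#' @param samples a [sample_wall_velocities()] result, or a list with
#'   `distances` (n x 3, mm, strictly increasing from 0) and `inplane_x` /
#'   `inplane_y` (n x 3, cm/s).
#' @param smoothing curvature penalty (>= 0; 0 interpolates).
#' @return list with `gradient` (n, s^-1: magnitude of the in-plane wall
#'   gradient vector), and per-component derivatives `dx`, `dy`
#'   ((cm/s)/mm).
#' @export
fit_wall_gradient <- function(samples, smoothing = 0) {
  d <- samples$distances
  if (is.null(dim(d))) d <- matrix(d, 1)
  if (ncol(d) != 3L) stop("exactly 3 samples per vertex required")
  if (any(d[, 1] != 0)) stop("first sample distance must be 0 (at the wall)")
  if (any(d[, 2] <= d[, 1] | d[, 3] <= d[, 2]))
    stop("coincident or non-increasing sample distances")
  deriv0 <- function(v) {
    ## quadratic v = a + b*d + c*d^2 with curvature penalty lam*c^2;
    ## derivative at the wall is b.  Closed form via 3x3 normal equations,
    ## vectorised over vertices.
    d1 <- d[, 2]; d2 <- d[, 3]
    X11 <- 3;            X12 <- d1 + d2;        X13 <- d1^2 + d2^2
    X22 <- d1^2 + d2^2;  X23 <- d1^3 + d2^3;    X33 <- d1^4 + d2^4 + smoothing
    y1 <- v[, 1] + v[, 2] + v[, 3]
    y2 <- v[, 2] * d1 + v[, 3] * d2
    y3 <- v[, 2] * d1^2 + v[, 3] * d2^2
    ## solve symmetric 3x3 [X11 X12 X13; X12 X22 X23; X13 X23 X33] b = y
    det3 <- X11 * (X22 * X33 - X23^2) - X12 * (X12 * X33 - X23 * X13) +
            X13 * (X12 * X23 - X22 * X13)
    num <- X11 * (y2 * X33 - X23 * y3) - y1 * (X12 * X33 - X23 * X13) +
           X13 * (X12 * y3 - y2 * X13)
    num / det3
  }
  dx <- deriv0(samples$inplane_x)
  dy <- deriv0(samples$inplane_y)
  grad <- sqrt(dx^2 + dy^2) * CMS_PER_MM_TO_PER_S
  if (length(samples$excluded)) grad[samples$excluded] <- NA_real_
  list(gradient = grad, dx = dx, dy = dy)
}

#' Wall shear stress map from a velocity volume
#'
#' WSS magnitude per vertex: dynamic viscosity times the in-plane wall
#' velocity-gradient magnitude obtained from the three-point
#' smoothing-spline fit along the inward normal
#' ([sample_wall_velocities()], [fit_wall_gradient()]).  Vertices whose
#' samples leave the image field of view carry `NA`, propagated through all
#' downstream statistics.
#'
#' @param mesh lumen [vessel_mesh()].
#' @param img a [velocity_image()] (background-corrected; a warning is
#'   issued if not flagged as corrected).
#' @param diameter_map local diameter [scalar_map()] (radius = D/2 sets the
#'   normal sampling length).
#' @param viscosity dynamic viscosity, Pa*s (default 3.2e-3, a common
#'   literature value for blood; recorded on the result).
#' @param smoothing spline smoothing parameter (see [fit_wall_gradient()]).
#' @return a [scalar_map()] of kind `"wss"` (Pa) with attributes
#'   `viscosity` and `n_excluded`.
#' @export
compute_wss_map <- function(mesh, img, diameter_map, viscosity = 3.2e-3,
                            smoothing = 0) {
  if (viscosity <= 0) stop("viscosity must be positive")
  if (!isTRUE(img$corrected))
    warning("velocity image is not flagged as background-corrected")
  samples <- sample_wall_velocities(mesh, img, diameter_map)
  g <- fit_wall_gradient(samples, smoothing = smoothing)
  wss <- viscosity * g$gradient
  out <- scalar_map(pmax(wss, 0), mesh, "wss")
  attr(out, "viscosity") <- viscosity
  attr(out, "n_excluded") <- length(samples$excluded)
  attr(out, "excluded") <- samples$excluded
  out
}
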
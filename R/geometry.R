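#' Wall thickness map: shortest distance from lumen to outer wall
#'
#' For each lumen vertex the wall thickness is the minimum Euclidean
#' distance to the outer-wall *surface* (point-to-triangle, not
#' point-to-vertex, so the result does not depend on the outer mesh
#' resolution).  An outer wall that intersects the lumen (nearest surface
#' point on the inward side of a vertex) is rejected.
#'
#' @param lumen lumen [vessel_mesh()].
#' @param outer outer-wall [vessel_mesh()], same mm frame.
#' @param k number of nearest outer-face candidates examined per vertex.
#' @param check reject non-positive / inward distances.
#' @return a [scalar_map()] of kind `"wt"` (mm) on the lumen vertices.
#' @export
compute_wall_thickness <- function(lumen, outer, k = 32L, check = TRUE) {
  cp <- closest_point_on_surface(lumen$vertices, outer, k = k)
  wt <- cp$dist
  if (check) {
    outward <- -lumen$inward_normals
    signed <- rowSums((cp$point - lumen$vertices) * outward)
    bad <- which(wt < 1e-6 | signed < -0.25 * wt)
    if (length(bad))
      stop("outer wall intersects or touches the lumen at ", length(bad),
           " vertices (first: ",
           paste(utils::head(bad, 5L), collapse = ", "), ")")
  }
  scalar_map(wt, lumen, "wt")
}

## Nearest point on a triangulated surface for each query point: the k
## nearest face centroids are screened, then exact point-to-triangle
## distances are taken over the candidates.
closest_point_on_surface <- function(points, mesh, k = 32L, chunk = 512L) {
  fc <- face_centroids(mesh)
  k <- min(k, nrow(fc))
  n <- nrow(points)
  va <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  vb <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  vc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  best_pt <- matrix(NA_real_, n, 3)
  best_d <- numeric(n)
  best_f <- integer(n)
  c2 <- rowSums(fc^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- points[s:e, , drop = FALSE]
    m <- nrow(q)
    d2 <- outer(rowSums(q^2), c2, "+") - 2 * tcrossprod(q, fc)
    cand <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
    qi <- rep(seq_len(m), each = k)
    fi <- as.integer(t(cand))
    cpt <- closest_point_on_triangle(q[qi, , drop = FALSE],
                                     va[fi, , drop = FALSE],
                                     vb[fi, , drop = FALSE],
                                     vc[fi, , drop = FALSE])
    dd <- rowSums((q[qi, , drop = FALSE] - cpt)^2)
    dm <- matrix(dd, nrow = m, byrow = TRUE)
    jbest <- max.col(-dm, ties.method = "first")
    sel <- (seq_len(m) - 1L) * k + jbest
    best_pt[s:e, ] <- cpt[sel, , drop = FALSE]
    best_d[s:e] <- sqrt(dm[cbind(seq_len(m), jbest)])
    best_f[s:e] <- fi[sel]
  }
  list(point = best_pt, dist = best_d, face = best_f)
}

## Barycentric coordinates of points known to lie on the given faces.
barycentric_on_faces <- function(mesh, points, faces_idx) {
  a <- mesh$vertices[mesh$faces[faces_idx, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[faces_idx, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[faces_idx, 3], , drop = FALSE]
  v0 <- b - a; v1 <- c_ - a; v2 <- points - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01^2
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  v[!is.finite(v)] <- 0; w[!is.finite(w)] <- 0
  v <- pmin(pmax(v, 0), 1); w <- pmin(pmax(w, 0), 1 - v)
  cbind(1 - v - w, v, w)
}

#' Lumen centerline by cross-section centroid chaining
#'
#' Marches a cutting plane through the lumen from the CCA inlet cap: at each
#' step the vertices in a thin slab perpendicular to the current direction
#' are collected, their centroid becomes the next centerline point and their
#' mean in-plane distance the local inscribed radius.  For a bifurcation the
#' CCA is traced to the apex and each daughter branch is traced back from
#' its outlet cap, so both returned paths share the CCA segment (one
#' polyline per outlet).  Caps are the clean boundary component farthest
#' from the apex within each branch, which is robust to ragged junction
#' seams.
#'
#' @param lumen a [vessel_mesh()] with at least two open boundary loops.
#' @param step slab spacing, mm (default 1.5x mean edge length).
#' @return an object of class `centerline`: a list of paths, each with
#'   `points` (m x 3, mm), `radius` (m, mm) and `branch`.
#' @export
compute_centerline <- function(lumen, step = NULL) {
  if (is.null(step)) step <- 1.5 * mean_edge_length(lumen)
  comps <- boundary_components(lumen)
  caps <- Filter(function(cc) cc$clean, comps)
  if (length(caps) < 2L)
    stop("fewer than 2 open boundary loops: cannot define centerline endpoints")
  apex <- lumen$apex
  has_branches <- !is.null(lumen$branch) &&
    all(c("cca", "ica", "eca") %in% lumen$branch)

  if (!has_branches) {
    ## single tube: trace between the two caps farthest apart
    if (length(caps) > 2L) {
      ctrs <- t(vapply(caps, function(cc) cc$centroid, numeric(3)))
      dd <- as.matrix(stats::dist(ctrs))
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      caps <- caps[ij]
    }
    path <- trace_branch(lumen$vertices, caps[[1]], caps[[2]]$centroid,
                         target_radius = caps[[2]]$radius, step = step)
    return(structure(list(paths = list(c(path, list(branch = "cca")))),
                     class = "centerline"))
  }

  if (is.null(apex)) apex <- colMeans(lumen$vertices[lumen$branch == "bifurcation", , drop = FALSE])
  pick_cap <- function(branchname) {
    cand <- Filter(function(cc) identical(cc$branch, branchname), caps)
    if (!length(cand))
      stop("no clean boundary cap found for branch ", branchname)
    d <- vapply(cand, function(cc) sqrt(sum((cc$centroid - apex)^2)), numeric(1))
    cand[[which.max(d)]]
  }
  vsel <- function(labels) lumen$vertices[lumen$branch %in% labels, , drop = FALSE]
  cca_cap <- pick_cap("cca")
  cca_path <- trace_branch(vsel(c("cca", "bifurcation")), cca_cap, apex,
                           target_radius = NULL, step = step)
  paths <- lapply(c("ica", "eca"), function(br) {
    cap <- pick_cap(br)
    p <- trace_branch(vsel(c(br, "bifurcation")), cap, apex,
                      target_radius = NULL, step = step)
    list(points = rbind(cca_path$points, p$points[rev(seq_len(nrow(p$points))), ]),
         radius = c(cca_path$radius, rev(p$radius)),
         branch = br)
  })
  structure(list(paths = paths), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("centerline:", length(x$paths), "path(s)\n")
  for (p in x$paths)
    cat(sprintf("  %s: %d points, radius %.2f .. %.2f mm\n", p$branch,
                nrow(p$points), min(p$radius), max(p$radius)))
  invisible(x)
}

## March slabs from a cap towards a target point.  verts: candidate surface
## vertices; cap: boundary component (start); target: stopping point.
trace_branch <- function(verts, cap, target, target_radius = NULL, step) {
  ctr <- cap$centroid
  dir <- target - ctr
  dir <- dir / sqrt(sum(dir^2))
  ## refine initial direction: cap plane normal via PCA of the cap ring
  ## (smallest principal axis), signed towards the target
  cap_pts <- verts
  pc <- tryCatch({
    ringpts <- cap_pts[dist_to_polyline(cap_pts, matrix(ctr, 1)) <
                         1.6 * cap$radius, , drop = FALSE]
    ev <- eigen(stats::cov(ringpts), symmetric = TRUE)$vectors[, 3]
    if (sum(ev * dir) < 0) ev <- -ev
    ev
  }, error = function(e) dir)
  dir <- pc
  points <- matrix(ctr, 1)
  radii <- cap$radius
  guard <- 3 * cap$radius
  slice <- function(cand, d) {
    rel <- sweep(verts, 2, cand)
    ax <- as.numeric(rel %*% d)
    perp2 <- pmax(rowSums(rel^2) - ax^2, 0)
    ring <- abs(ax) <= step / 2 & perp2 <= guard^2
    if (sum(ring) < 4L) ring <- abs(ax) <= step & perp2 <= guard^2
    if (sum(ring) < 4L) return(NULL)
    ## in-plane centroid: keep the axial coordinate of the requested plane
    inplane <- rel[ring, , drop = FALSE] - outer(ax[ring], d)
    list(centre = cand + colMeans(inplane), radius = mean(sqrt(perp2[ring])))
  }
  for (it in seq_len(1000L)) {
    sl <- slice(ctr + step * dir, dir)
    if (is.null(sl)) break
    ## refine once with the re-centred slab (stabilises curved tubes where
    ## the slab straddles mesh rings unevenly)
    sl2 <- slice(sl$centre, dir)
    if (!is.null(sl2)) sl <- sl2
    newdir <- sl$centre - ctr
    nn <- sqrt(sum(newdir^2))
    if (nn < 1e-9) break
    dir <- unit_rows(matrix(0.5 * dir + 0.5 * newdir / nn, 1))[1, ]
    ctr <- sl$centre
    points <- rbind(points, ctr)
    radii <- c(radii, sl$radius)
    guard <- 3 * sl$radius
    if (sqrt(sum((ctr - target)^2)) < 1.5 * step) break
  }
  points <- rbind(points, target)
  radii <- c(radii, if (is.null(target_radius)) radii[length(radii)] else target_radius)
  list(points = points, radius = radii)
}

#' Diameter map from the centerline
#'
#' Per lumen vertex, the local vessel diameter is twice the distance from
#' the vertex to the nearest point of the centerline (minimum over all
#' branch polylines; at the bifurcation apex the nearest branch wins, ties
#' broken by branch order).
#'
#' @param lumen lumen [vessel_mesh()].
#' @param cl a [compute_centerline()] result.
#' @return a [scalar_map()] of kind `"d"` (mm) with a `branch_assignment`
#'   attribute giving the winning branch per vertex.
#' @export
compute_diameter_map <- function(lumen, cl) {
  if (!length(cl$paths)) stop("empty centerline")
  d_by_path <- vapply(cl$paths,
                      function(p) dist_to_polyline(lumen$vertices, p$points),
                      numeric(nrow(lumen$vertices)))
  d_by_path <- matrix(d_by_path, nrow = nrow(lumen$vertices))
  jmin <- max.col(-d_by_path, ties.method = "first")
  dmin <- d_by_path[cbind(seq_len(nrow(d_by_path)), jmin)]
  out <- scalar_map(2 * dmin, lumen, "d")
  attr(out, "branch_assignment") <-
    vapply(cl$paths, function(p) p$branch, character(1))[jmin]
  out
}
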
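#' Triangulated vessel wall surface
#'
#' A `vessel_mesh` holds the triangulated surface all per-vertex maps live
#' on: vertex coordinates in millimetres (world frame shared with the
#' velocity image affine), triangular faces, unit inward normals, and a
#' per-vertex branch label (`"cca"`, `"ica"`, `"eca"` or `"bifurcation"`).
#'
#' @param vertices numeric n x 3 matrix, mm.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param inward_normals optional n x 3 matrix of unit inward normals.  If
#'   omitted they are computed from the faces and oriented towards the local
#'   interior (centroid heuristic).
#' @param branch optional character vector of per-vertex branch labels.
#' @param apex optional length-3 bifurcation apex landmark, mm.
#' @param branch_geometry optional parametric branch description attached by
#'   the synthetic generator (used by [generate_velocity_image()]).
#' @return an object of class `vessel_mesh`.
#' @export
vessel_mesh <- function(vertices, faces, inward_normals = NULL, branch = NULL,
                        apex = NULL, branch_geometry = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("faces reference vertices outside 1..n")
  if (is.null(inward_normals)) {
    inward_normals <- -oriented_vertex_normals(vertices, faces)
  } else {
    inward_normals <- unit_rows(as.matrix(inward_normals))
  }
  if (nrow(inward_normals) != nrow(vertices))
    stop("one inward normal per vertex required")
  if (!is.null(branch) && length(branch) != nrow(vertices))
    stop("one branch label per vertex required")
  structure(list(
    vertices = vertices, faces = faces,
    inward_normals = inward_normals,
    branch = branch, apex = apex,
    branch_geometry = branch_geometry
  ), class = "vessel_mesh")
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat("vessel_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (!is.null(x$branch)) {
    tb <- table(x$branch)
    cat("  branches:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  mean edge length %.3f mm\n", mean_edge_length(x)))
  invisible(x)
}

## Area-weighted vertex normals oriented outwards: each vertex normal is
## flipped, if needed, to point away from the centroid of its surface
## neighbourhood (works for tubular surfaces; the generator supplies exact
## normals so this heuristic only serves meshes read from disk).
oriented_vertex_normals <- function(vertices, faces) {
  fa <- vertices[faces[, 1], , drop = FALSE]
  fb <- vertices[faces[, 2], , drop = FALSE]
  fc <- vertices[faces[, 3], , drop = FALSE]
  e1 <- fb - fa; e2 <- fc - fa
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ## accumulate face normals onto their vertices
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- faces[, k]
    for (d in 1:3) {
      acc <- rowsum(fn[, d], idx)
      vn[as.integer(rownames(acc)), d] <- vn[as.integer(rownames(acc)), d] + acc[, 1]
    }
  }
  vn <- unit_rows(vn)
  ## orient: normal should point away from local interior
  ctr <- colMeans(vertices)
  toward_ctr <- unit_rows(sweep(vertices, 2, ctr, "-"))
  flip <- rowSums(vn * toward_ctr) < 0
  vn[flip, ] <- -vn[flip, ]
  vn
}

#' Mean edge length of a mesh
#' @param mesh a [vessel_mesh()].
#' @return mean length over unique edges, mm.
#' @export
mean_edge_length <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Rigidly transform a mesh
#'
#' @param mesh a [vessel_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @return the transformed mesh (normals rotated, apex carried along).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  n <- mesh$inward_normals %*% t(rotation)
  apex <- if (!is.null(mesh$apex)) as.numeric(rotation %*% mesh$apex) + translation
  bg <- mesh$branch_geometry
  if (!is.null(bg)) {
    bg <- lapply(bg, function(b) {
      b$origin <- as.numeric(rotation %*% b$origin) + translation
      b$dir <- as.numeric(rotation %*% b$dir)
      b
    })
  }
  vessel_mesh(v, mesh$faces, inward_normals = n, branch = mesh$branch,
              apex = apex, branch_geometry = bg)
}

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

## Boundary edge components.  Returns a list of components, each a list with
## vertex indices, centroid, mean in-plane radius, whether the component is a
## clean loop (every vertex on exactly two boundary edges) and its dominant
## branch label.
boundary_components <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (!length(bkey)) return(list())
  bm <- do.call(rbind, strsplit(bkey, " ", fixed = TRUE))
  be <- cbind(as.integer(bm[, 1]), as.integer(bm[, 2]))
  ## union-find over boundary vertices
  verts <- sort(unique(as.integer(be)))
  parent <- seq_along(verts)
  vid <- match(be, verts); dim(vid) <- dim(be)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(vid))) {
    a <- find(vid[r, 1]); b <- find(vid[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(verts), find, integer(1))
  comps <- split(verts, roots)
  deg <- table(factor(as.integer(be), levels = verts))
  lapply(unname(comps), function(vs) {
    pts <- mesh$vertices[vs, , drop = FALSE]
    ctr <- colMeans(pts)
    rad <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
    clean <- all(deg[as.character(vs)] == 2L)
    lab <- if (!is.null(mesh$branch)) names(sort(table(mesh$branch[vs]), decreasing = TRUE))[1]
    list(vertices = vs, centroid = ctr, radius = rad, clean = clean, branch = lab)
  })
}
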
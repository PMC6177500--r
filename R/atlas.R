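#' Build a shared geometry (cohort atlas) from lumen meshes
#'
#' The atlas mesh is the first subject's mesh; every subject is rigidly
#' aligned to it (translation of the bifurcation apex, rotation aligning
#' the CCA and ICA branch directions, then iterative-closest-point
#' refinement) and each atlas vertex is matched to the closest point on
#' the aligned subject's surface (barycentric interpolation over the
#' nearest triangle, weights summing to 1).  Matches farther than
#' `gate_factor` times the atlas mean edge length are marked missing for
#' that subject.
#'
#' @param lumens list of lumen [vessel_mesh()] objects (>= 2).  For
#'   bifurcation alignment each needs branch labels and an apex landmark;
#'   unlabelled meshes fall back to centroid + ICP alignment.
#' @param gate_factor correspondence distance gate, in atlas mean edge
#'   lengths.
#' @param icp_iterations maximum ICP refinement iterations.
#' @param coverage_warn warn when a subject covers less than this fraction
#'   of atlas vertices.
#' @return an object of class `shared_geometry`: `atlas` (mesh),
#'   `correspondence` (per subject: atlas-vertices x 3 source vertex index
#'   and weight matrices, `NA` rows where gated), `coverage` (fraction per
#'   subject), `alignment_rms` (per subject), `transforms`.
#' @export
build_shared_geometry <- function(lumens, gate_factor = 2,
                                  icp_iterations = 10L,
                                  coverage_warn = 0.8) {
  if (length(lumens) < 2L) stop("need at least 2 meshes to build a shared geometry")
  atlas <- lumens[[1L]]
  gate <- gate_factor * mean_edge_length(atlas)
  n_sub <- length(lumens)
  nv <- nrow(atlas$vertices)
  corr <- vector("list", n_sub)
  cover <- numeric(n_sub)
  rms <- numeric(n_sub)
  transforms <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    tr <- align_to_atlas(lumens[[i]], atlas, icp_iterations = icp_iterations)
    transforms[[i]] <- tr
    av <- sweep(lumens[[i]]$vertices %*% t(tr$rotation), 2, tr$translation, "+")
    amesh <- lumens[[i]]
    amesh$vertices <- av
    cp <- closest_point_on_surface(atlas$vertices, amesh)
    hit <- cp$dist <= gate
    idx <- matrix(NA_integer_, nv, 3)
    w <- matrix(NA_real_, nv, 3)
    if (any(hit)) {
      idx[hit, ] <- amesh$faces[cp$face[hit], , drop = FALSE]
      w[hit, ] <- barycentric_on_faces(amesh, cp$point[hit, , drop = FALSE],
                                       cp$face[hit])
    }
    corr[[i]] <- list(index = idx, weight = w)
    cover[i] <- mean(hit)
    rms[i] <- sqrt(mean(cp$dist[hit]^2))
    if (cover[i] < coverage_warn)
      warning(sprintf("subject %d covers only %.0f%% of atlas vertices", i,
                      100 * cover[i]))
  }
  structure(list(atlas = atlas, correspondence = corr, coverage = cover,
                 alignment_rms = rms, transforms = transforms,
                 gate = gate, n_subjects = n_sub, n_atlas_vertices = nv),
            class = "shared_geometry")
}

#' @export
print.shared_geometry <- function(x, ...) {
  cat("shared_geometry:", x$n_subjects, "subjects on",
      nrow(x$atlas$vertices), "atlas vertices\n")
  cat(sprintf("  coverage %.0f%% .. %.0f%%, alignment RMS %.2f .. %.2f mm\n",
              100 * min(x$coverage), 100 * max(x$coverage),
              min(x$alignment_rms), max(x$alignment_rms)))
  invisible(x)
}

## Rigid alignment of a subject mesh onto the atlas mesh: landmark/branch
## initialisation followed by trimmed ICP (Kabsch updates on the best 80%
## of nearest-neighbour pairs, subsampled for speed).
align_to_atlas <- function(mesh, atlas, icp_iterations = 10L,
                           subsample = 800L, trim = 0.8) {
  branch_dir <- function(m, lab) {
    sel <- !is.null(m$branch) & m$branch == lab
    if (!any(sel)) return(NULL)
    pts <- m$vertices[m$branch == lab, , drop = FALSE]
    if (nrow(pts) < 8L) return(NULL)
    ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
    ## orient away from the apex (or mesh centroid)
    ref <- if (!is.null(m$apex)) m$apex else colMeans(m$vertices)
    if (sum(ev * (colMeans(pts) - ref)) < 0) ev <- -ev
    ev
  }
  R0 <- diag(3); t0 <- c(0, 0, 0)
  a_cca <- branch_dir(atlas, "cca"); s_cca <- branch_dir(mesh, "cca")
  a_ica <- branch_dir(atlas, "ica"); s_ica <- branch_dir(mesh, "ica")
  if (!is.null(a_cca) && !is.null(s_cca) && !is.null(a_ica) && !is.null(s_ica) &&
      !is.null(mesh$apex) && !is.null(atlas$apex)) {
    frame <- function(u, v) {
      e1 <- u / sqrt(sum(u^2))
      e2 <- v - sum(v * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
      e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      cbind(e1, e2, e3)
    }
    R0 <- frame(a_cca, a_ica) %*% t(frame(s_cca, s_ica))
    t0 <- atlas$apex - as.numeric(R0 %*% mesh$apex)
  } else {
    t0 <- colMeans(atlas$vertices) - colMeans(mesh$vertices)
  }
  R <- R0; t_ <- t0
  src <- mesh$vertices
  if (nrow(src) > subsample) {
    keep <- round(seq(1L, nrow(src), length.out = subsample))
    src <- src[keep, , drop = FALSE]
  }
  prev <- Inf
  for (it in seq_len(icp_iterations)) {
    cur <- sweep(src %*% t(R), 2, t_, "+")
    nn <- nearest_neighbor(cur, atlas$vertices)
    ord <- order(nn$dist)
    keep <- ord[seq_len(max(3L, floor(trim * length(ord))))]
    fit <- kabsch(src[keep, , drop = FALSE],
                  atlas$vertices[nn$index[keep], , drop = FALSE])
    R <- fit$rotation; t_ <- fit$translation
    err <- sqrt(mean(nn$dist[keep]^2))
    if (abs(prev - err) < 1e-6) break
    prev <- err
  }
  list(rotation = R, translation = t_, rms = prev)
}

#' Resample a subject map onto the shared geometry
#'
#' Atlas-vertex values are the barycentric interpolation of the
#' source-subject values over the corresponding triangle (weights sum to
#' 1, so constants are preserved); atlas vertices gated out during
#' correspondence, or touching missing source values, are `NA`.
#'
#' @param map a [scalar_map()] (or plain numeric vector) on the subject's
#'   mesh.
#' @param shared a [build_shared_geometry()] result.
#' @param subject_index which subject the map belongs to.
#' @return numeric vector of atlas-vertex values.
#' @export
map_to_shared <- function(map, shared, subject_index) {
  if (subject_index < 1L || subject_index > shared$n_subjects)
    stop("subject ", subject_index, " is not part of the shared geometry")
  cr <- shared$correspondence[[subject_index]]
  vals <- as.numeric(map)
  nv <- nrow(cr$index)
  out <- rep(NA_real_, nv)
  hit <- !is.na(cr$index[, 1])
  v1 <- vals[cr$index[hit, 1]]
  v2 <- vals[cr$index[hit, 2]]
  v3 <- vals[cr$index[hit, 3]]
  out[hit] <- cr$weight[hit, 1] * v1 + cr$weight[hit, 2] * v2 +
              cr$weight[hit, 3] * v3
  out
}

#' Cohort map matrices on the shared geometry
#'
#' Stacks each subject's WT, WSS and diameter maps (resampled via
#' [map_to_shared()]) into subjects x atlas-vertices matrices.
#'
#' @param shared a [build_shared_geometry()] result.
#' @param maps list (length = subjects) of named lists of maps; names
#'   become the quantity names (e.g. `wt`, `wss`, `d`).
#' @return an object of class `cohort_map_set` with `shared`, `matrices`
#'   (named list) and `complete_vertices` (atlas vertices covered by every
#'   subject for every quantity — the default analysis set downstream).
#' @export
build_cohort_maps <- function(shared, maps) {
  if (length(maps) != shared$n_subjects)
    stop("need one map list per subject")
  qnames <- names(maps[[1L]])
  if (is.null(qnames)) stop("maps must be named lists (e.g. wt, wss, d)")
  nv <- shared$n_atlas_vertices
  matrices <- lapply(qnames, function(q) {
    t(vapply(seq_along(maps), function(i)
      map_to_shared(maps[[i]][[q]], shared, i), numeric(nv)))
  })
  names(matrices) <- qnames
  complete <- Reduce(`&`, lapply(matrices, function(m) colSums(is.na(m)) == 0L))
  structure(list(shared = shared, matrices = matrices,
                 complete_vertices = complete),
            class = "cohort_map_set")
}

#' Cohort map set from plain matrices
#'
#' Builds a [build_cohort_maps()]-compatible object directly from
#' subjects x vertices matrices (no shared-geometry step), e.g. for
#' simulation studies on synthetic map matrices.
#'
#' @param matrices named list of subjects x vertices matrices with
#'   identical dimensions (`NA` = missing).
#' @return a `cohort_map_set`.
#' @export
as_cohort_map_set <- function(matrices) {
  if (is.null(names(matrices))) stop("matrices must be a named list")
  d <- dim(matrices[[1L]])
  if (!all(vapply(matrices, function(m) identical(dim(m), d), logical(1))))
    stop("all matrices must share the same dimensions")
  complete <- Reduce(`&`, lapply(matrices, function(m) colSums(is.na(m)) == 0L))
  structure(list(shared = NULL, matrices = matrices,
                 complete_vertices = complete),
            class = "cohort_map_set")
}

#' @export
print.cohort_map_set <- function(x, ...) {
  cat("cohort_map_set:", nrow(x$matrices[[1]]), "subjects x",
      ncol(x$matrices[[1]]), "atlas vertices\n")
  cat("  quantities:", paste(names(x$matrices), collapse = ", "),
      sprintf("| complete vertices: %d (%.0f%%)\n", sum(x$complete_vertices),
              100 * mean(x$complete_vertices)))
  invisible(x)
}

#' Serialize a shared geometry or cohort map set to disk
#'
#' The atlas mesh is written as ASCII PLY and the correspondence tables
#' (per-subject source-vertex indices and barycentric weights), coverage,
#' alignment summaries and gate as JSON.  Cohort map matrices are written
#' one CSV per quantity (subjects x vertices) plus a JSON manifest; this
#' plain-text container is the package's documented exchange format.
#'
#' @param shared a [build_shared_geometry()] result.
#' @param set a [build_cohort_maps()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly (writers); the reconstructed object (readers).
#' @export
write_shared_geometry <- function(shared, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(shared$atlas, file.path(dir, "atlas.ply"))
  meta <- list(
    n_subjects = shared$n_subjects,
    n_atlas_vertices = shared$n_atlas_vertices,
    gate = shared$gate, coverage = shared$coverage,
    alignment_rms = shared$alignment_rms,
    transforms = lapply(shared$transforms, function(tr)
      list(rotation = as.numeric(tr$rotation), translation = tr$translation)),
    correspondence = lapply(shared$correspondence, function(cr)
      list(index = as.integer(t(cr$index)), weight = as.numeric(t(cr$weight))))
  )
  jsonlite::write_json(meta, file.path(dir, "shared_geometry.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_shared_geometry
#' @export
read_shared_geometry <- function(dir) {
  atlas <- read_mesh(file.path(dir, "atlas.ply"))
  meta <- jsonlite::read_json(file.path(dir, "shared_geometry.json"),
                              simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
  nv <- meta$n_atlas_vertices
  corr <- lapply(meta$correspondence, function(cr)
    list(index = matrix(as.integer(num(cr$index)), nv, 3, byrow = TRUE),
         weight = matrix(num(cr$weight), nv, 3, byrow = TRUE)))
  structure(list(atlas = atlas, correspondence = corr,
                 coverage = num(meta$coverage),
                 alignment_rms = num(meta$alignment_rms),
                 transforms = lapply(meta$transforms, function(tr)
                   list(rotation = matrix(num(tr$rotation), 3, 3),
                        translation = num(tr$translation))),
                 gate = meta$gate, n_subjects = meta$n_subjects,
                 n_atlas_vertices = nv),
            class = "shared_geometry")
}

#' @rdname write_shared_geometry
#' @export
write_cohort_maps <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (q in names(set$matrices))
    utils::write.csv(set$matrices[[q]],
                     file.path(dir, paste0("maps_", q, ".csv")),
                     row.names = FALSE, na = "")
  jsonlite::write_json(list(quantities = names(set$matrices),
                            n_subjects = nrow(set$matrices[[1]]),
                            n_vertices = ncol(set$matrices[[1]])),
                       file.path(dir, "cohort_maps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_shared_geometry
#' @export
read_cohort_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort_maps.json"),
                              simplifyVector = TRUE)
  mats <- lapply(meta$quantities, function(q)
    unname(as.matrix(utils::read.csv(file.path(dir, paste0("maps_", q, ".csv"))))))
  names(mats) <- meta$quantities
  as_cohort_map_set(mats)
}

#' Average maps over a subject multiset on the shared geometry
#'
#' Vertex-wise arithmetic mean over the (possibly repeated) subjects of the
#' multiset — repetition is what the bootstrap draws with replacement.
#' Missing entries are dropped per vertex (available-case averaging); a
#' vertex with no valid entry is `NA`.
#'
#' @param set a [build_cohort_maps()] result.
#' @param subject_multiset integer indices with repetition.
#' @param quantity which matrix to average (e.g. `"wt"`).
#' @return numeric atlas-vertex vector with attribute `n_contributing`.
#' @export
average_maps <- function(set, subject_multiset, quantity) {
  m <- set$matrices[[quantity]]
  if (is.null(m)) stop("unknown quantity: ", quantity)
  subject_multiset <- as.integer(subject_multiset)
  if (!length(subject_multiset)) stop("empty subject multiset")
  if (any(subject_multiset < 1L | subject_multiset > nrow(m)))
    stop("subject index out of range")
  sub <- m[subject_multiset, , drop = FALSE]
  n_ok <- colSums(!is.na(sub))
  out <- colSums(sub, na.rm = TRUE) / n_ok
  out[n_ok == 0L] <- NA_real_
  attr(out, "n_contributing") <- n_ok
  out
}
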
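#' Read a surface mesh from PLY or OBJ
#'
#' Supports ASCII PLY (with optional per-vertex normal and integer branch
#' label properties as written by [write_mesh()]) and Wavefront OBJ
#' (`v`/`vn`/`f` records).  The format is chosen from the file extension.
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return a [vessel_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stop("unsupported mesh format: .", ext)
  )
}

#' Write a surface mesh to PLY or OBJ
#'
#' PLY output is ASCII with per-vertex `x y z nx ny nz` (outward normals,
#' following the usual PLY convention) and an integer `branch` property
#' (0 = cca, 1 = ica, 2 = eca, 3 = bifurcation) when branch labels are
#' present.  OBJ output carries vertices, outward normals and faces only.
#'
#' @param mesh a [vessel_mesh()].
#' @param path destination path ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: .", ext)
  )
  invisible(path)
}

BRANCH_CODES <- c(cca = 0L, ica = 1L, eca = 2L, bifurcation = 3L)

write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  has_branch <- !is.null(mesh$branch)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "ply", "format ascii 1.0", "comment wallmap vessel surface",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    if (has_branch) "property int branch",
    paste("element face", m),
    "property list uchar int vertex_indices",
    "end_header")
  writeLines(hdr, con)
  outward <- -mesh$inward_normals
  vt <- cbind(mesh$vertices, outward)
  lines <- apply(format(vt, digits = 9, scientific = FALSE, trim = TRUE), 1, paste, collapse = " ")
  if (has_branch) lines <- paste(lines, BRANCH_CODES[mesh$branch])
  writeLines(lines, con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("not an ASCII PLY file (no end_header): ", path)
  hdr <- trimws(lines[seq_len(end)])
  if (!identical(hdr[1], "ply") || !any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  ## vertex property names in declared order
  vstart <- grep("^element vertex ", hdr)
  fstart <- grep("^element face ", hdr)
  props <- sub("^property \\S+ ", "", hdr[(vstart + 1):(fstart - 1)])
  props <- props[!grepl("^list", hdr[(vstart + 1):(fstart - 1)])]
  vdat <- utils::read.table(text = lines[(end + 1):(end + nv)])
  names(vdat) <- props[seq_len(ncol(vdat))]
  fdat <- utils::read.table(text = lines[(end + nv + 1):(end + nv + nf)])
  if (any(fdat[, 1] != 3L)) stop("non-triangular face in PLY: ", path)
  faces <- as.matrix(fdat[, 2:4]) + 1L
  normals <- if (all(c("nx", "ny", "nz") %in% names(vdat)))
    -as.matrix(vdat[, c("nx", "ny", "nz")])  # file stores outward normals
  branch <- if ("branch" %in% names(vdat))
    names(BRANCH_CODES)[match(vdat$branch, BRANCH_CODES)]
  vessel_mesh(as.matrix(vdat[, c("x", "y", "z")]), faces,
              inward_normals = normals, branch = branch)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wallmap vessel surface", con)
  v <- mesh$vertices
  writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
  nrm <- -mesh$inward_normals
  writeLines(paste("vn", nrm[, 1], nrm[, 2], nrm[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     f[, 1], f[, 1], f[, 2], f[, 2], f[, 3], f[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  nl <- grep("^vn ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  normals <- if (length(nl))
    -do.call(rbind, lapply(strsplit(nl, "\\s+"), function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  vessel_mesh(verts, faces, inward_normals = normals)
}
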
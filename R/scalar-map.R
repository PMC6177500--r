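MAP_UNITS <- c(wt = "mm", wss = "Pa", d = "mm", residual = "mm",
               predicted_wt = "mm", other = "")

#' Per-vertex scalar map bound to a mesh
#'
#' A `scalar_map` is one scalar per mesh vertex: wall thickness (`"wt"`,
#' mm), wall shear stress magnitude (`"wss"`, Pa), lumen diameter (`"d"`,
#' mm), a regression residual or a predicted wall thickness.  Missing
#' values (`NA`) mark vertices excluded upstream (e.g. velocity samples
#' outside the field of view) and are propagated through all downstream
#' statistics.
#'
#' @param values numeric vector, one value per mesh vertex (`NA` allowed).
#' @param mesh the [vessel_mesh()] the map lives on.
#' @param kind one of `"wt"`, `"wss"`, `"d"`, `"residual"`,
#'   `"predicted_wt"`, `"other"`.
#' @param check validate positivity constraints (WT and D strictly positive,
#'   WSS non-negative) on non-missing values.
#' @return an object of class `scalar_map` (a numeric vector with
#'   attributes).
#' @export
scalar_map <- function(values, mesh, kind = c("wt", "wss", "d", "residual",
                                              "predicted_wt", "other"),
                       check = TRUE) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!inherits(mesh, "vessel_mesh")) stop("mesh must be a vessel_mesh")
  if (length(values) != nrow(mesh$vertices))
    stop("map length ", length(values), " does not match vertex count ",
         nrow(mesh$vertices))
  ok <- !is.na(values)
  if (check) {
    if (kind %in% c("wt", "d") && any(values[ok] <= 0))
      stop(sum(values[ok] <= 0), " non-positive ", toupper(kind),
           " values violate the positivity invariant")
    if (kind == "wss" && any(values[ok] < 0))
      stop("negative WSS magnitude values")
  }
  structure(values, class = "scalar_map", kind = kind,
            units = MAP_UNITS[[kind]], n_vertices = nrow(mesh$vertices))
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- as.numeric(x)
  cat(sprintf("scalar_map [%s, %s]: %d vertices, %d missing\n",
              attr(x, "kind"), attr(x, "units"), length(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), mean(v, na.rm = TRUE)))
  invisible(x)
}

map_values <- function(x) as.numeric(x)

#' Write / read a scalar map as sidecar CSV
#'
#' Two-column CSV `vertex_id,value` with 1-based vertex ids; missing values
#' written as empty fields.
#'
#' @param map a [scalar_map()].
#' @param path CSV destination.
#' @return `path` invisibly (write); numeric vector of values (read).
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(vertex_id = seq_along(map), value = as.numeric(map))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path)
  df$value[order(df$vertex_id)]
}
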
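#' @keywords internal
"_PACKAGE"

## Centralised unit conversions.
## Velocities are handled in cm/s, distances in mm, WSS in Pa throughout.
## A velocity gradient of 1 (cm/s)/mm equals 10 s^-1.
CMS_PER_MM_TO_PER_S <- 10

#' Derive reproducible child seeds from one master seed
#'
#' All stochastic stages draw their own seed from the master seed through
#' this one function, so that a single integer determines every random
#' stream in a run (stream splitting).  Child seeds are drawn without
#' replacement from the 31-bit integer range.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds required.
#' @return integer vector of length `n`.
#' @export
rng_child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(
    x * x * C + c_,     x * y * C - z * s_, x * z * C + y * s_,
    y * x * C + z * s_, y * y * C + c_,     y * z * C - x * s_,
    z * x * C - y * s_, z * y * C + x * s_, z * z * C + c_
  ), 3, 3, byrow = TRUE)
}

## Rotation mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    return(rotation_about_axis(ax, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

## Least-squares rigid alignment (Kabsch): returns R, t with Q ~ P %*% t(R) + t
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cq - as.numeric(R %*% cp)
  list(rotation = R, translation = t_)
}

## Brute-force nearest neighbour of each query row in ref rows, chunked to
## bound memory.  Returns index into ref and the distance.
nearest_neighbor <- function(query, ref, chunk = 1024L) {
  n <- nrow(query)
  idx <- integer(n); dst <- numeric(n)
  r2 <- rowSums(ref^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), r2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, dist = dst)
}

## Closest point on each triangle (a,b,c) to each point p, all row-matched
## n x 3 matrices.  Vectorised version of the standard barycentric
## region-classification algorithm (Ericson).
closest_point_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)

  out <- matrix(NA_real_, nrow(p), 3)
  done <- rep(FALSE, nrow(p))

  set_rows <- function(mask, val) {
    m <- mask & !done
    if (any(m)) {
      out[m, ] <<- val[m, , drop = FALSE]
      done[m] <<- TRUE
    }
  }

  set_rows(d1 <= 0 & d2 <= 0, a)                                   # vertex A
  set_rows(d3 >= 0 & d4 <= d3, b)                                  # vertex B
  vc <- d1 * d4 - d3 * d2
  v_ab <- d1 / (d1 - d3)
  set_rows(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * ifelse(is.finite(v_ab), v_ab, 0))  # edge AB
  set_rows(d6 >= 0 & d5 <= d6, c)                                  # vertex C
  vb <- d5 * d2 - d1 * d6
  w_ac <- d2 / (d2 - d6)
  set_rows(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * ifelse(is.finite(w_ac), w_ac, 0))  # edge AC
  va <- d3 * d6 - d5 * d4
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_rows(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           b + (c - b) * ifelse(is.finite(w_bc), w_bc, 0))         # edge BC
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  interior <- a + ab * ifelse(is.finite(v), v, 0) + ac * ifelse(is.finite(w), w, 0)
  set_rows(rep(TRUE, nrow(p)), interior)                           # face interior
  out
}

## Distance from points (n x 3) to a polyline given as an ordered point
## matrix (m x 3); distance to the union of its segments.
dist_to_polyline <- function(points, line) {
  m <- nrow(line)
  if (m == 1L) {
    d <- sweep(points, 2, line[1, ])
    return(sqrt(rowSums(d^2)))
  }
  best <- rep(Inf, nrow(points))
  for (i in seq_len(m - 1L)) {
    a <- line[i, ]; ab <- line[i + 1L, ] - a
    l2 <- sum(ab^2)
    ap <- sweep(points, 2, a)
    t_ <- if (l2 > 0) pmin(pmax(as.numeric(ap %*% ab) / l2, 0), 1)
          else rep(0, nrow(points))
    dd <- ap - outer(t_, ab)
    best <- pmin(best, rowSums(dd^2))
  }
  sqrt(best)
}
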
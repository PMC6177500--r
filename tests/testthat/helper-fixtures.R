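# Shared fixtures, all built in code.

# Straight tube of radius r along +z (via the generator's degenerate
# single-branch mode; exact circular cross-sections).
make_cylinder <- function(r = 3, len = 12, seed = 1, n_circ = 24L,
                          ring_spacing = 0.8) {
  generate_bifurcation_mesh(radii = r, lengths = c(cca = len), jitter = 0,
                            seed = seed, n_circ = n_circ,
                            ring_spacing = ring_spacing)
}

# Torus segment (bent tube): tube radius r, bend radius bend, quarter turn.
make_torus_tube <- function(r = 3, bend = 20, n_rings = 40L, n_circ = 20L,
                            arc = pi / 2) {
  th <- seq(0, arc, length.out = n_rings)
  phi <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  verts <- do.call(rbind, lapply(th, function(ang) {
    ctr <- c(bend * cos(ang), 0, bend * sin(ang))
    e1 <- c(cos(ang), 0, sin(ang)); e2 <- c(0, 1, 0)
    t(vapply(phi, function(p) ctr + r * (cos(p) * e1 + sin(p) * e2),
             numeric(3)))
  }))
  faces <- NULL
  for (i in seq_len(n_rings - 1L)) {
    j <- seq_len(n_circ); jn <- c(seq_len(n_circ)[-1], 1L)
    a <- (i - 1L) * n_circ + j; b <- (i - 1L) * n_circ + jn
    c2 <- i * n_circ + jn; d <- i * n_circ + j
    faces <- rbind(faces, cbind(a, b, d), cbind(b, c2, d))
  }
  vessel_mesh(verts, faces)
}

# Small cohort config for fast tests (coarser meshes, fewer subjects).
small_config <- function(n_subjects = 6L, seed = 1L, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed, n_circ = 16L,
                ring_spacing = 1.2,
                lengths = c(cca = 16, ica = 12, eca = 12), ...)
}

# Truth-map cohort -> cohort_map_set (no velocity / estimator stages).
truth_map_set <- function(config) {
  subs <- generate_cohort(config, velocity = FALSE)
  shared <- suppressWarnings(
    build_shared_geometry(lapply(subs, function(s) s$lumen)))
  set <- build_cohort_maps(shared, lapply(subs, function(s)
    list(wt = s$truth$wt, wss = s$truth$wss, d = s$truth$diameter)))
  list(subjects = subs, shared = shared, set = set)
}

# Independent-null cohort matrices: per-subject smooth random fields with
# no population structure (true rho = 0 between quantities).
null_field_matrices <- function(n = 20L, V = 300L, harmonics = 2L) {
  s <- seq(0, 1, length.out = V)
  M <- vapply(seq_len(harmonics), function(k)
    cbind(sin(2 * pi * k * s), cos(2 * pi * k * s)), matrix(0, V, 2))
  basis <- cbind(1, s, matrix(M, nrow = V))
  K <- ncol(basis)
  field <- function() t(basis %*% matrix(stats::rnorm(K * n), K))
  list(wt = field(), wss = field())
}
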
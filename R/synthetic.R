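#' Configuration for a synthetic carotid-bifurcation cohort
#'
#' Bundles every knob of the synthetic data generator.  The defaults are the
#' study conditions emulated throughout the package: a 20-subject cohort,
#' a CCA that splits into a (flared) ICA and ECA, near-parabolic steady
#' velocity profiles with a 60 cm/s peak (the phase-contrast velocity
#' encoding), and a wall-thickness field built from the linear model
#' WT = b0 + b1*WSS + b2*D + b3*WSS*D + eps with i.i.d. Gaussian vertex
#' noise.
#'
#' @param n_subjects cohort size (>= 2).
#' @param beta_true length-4 ground-truth coefficient vector
#'   (b0 mm, b1 mm/Pa, b2 dimensionless, b3 mm/(Pa*mm)).
#' @param noise_sd standard deviation of the vertex-wise WT noise, mm.
#' @param geometry_variability fractional scale of the per-subject jitter on
#'   branch radii, branch angles and modulation phases.
#' @param peak_velocity peak axial velocity, cm/s.
#' @param viscosity dynamic viscosity of blood, Pa*s.
#' @param background_offset constant velocity offset added to every voxel
#'   (cm/s per component), emulating an uncorrected background phase offset.
#' @param noise_smoothing integer >= 0; number of neighbourhood-averaging
#'   passes applied to the WT noise field (0 = i.i.d. noise; larger values
#'   yield spatially correlated noise, rescaled to `noise_sd`).
#' @param radii nominal branch radii, mm (named cca/ica/eca, or a single
#'   value for a straight tube).
#' @param angles branch angles of ICA and ECA from the CCA axis, degrees.
#' @param lengths branch lengths, mm (each >= 3x its radius).
#' @param modulation list with `radius_amp`, `radius_freq`, `vpeak_amp`,
#'   `vpeak_freq`: fractional amplitude and spatial frequency (cycles per
#'   branch length) of the smooth axial modulation of local radius and local
#'   peak velocity.  Independent modulation of the two keeps WSS, D and
#'   WSS*D linearly independent within a subject.
#' @param n_circ vertices per cross-section ring.
#' @param ring_spacing axial ring spacing, mm.
#' @param voxel_mm velocity-image voxel size, mm (length 3).
#' @param velocity_noise_sd Gaussian noise on each velocity component, cm/s.
#' @param wt_floor lower clip for the wall thickness field, mm (a physical
#'   wall cannot vanish).
#' @param seed master seed; every random stream of the generator is derived
#'   from it via [rng_child_seeds()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 20L,
                          beta_true = c(1.2, -0.3, 0.08, 0.02),
                          noise_sd = 0.1,
                          geometry_variability = 0.05,
                          peak_velocity = 60,
                          viscosity = 3.2e-3,
                          background_offset = c(0, 0, 0),
                          noise_smoothing = 0L,
                          radii = c(cca = 3, ica = 2.2, eca = 1.8),
                          angles = c(ica = 25, eca = 25),
                          lengths = c(cca = 20, ica = 15, eca = 15),
                          modulation = list(radius_amp = 0.15, radius_freq = 1.5,
                                            vpeak_amp = 0.30, vpeak_freq = 2.5),
                          n_circ = 24L, ring_spacing = 0.8,
                          voxel_mm = c(0.45, 0.45, 0.45),
                          velocity_noise_sd = 0,
                          wt_floor = 0.1,
                          seed = 1L) {
  stopifnot(n_subjects >= 2L, length(beta_true) == 4L, noise_sd >= 0,
            peak_velocity > 0, viscosity > 0, all(radii > 0),
            noise_smoothing >= 0L, wt_floor > 0)
  if (any(lengths < 3 * radii[seq_along(lengths)]))
    stop("branch lengths must be at least 3x the branch radius")
  structure(list(
    n_subjects = as.integer(n_subjects), beta_true = as.numeric(beta_true),
    noise_sd = noise_sd, geometry_variability = geometry_variability,
    peak_velocity = peak_velocity, viscosity = viscosity,
    background_offset = as.numeric(background_offset),
    noise_smoothing = as.integer(noise_smoothing),
    radii = radii, angles = angles, lengths = lengths,
    modulation = modulation, n_circ = as.integer(n_circ),
    ring_spacing = ring_spacing, voxel_mm = as.numeric(voxel_mm),
    velocity_noise_sd = velocity_noise_sd, wt_floor = wt_floor,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat(sprintf("  beta_true = (%.3g, %.3g, %.3g, %.3g), noise_sd = %.3g mm\n",
              x$beta_true[1], x$beta_true[2], x$beta_true[3], x$beta_true[4],
              x$noise_sd))
  cat(sprintf("  peak velocity %.3g cm/s, viscosity %.3g Pa.s, jitter %.3g\n",
              x$peak_velocity, x$viscosity, x$geometry_variability))
  invisible(x)
}

## ---- parametric branch geometry ------------------------------------------

## Local radius of a branch at axial position s (mm), including the smooth
## axial modulation and the ostium flare.
branch_radius <- function(b, s) {
  r <- b$r0 * (1 + b$radius_amp * sin(2 * pi * b$radius_freq * s / b$length +
                                      b$radius_phase))
  if (b$flare_amp > 0) r <- r + b$flare_amp * exp(-(s / b$flare_w)^2)
  r
}

branch_radius_deriv <- function(b, s) {
  dr <- b$r0 * b$radius_amp * cos(2 * pi * b$radius_freq * s / b$length +
                                  b$radius_phase) *
        2 * pi * b$radius_freq / b$length
  if (b$flare_amp > 0)
    dr <- dr - b$flare_amp * (2 * s / b$flare_w^2) * exp(-(s / b$flare_w)^2)
  dr
}

## Relative local peak velocity (multiplies the configured peak velocity).
branch_vpeak_scale <- function(b, s) {
  1 + b$vpeak_amp * sin(2 * pi * b$vpeak_freq * s / b$length + b$vpeak_phase)
}

## Orthonormal in-plane basis for a branch direction.
branch_basis <- function(dir) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  ## (e1, e2, dir) right handed: e1 x e2 = dir
  e2 <- -e2
  list(e1 = e1, e2 = e2)
}

## Build the list of branch descriptors for one subject.  Nominal modulation
## phases are fixed constants per branch; jitter perturbs radii, angles and
## phases.
make_branch_geometry <- function(radii, angles, lengths, modulation, jitter,
                                 peak_velocity) {
  mod <- modulation
  if (is.null(mod)) mod <- list(radius_amp = 0, radius_freq = 1,
                                vpeak_amp = 0, vpeak_freq = 1)
  nominal_rphase <- c(cca = 0.4, ica = 1.3, eca = 2.6)
  nominal_vphase <- c(cca = 2.1, ica = 0.6, eca = 3.6)
  ## jitter draws are truncated at +-2.5 sd: physiological bounds that also
  ## keep every subject inside the velocity-image voxel/radius precondition
  jr <- function() if (jitter > 0) 1 + jitter * max(min(stats::rnorm(1), 2.5), -2.5) else 1
  jp <- function() if (jitter > 0) stats::rnorm(1, 0, jitter * 2 * pi) else 0

  single <- length(radii) == 1L
  if (single) {
    b <- list(name = "cca", origin = c(0, 0, 0), dir = c(0, 0, 1),
              length = unname(lengths[1]), r0 = unname(radii[1]) * jr(),
              radius_amp = mod$radius_amp, radius_freq = mod$radius_freq,
              radius_phase = nominal_rphase[["cca"]] + jp(),
              vpeak_amp = mod$vpeak_amp, vpeak_freq = mod$vpeak_freq,
              vpeak_phase = nominal_vphase[["cca"]] + jp(),
              flare_amp = 0, flare_w = 1, peak_velocity = peak_velocity)
    return(list(cca = b))
  }

  r <- radii[c("cca", "ica", "eca")] * c(jr(), jr(), jr())
  a <- angles[c("ica", "eca")] * c(jr(), jr()) * pi / 180
  dir_ica <- c(sin(a[["ica"]]), 0, cos(a[["ica"]]))
  dir_eca <- c(-sin(a[["eca"]]), 0, cos(a[["eca"]]))
  cca <- list(name = "cca", origin = c(0, 0, -unname(lengths[["cca"]])),
              dir = c(0, 0, 1), length = unname(lengths[["cca"]]),
              r0 = unname(r[["cca"]]),
              radius_amp = mod$radius_amp, radius_freq = mod$radius_freq,
              radius_phase = nominal_rphase[["cca"]] + jp(),
              vpeak_amp = mod$vpeak_amp, vpeak_freq = mod$vpeak_freq,
              vpeak_phase = nominal_vphase[["cca"]] + jp(),
              flare_amp = 0, flare_w = 1, peak_velocity = peak_velocity)
  r_cca_end <- branch_radius(cca, cca$length)
  mk_branch <- function(name, dir) {
    b <- list(name = name, origin = c(0, 0, 0), dir = dir,
              length = unname(lengths[[name]]), r0 = unname(r[[name]]),
              radius_amp = mod$radius_amp, radius_freq = mod$radius_freq,
              radius_phase = nominal_rphase[[name]] + jp(),
              vpeak_amp = mod$vpeak_amp, vpeak_freq = mod$vpeak_freq,
              vpeak_phase = nominal_vphase[[name]] + jp(),
              flare_amp = 0, flare_w = 1.5 * r_cca_end,
              peak_velocity = peak_velocity)
    ## flare the ostium up to just beyond the CCA end radius so the three
    ## tubes form a closed junction (and mimic the carotid bulb)
    b$flare_amp <- max(0, 1.1 * r_cca_end - branch_radius(b, 0))
    b
  }
  list(cca = cca, ica = mk_branch("ica", dir_ica), eca = mk_branch("eca", dir_eca))
}

## Signed axial coordinate and perpendicular distance of points to a branch
## axis.  Returns list(s, d).
branch_coords <- function(b, points) {
  rel <- sweep(points, 2, b$origin)
  s <- as.numeric(rel %*% b$dir)
  perp <- rel - outer(s, b$dir)
  list(s = s, d = sqrt(rowSums(perp^2)))
}

## Is each point strictly inside branch b's (possibly grown) tube?
inside_branch <- function(b, points, grow = 0, tol = 1e-6) {
  bc <- branch_coords(b, points)
  ok <- bc$s >= 0 & bc$s <= b$length
  r <- branch_radius(b, pmin(pmax(bc$s, 0), b$length)) + grow
  ok & bc$d < r * (1 - tol)
}

## ---- mesh generation ------------------------------------------------------

#' Generate a synthetic carotid-bifurcation lumen mesh
#'
#' Builds a triangulated lumen surface as the clipped union of three
#' straight tubes (CCA splitting into ICA and ECA in the x-z plane), with a
#' smooth ostium flare of the daughter branches that both closes the
#' junction and mimics the carotid bulb.  A single radius produces a
#' straight tube (degenerate single-branch case).  Local radius and local
#' peak-velocity scale can be modulated smoothly along each branch; the
#' parametric description is attached to the mesh (`branch_geometry`) and is
#' used by [generate_velocity_image()] and for analytic ground-truth maps.
#'
#' @param radii branch radii in mm: named vector (cca/ica/eca) or a single
#'   value for a straight tube.
#' @param branch_angles ICA and ECA angles from the CCA axis, degrees.
#' @param lengths branch lengths, mm (each >= 3x radius).
#' @param jitter fractional per-subject jitter applied to radii, angles and
#'   modulation phases (0 = nominal geometry).
#' @param seed integer seed (meshes are vertex-identical for a fixed seed);
#'   `NULL` leaves the RNG state alone.
#' @param n_circ vertices per ring.
#' @param ring_spacing axial ring spacing, mm.
#' @param modulation see [cohort_config()]; `NULL` disables modulation so
#'   cross-sections are exact circles.
#' @param peak_velocity nominal peak velocity carried in the branch
#'   geometry, cm/s.
#' @return a [vessel_mesh()] with branch labels, exact inward normals, apex
#'   landmark and per-vertex generator data (`axial_s`, `truth_radius`,
#'   `truth_vscale`, `origin_branch` attributes).
#' @export
generate_bifurcation_mesh <- function(radii = c(cca = 3, ica = 2.2, eca = 1.8),
                                      branch_angles = c(ica = 25, eca = 25),
                                      lengths = NULL, jitter = 0, seed = NULL,
                                      n_circ = 24L, ring_spacing = 0.8,
                                      modulation = NULL, peak_velocity = 60) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(lengths)) {
    lengths <- if (length(radii) == 1L) c(cca = 4 * unname(radii[1]))
               else c(cca = 20, ica = 15, eca = 15)
  }
  if (any(radii <= 0)) stop("radii must be positive")
  if (any(lengths < 3 * radii[seq_along(lengths)]))
    stop("branch lengths must be at least 3x the branch radius")
  geo <- make_branch_geometry(radii, branch_angles, lengths, modulation,
                              jitter, peak_velocity)
  single <- length(geo) == 1L

  if (!single) {
    ## reject parameter combinations whose outlets do not separate
    ends <- lapply(geo[c("ica", "eca")], function(b) b$origin + b$length * b$dir)
    sep <- sqrt(sum((ends[[1]] - ends[[2]])^2))
    rsum <- branch_radius(geo$ica, geo$ica$length) +
            branch_radius(geo$eca, geo$eca$length)
    if (sep <= rsum)
      stop(sprintf(paste0("self-intersecting geometry: ICA/ECA outlets are ",
                          "%.2f mm apart but their radii sum to %.2f mm; ",
                          "increase the branch angles or lengths"), sep, rsum))
  }

  verts <- NULL; normals <- NULL; faces <- NULL
  branch_of <- character(0); axial_s <- numeric(0)
  t_radius <- numeric(0); t_vscale <- numeric(0)

  for (b in geo) {
    n_rings <- max(4L, ceiling(b$length / ring_spacing) + 1L)
    svals <- seq(0, b$length, length.out = n_rings)
    bb <- branch_basis(b$dir)
    theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
    ct <- cos(theta); st <- sin(theta)
    nv0 <- if (is.null(verts)) 0L else nrow(verts)
    rv <- branch_radius(b, svals)
    drv <- branch_radius_deriv(b, svals)
    vs <- branch_vpeak_scale(b, svals)
    ring_pts <- vector("list", n_rings)
    ring_nrm <- vector("list", n_rings)
    for (i in seq_len(n_rings)) {
      ctr <- b$origin + svals[i] * b$dir
      radial <- outer(ct, bb$e1) + outer(st, bb$e2)
      pts <- sweep(radial * rv[i], 2, ctr, "+")
      ## outward normal of the surface r(s): radial - r'(s) * axial
      nrm <- unit_rows(radial - matrix(b$dir, n_circ, 3, byrow = TRUE) * drv[i])
      ring_pts[[i]] <- pts
      ring_nrm[[i]] <- nrm
    }
    verts <- rbind(verts, do.call(rbind, ring_pts))
    normals <- rbind(normals, do.call(rbind, ring_nrm))
    branch_of <- c(branch_of, rep(b$name, n_rings * n_circ))
    axial_s <- c(axial_s, rep(svals, each = n_circ))
    t_radius <- c(t_radius, rep(rv, each = n_circ))
    t_vscale <- c(t_vscale, rep(vs, each = n_circ))
    ## quad strip faces with outward winding
    fi <- NULL
    for (i in seq_len(n_rings - 1L)) {
      j <- seq_len(n_circ); jn <- c(seq_len(n_circ)[-1], 1L)
      a_ <- nv0 + (i - 1L) * n_circ + j
      b_ <- nv0 + (i - 1L) * n_circ + jn
      c_ <- nv0 + i * n_circ + jn
      d_ <- nv0 + i * n_circ + j
      fi <- rbind(fi, cbind(a_, b_, d_), cbind(b_, c_, d_))
    }
    faces <- rbind(faces, fi)
  }

  keep <- rep(TRUE, nrow(verts))
  if (!single) {
    for (b in geo) {
      others <- branch_of != b$name
      keep[others] <- keep[others] & !inside_branch(b, verts[others, , drop = FALSE])
    }
  }
  if (!all(keep)) {
    remap <- cumsum(keep)
    fkeep <- keep[faces[, 1]] & keep[faces[, 2]] & keep[faces[, 3]]
    faces <- matrix(remap[faces[fkeep, , drop = FALSE]], ncol = 3)
    verts <- verts[keep, , drop = FALSE]
    normals <- normals[keep, , drop = FALSE]
    branch_of <- branch_of[keep]
    axial_s <- axial_s[keep]
    t_radius <- t_radius[keep]
    t_vscale <- t_vscale[keep]
  }
  ## drop vertices that lost all their faces
  used <- sort(unique(as.integer(faces)))
  if (length(used) < nrow(verts)) {
    remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
    faces <- matrix(remap[faces], ncol = 3)
    verts <- verts[used, , drop = FALSE]
    normals <- normals[used, , drop = FALSE]
    branch_of <- branch_of[used]
    axial_s <- axial_s[used]
    t_radius <- t_radius[used]
    t_vscale <- t_vscale[used]
  }

  apex <- if (!single) c(0, 0, 0)
  label <- branch_of
  if (!single) {
    r_ref <- branch_radius(geo$cca, geo$cca$length)
    near_apex <- sqrt(rowSums(verts^2)) < 1.5 * r_ref
    label[near_apex] <- "bifurcation"
  }
  mesh <- vessel_mesh(verts, faces, inward_normals = -normals, branch = label,
                      apex = apex, branch_geometry = geo)
  attr(mesh, "origin_branch") <- branch_of
  attr(mesh, "axial_s") <- axial_s
  attr(mesh, "truth_radius") <- t_radius
  attr(mesh, "truth_vscale") <- t_vscale
  mesh
}

## ---- velocity image -------------------------------------------------------

#' Generate a synthetic velocity volume for a lumen mesh
#'
#' Fills a regular voxel grid covering the lumen with a steady,
#' near-parabolic axial velocity field: inside each branch the axial
#' velocity is v(r) = v_peak(s) * (1 - r^2/R(s)^2); in the junction the
#' branch profiles are blended by a smooth partition of unity, so exactness
#' is only claimed on straight single-branch segments.  Voxels outside the
#' lumen are zero.  A constant background offset and i.i.d. Gaussian noise
#' can be added to every voxel to emulate uncorrected phase offsets and
#' measurement noise.
#'
#' @param lumen a lumen [vessel_mesh()] carrying `branch_geometry` (i.e.
#'   generated by [generate_bifurcation_mesh()]).
#' @param peak_velocity nominal peak velocity, cm/s.
#' @param voxel_mm voxel size, mm (length 3; each must be <= R/3 so at
#'   least three samples fit along a radius).
#' @param noise_sd Gaussian noise per component, cm/s.
#' @param background_offset length-3 constant offset, cm/s.
#' @param seed integer seed for the noise stream.
#' @param margin grid margin around the mesh bounding box, mm.
#' @return a [velocity_image()].
#' @export
generate_velocity_image <- function(lumen, peak_velocity = 60,
                                    voxel_mm = c(0.5, 0.5, 0.5),
                                    noise_sd = 0, background_offset = c(0, 0, 0),
                                    seed = NULL, margin = 8) {
  geo <- lumen$branch_geometry
  if (is.null(geo))
    stop("lumen carries no branch_geometry; generate it with generate_bifurcation_mesh()")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  min_r <- min(vapply(geo, function(b)
    min(branch_radius(b, seq(0, b$length, length.out = 64))), numeric(1)))
  if (max(voxel_mm) > min_r / 3)
    stop(sprintf(paste0("voxel size %.3g mm too coarse for minimum radius ",
                        "%.3g mm (need voxel <= radius/3 = %.3g mm)"),
                 max(voxel_mm), min_r, min_r / 3))
  lo <- apply(lumen$vertices, 2, min) - margin
  hi <- apply(lumen$vertices, 2, max) + margin
  dims <- pmax(2L, ceiling((hi - lo) / voxel_mm) + 1L)
  origin <- lo
  gx <- origin[1] + voxel_mm[1] * (seq_len(dims[1]) - 1L)
  gy <- origin[2] + voxel_mm[2] * (seq_len(dims[2]) - 1L)
  gz <- origin[3] + voxel_mm[3] * (seq_len(dims[3]) - 1L)
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  n <- nrow(pts)
  wsum <- numeric(n)
  vacc <- matrix(0, n, 3)
  for (b in geo) {
    bc <- branch_coords(b, pts)
    act <- bc$s >= 0 & bc$s <= b$length
    if (!any(act)) next
    s <- bc$s[act]
    r <- branch_radius(b, s)
    u <- 1 - (bc$d[act] / r)^2
    inside <- u > 0
    if (!any(inside)) next
    ii <- which(act)[inside]
    u <- u[inside]
    vmag <- peak_velocity * branch_vpeak_scale(b, s[inside]) * u
    w <- u^2
    wsum[ii] <- wsum[ii] + w
    vacc[ii, ] <- vacc[ii, ] + (w * vmag) %o% b$dir
  }
  nz <- wsum > 0
  vacc[nz, ] <- vacc[nz, ] / wsum[nz]
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0)
    vacc <- vacc + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  vacc <- sweep(vacc, 2, rep_len(as.numeric(background_offset), 3L), "+")
  dat <- array(vacc, dim = c(dims, 3L))
  velocity_image(dat, spacing = voxel_mm, origin = origin)
}

## ---- cohort ---------------------------------------------------------------

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("synthetic_subject", x$subject_id, "\n")
  print(x$lumen)
  cat(sprintf("  truth beta = (%.3g, %.3g, %.3g, %.3g)\n",
              x$truth_beta[1], x$truth_beta[2], x$truth_beta[3], x$truth_beta[4]))
  invisible(x)
}

## Smooth a per-vertex field by iterated 1-ring averaging on the mesh graph.
smooth_vertex_field <- function(mesh, values, iterations) {
  if (iterations <= 0L) return(values)
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  for (it in seq_len(iterations)) {
    s <- rowsum(values[e[, 2]], e[, 1])
    cnt <- rowsum(rep(1, nrow(e)), e[, 1])
    nb <- numeric(length(values))
    nb[as.integer(rownames(s))] <- s[, 1] / cnt[, 1]
    values <- 0.5 * values + 0.5 * nb
  }
  values
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each subject: a jittered bifurcation lumen mesh; analytic
#' ground-truth WSS (2*mu*v_peak(s)/R(s), converted to Pa), diameter
#' (2*R(s)) and wall thickness WT = b0 + b1*WSS + b2*D + b3*WSS*D + eps
#' maps; an outer-wall mesh offset from the lumen along the outward normals
#' by the truth WT; and (optionally) a synthetic velocity volume.  All
#' randomness derives from `config$seed` via documented stream splitting, so
#' an identical config yields a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @param velocity generate velocity volumes (set `FALSE` to skip the
#'   image stage when only meshes and truth maps are needed).
#' @return list of `synthetic_subject` objects, each with elements
#'   `subject_id`, `lumen`, `outer_wall`, `velocity`, `truth` (scalar maps
#'   `wss`, `wt`, `diameter`) and `truth_beta`.
#' @export
generate_cohort <- function(config, velocity = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- matrix(rng_child_seeds(config$seed, 3L * config$n_subjects),
                  ncol = 3L)
  lapply(seq_len(config$n_subjects), function(i) {
    generate_subject(config, sprintf("S%02d", i),
                     mesh_seed = seeds[i, 1], noise_seed = seeds[i, 2],
                     velocity_seed = seeds[i, 3], velocity = velocity)
  })
}

generate_subject <- function(config, subject_id, mesh_seed, noise_seed,
                             velocity_seed, velocity = TRUE) {
  lumen <- generate_bifurcation_mesh(
    radii = config$radii, branch_angles = config$angles,
    lengths = config$lengths, jitter = config$geometry_variability,
    seed = mesh_seed, n_circ = config$n_circ,
    ring_spacing = config$ring_spacing, modulation = config$modulation,
    peak_velocity = config$peak_velocity)

  r_loc <- attr(lumen, "truth_radius")
  vscale <- attr(lumen, "truth_vscale")
  ## WSS = mu * 2 v_peak / R; v in cm/s and R in mm -> factor 10 to s^-1
  wss <- config$viscosity * 2 * (config$peak_velocity * vscale) / r_loc *
         CMS_PER_MM_TO_PER_S
  dia <- 2 * r_loc
  b <- config$beta_true
  wt0 <- b[1] + b[2] * wss + b[3] * dia + b[4] * wss * dia
  set.seed(noise_seed)
  eps <- if (config$noise_sd > 0)
    stats::rnorm(length(wt0), 0, config$noise_sd) else numeric(length(wt0))
  if (config$noise_smoothing > 0L && config$noise_sd > 0) {
    eps <- smooth_vertex_field(lumen, eps, config$noise_smoothing)
    eps <- eps * config$noise_sd / stats::sd(eps)
  }
  wt <- wt0 + eps
  frac_bad <- mean(wt <= 0)
  if (frac_bad > 0.2)
    warning(sprintf("beta yields non-physical WT (<= 0) on %.1f%% of vertices before clipping",
                    100 * frac_bad))
  wt <- pmax(wt, config$wt_floor)

  ## exclude crotch vertices whose wall would merge into the sibling
  ## branch's wall (shared septum thinner than the model WT)
  feasible <- wall_feasible(lumen, wt)
  if (!all(feasible)) {
    sub <- subset_mesh(lumen, feasible)
    lumen <- sub$mesh
    wss <- wss[sub$kept]; dia <- dia[sub$kept]; wt <- wt[sub$kept]
  }

  outer_wall <- offset_outer_wall(lumen, wt)
  vel <- if (velocity) generate_velocity_image(
    lumen, peak_velocity = config$peak_velocity, voxel_mm = config$voxel_mm,
    noise_sd = config$velocity_noise_sd,
    background_offset = config$background_offset, seed = velocity_seed)

  structure(list(
    subject_id = subject_id, lumen = lumen, outer_wall = outer_wall,
    velocity = vel,
    truth = list(wss = scalar_map(wss, lumen, "wss"),
                 wt = scalar_map(wt, lumen, "wt"),
                 diameter = scalar_map(dia, lumen, "d")),
    truth_beta = config$beta_true,
    seeds = c(mesh = mesh_seed, noise = noise_seed, velocity = velocity_seed)
  ), class = "synthetic_subject")
}

## Keep a subset of vertices, remapping faces, normals, labels and the
## generator's per-vertex attributes; vertices losing all faces are dropped.
subset_mesh <- function(mesh, keep) {
  verts <- mesh$vertices; normals <- mesh$inward_normals
  faces <- mesh$faces; branch <- mesh$branch
  attrs <- lapply(c("origin_branch", "axial_s", "truth_radius", "truth_vscale"),
                  function(a) attr(mesh, a))
  names(attrs) <- c("origin_branch", "axial_s", "truth_radius", "truth_vscale")
  take <- function(idx) {
    verts <<- verts[idx, , drop = FALSE]
    normals <<- normals[idx, , drop = FALSE]
    if (!is.null(branch)) branch <<- branch[idx]
    attrs <<- lapply(attrs, function(a) if (!is.null(a)) a[idx])
  }
  orig <- which(keep)
  remap <- cumsum(keep)
  fkeep <- keep[faces[, 1]] & keep[faces[, 2]] & keep[faces[, 3]]
  faces <- matrix(remap[faces[fkeep, , drop = FALSE]], ncol = 3)
  take(orig)
  used <- sort(unique(as.integer(faces)))
  if (length(used) < nrow(verts)) {
    remap2 <- integer(nrow(verts)); remap2[used] <- seq_along(used)
    faces <- matrix(remap2[faces], ncol = 3)
    take(used)
    orig <- orig[used]
  }
  out <- vessel_mesh(verts, faces, inward_normals = normals, branch = branch,
                     apex = mesh$apex, branch_geometry = mesh$branch_geometry)
  for (a in names(attrs)) attr(out, a) <- attrs[[a]]
  list(mesh = out, kept = orig)
}

## Lumen vertices whose offset tip p + wt*n lands inside another branch's
## wall envelope (lumen tube grown by that branch's typical wall thickness)
## have no geometrically realisable wall of their own: in the crotch the two
## daughter walls merge into a shared septum thinner than the nominal WT.
## These vertices are excluded from the subject's maps.
wall_feasible <- function(lumen, wt) {
  geo <- lumen$branch_geometry
  origin_branch <- attr(lumen, "origin_branch")
  keep <- rep(TRUE, nrow(lumen$vertices))
  if (is.null(geo) || length(geo) < 2L || is.null(origin_branch)) return(keep)
  tip <- lumen$vertices - lumen$inward_normals * wt
  for (b in geo) {
    others <- which(origin_branch != b$name)
    if (!length(others)) next
    grow <- stats::quantile(wt[origin_branch == b$name], 0.75, names = FALSE)
    keep[others] <- keep[others] &
      !inside_branch(b, tip[others, , drop = FALSE], grow = grow)
  }
  keep
}

## Outer wall = lumen offset along outward normals by the per-vertex wall
## thickness (wall-infeasible crotch vertices have already been removed).
offset_outer_wall <- function(lumen, wt) {
  overt <- lumen$vertices - lumen$inward_normals * wt
  vessel_mesh(overt, lumen$faces, inward_normals = lumen$inward_normals,
              branch = lumen$branch, apex = lumen$apex)
}
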
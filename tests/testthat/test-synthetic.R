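test_that("straight-branch mesh has exact circular cross-sections and is deterministic", {
  m1 <- make_cylinder(r = 3, len = 12, seed = 7)
  rad <- sqrt(rowSums(m1$vertices[, 1:2]^2))
  expect_equal(rad, rep(3, length(rad)), tolerance = 1e-12)
  m2 <- make_cylinder(r = 3, len = 12, seed = 7)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  # inward normals point towards the axis
  expect_true(all(rowSums(m1$inward_normals * cbind(-m1$vertices[, 1:2], 0)) > 0))
})

test_that("radius jitter produces the configured between-subject spread", {
  n <- 50
  mean_r <- vapply(seq_len(n), function(i) {
    m <- generate_bifurcation_mesh(jitter = 0.1, seed = 1000 + i,
                                   n_circ = 12L, ring_spacing = 1.6)
    mean(attr(m, "truth_radius")[attr(m, "origin_branch") == "cca"])
  }, numeric(1))
  # sample SD of the per-subject mean CCA radius ~ 0.1 x nominal (3 mm),
  # within +-30% (jitter is truncated at +-2.5 sd)
  expect_gt(sd(mean_r), 0.7 * 0.1 * 3)
  expect_lt(sd(mean_r), 1.3 * 0.1 * 3)
})

test_that("self-intersecting branch parameters are rejected with a diagnostic", {
  expect_error(
    generate_bifurcation_mesh(branch_angles = c(ica = 2, eca = 2),
                              lengths = c(cca = 20, ica = 10, eca = 10)),
    "self-intersecting"
  )
})

test_that("velocity image realises the parabolic profile", {
  lum <- make_cylinder(r = 3, len = 12)
  img <- generate_velocity_image(lum, peak_velocity = 60,
                                 voxel_mm = rep(0.5, 3))
  # centerline sample = peak, wall-adjacent below peak
  ctr <- sample_velocity(img, rbind(c(0, 0, 6), c(0, 2.5, 6)))
  expect_equal(ctr[1, 3], 60, tolerance = 1)
  expect_lt(ctr[2, 3], 55)
  expect_equal(ctr[1, 1:2], c(0, 0), tolerance = 1e-9)
  # noiseless, offset-free: |v| never exceeds the analytic peak
  speed <- sqrt(rowSums(matrix(img$data, ncol = 3)^2))
  expect_lte(max(speed), 60 * (1 + 1e-6))
  expect_gt(max(speed), 58)  # peak is attained on the grid
})

test_that("background offset shifts empty-region voxels by the offset", {
  lum <- make_cylinder(r = 3, len = 12)
  img <- generate_velocity_image(lum, peak_velocity = 60,
                                 voxel_mm = rep(0.5, 3),
                                 background_offset = c(5, 0, 0))
  mask <- static_tissue_mask(img, lum, margin = 5)
  expect_true(any(mask))
  vx <- img$data[, , , 1]
  expect_equal(mean(vx[mask]), 5, tolerance = 1e-9)
  expect_equal(mean(img$data[, , , 2][mask]), 0, tolerance = 1e-9)
})

test_that("too-coarse voxels are rejected naming the violated ratio", {
  lum <- make_cylinder(r = 3, len = 12)
  expect_error(generate_velocity_image(lum, voxel_mm = rep(1.5, 3)),
               "radius/3")
})

test_that("cohort truth maps satisfy the linear model by construction", {
  cfg <- small_config(n_subjects = 3L, noise_sd = 0, seed = 11)
  subs <- generate_cohort(cfg, velocity = FALSE)
  for (s in subs) {
    wss <- as.numeric(s$truth$wss); d <- as.numeric(s$truth$diameter)
    wt <- as.numeric(s$truth$wt)
    b <- s$truth_beta
    expect_lt(max(abs(wt - (b[1] + b[2] * wss + b[3] * d + b[4] * wss * d))),
              1e-9)
    expect_true(all(wt > 0))
  }
})

test_that("constant-beta cohort yields constant WT maps", {
  cfg <- small_config(n_subjects = 2L, noise_sd = 0, seed = 2,
                      beta_true = c(1, 0, 0, 0))
  subs <- generate_cohort(cfg, velocity = FALSE)
  expect_equal(as.numeric(subs[[1]]$truth$wt),
               rep(1, length(subs[[1]]$truth$wt)))
})

test_that("cohort generation is bit-identical for a fixed config", {
  cfg <- small_config(n_subjects = 2L, seed = 42)
  a <- generate_cohort(cfg, velocity = FALSE)
  b <- generate_cohort(cfg, velocity = FALSE)
  expect_identical(a[[1]]$lumen$vertices, b[[1]]$lumen$vertices)
  expect_identical(as.numeric(a[[2]]$truth$wt), as.numeric(b[[2]]$truth$wt))
})

test_that("negative WSS-WT coupling appears in every subject's truth maps", {
  # beta1 < 0, small noise: per-subject Spearman rho(WSS, WT) < 0
  for (seed in c(3, 14, 25)) {
    cfg <- small_config(n_subjects = 4L, noise_sd = 0.02, seed = seed)
    subs <- generate_cohort(cfg, velocity = FALSE)
    rhos <- vapply(subs, function(s)
      as.numeric(spearman_rho(s$truth$wss, s$truth$wt)), numeric(1))
    expect_true(all(rhos < 0))
  }
})

test_that("non-physical beta triggers the clipping warning", {
  cfg <- small_config(n_subjects = 2L, noise_sd = 0, seed = 5,
                      beta_true = c(-0.5, 0, 0, 0), wt_floor = 0.1)
  w <- capture_warnings(generate_cohort(cfg, velocity = FALSE))
  expect_length(w, 2L)  # one per subject
  expect_match(w, "non-physical", all = TRUE)
})

test_that("outer wall is offset from the lumen by the truth wall thickness", {
  cfg <- small_config(n_subjects = 2L, seed = 9)
  subs <- generate_cohort(cfg, velocity = FALSE)
  for (s in subs) {
    wt_geom <- compute_wall_thickness(s$lumen, s$outer_wall)
    err <- abs(as.numeric(wt_geom) - as.numeric(s$truth$wt))
    tol <- 0.02 * as.numeric(s$truth$wt) + mean_edge_length(s$lumen)
    expect_true(all(err <= tol))
  }
})

test_that("spatially correlated WT noise keeps the requested magnitude", {
  cfg <- small_config(n_subjects = 2L, seed = 8, noise_sd = 0.15,
                      noise_smoothing = 3L)
  subs <- generate_cohort(cfg, velocity = FALSE)
  s <- subs[[1]]
  b <- s$truth_beta
  wss <- as.numeric(s$truth$wss); d <- as.numeric(s$truth$diameter)
  eps <- as.numeric(s$truth$wt) - (b[1] + b[2] * wss + b[3] * d + b[4] * wss * d)
  expect_equal(sd(eps), 0.15, tolerance = 0.02)
  # smoothing induces positive correlation between mesh neighbours
  f <- s$lumen$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  expect_gt(cor(eps[e[, 1]], eps[e[, 2]]), 0.5)
})
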
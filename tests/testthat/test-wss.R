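test_that("background offset correction recovers a clean static region", {
  lum <- make_cylinder(r = 3, len = 12)
  img <- generate_velocity_image(lum, voxel_mm = rep(0.5, 3),
                                 background_offset = c(5, 0, 0))
  mask <- static_tissue_mask(img, lum, margin = 5)
  cor1 <- correct_background_offset(img, mask)
  expect_true(cor1$corrected)
  expect_equal(attr(cor1, "offset_removed"), c(5, 0, 0), tolerance = 1e-9)
  expect_equal(mean(cor1$data[, , , 1][mask]), 0, tolerance = 1e-9)
  # an already-clean image passes through unchanged
  img0 <- generate_velocity_image(lum, voxel_mm = rep(0.5, 3))
  cor0 <- correct_background_offset(img0, mask)
  expect_lt(max(abs(cor0$data - img0$data)), 1e-9)
  expect_error(correct_background_offset(img, array(FALSE, dim(img$data)[1:3])),
               "empty")
})

test_that("wall samples read the parabolic profile at centre and wall", {
  lum <- make_cylinder(r = 3, len = 18)
  img <- generate_velocity_image(lum, peak_velocity = 60, voxel_mm = rep(0.4, 3))
  r_map <- scalar_map(rep(6, nrow(lum$vertices)), lum, "d")
  ws <- sample_wall_velocities(lum, img, r_map)
  mid <- abs(lum$vertices[, 3] - 9) < 3  # away from open ends
  speed_ctr <- sqrt(ws$inplane_x[, 3]^2 + ws$inplane_y[, 3]^2)
  expect_equal(stats::median(speed_ctr[mid]), 60, tolerance = 1.5)
  speed_wall <- sqrt(ws$inplane_x[, 1]^2 + ws$inplane_y[, 1]^2)
  expect_lt(stats::median(speed_wall[mid]), 0.1 * 60)
  expect_length(ws$excluded, 0L)
})

test_that("vertices sampling outside the image are excluded, not mapped", {
  lum <- make_cylinder(r = 3, len = 30)
  img <- generate_velocity_image(lum, voxel_mm = rep(0.5, 3), margin = 2)
  # crop the grid so one tube end leaves the field of view
  img$data <- img$data[, , 1:round(dim(img$data)[3] / 2), , drop = FALSE]
  wss <- suppressWarnings(
    compute_wss_map(lum, img, scalar_map(rep(6, nrow(lum$vertices)), lum, "d")))
  excl <- attr(wss, "n_excluded")
  expect_gt(excl, 0L)
  expect_equal(sum(is.na(as.numeric(wss))), excl)
  expect_equal(sum(!is.na(as.numeric(wss))) + excl, nrow(lum$vertices))
})

test_that("three-point spline derivative matches the quadratic oracle", {
  # parabola v = 60 (1 - ((3-d)/3)^2) sampled at d = 0, 1.5, 3 mm:
  # the interpolating quadratic has dv/dd = 40 (cm/s)/mm = 400 1/s at d = 0
  s <- list(distances = matrix(c(0, 1.5, 3), 1),
            inplane_x = matrix(c(0, 45, 60), 1),
            inplane_y = matrix(c(0, 0, 0), 1), excluded = integer(0))
  g <- fit_wall_gradient(s, smoothing = 0)
  expect_equal(g$dx, 40, tolerance = 1e-9)
  expect_equal(g$gradient, 400, tolerance = 1e-6)
  # constant samples -> zero gradient
  s$inplane_x <- matrix(c(7, 7, 7), 1)
  expect_equal(fit_wall_gradient(s)$gradient, 0, tolerance = 1e-9)
  # linear profile through the origin is reproduced for any smoothing
  s$inplane_x <- matrix(c(0, 3, 6), 1)  # slope 2 (cm/s)/mm
  expect_equal(fit_wall_gradient(s, smoothing = 0)$dx, 2, tolerance = 1e-9)
  expect_equal(fit_wall_gradient(s, smoothing = 5)$dx, 2, tolerance = 1e-9)
  # coincident distances are rejected
  s$distances <- matrix(c(0, 0, 3), 1)
  expect_error(fit_wall_gradient(s), "coincident|increasing")
})

test_that("Poiseuille tubes recover the closed-form wall shear stress", {
  mu <- 3.2e-3
  for (R in c(2, 3, 4)) {
    lum <- make_cylinder(r = R, len = max(12, 4 * R))
    img <- generate_velocity_image(lum, peak_velocity = 60,
                                   voxel_mm = rep(R / 8, 3))
    img$corrected <- TRUE
    dm <- compute_diameter_map(lum, compute_centerline(lum))
    wss <- compute_wss_map(lum, img, dm, viscosity = mu)
    truth <- mu * 2 * 0.6 / (R / 1000)
    expect_equal(stats::median(as.numeric(wss), na.rm = TRUE), truth,
                 tolerance = 0.1 * truth)
  }
})

test_that("WSS is linear in the velocity and zero for a still fluid", {
  lum <- make_cylinder(r = 3, len = 12)
  img <- generate_velocity_image(lum, peak_velocity = 60, voxel_mm = rep(0.5, 3))
  img$corrected <- TRUE
  dm <- compute_diameter_map(lum, compute_centerline(lum))
  w1 <- compute_wss_map(lum, img, dm)
  img2 <- img; img2$data <- img$data * 2
  w2 <- compute_wss_map(lum, img2, dm)
  nz <- as.numeric(w1) > 1e-12
  expect_lt(max(abs(as.numeric(w2)[nz] / as.numeric(w1)[nz] - 2)), 1e-6)
  img0 <- img; img0$data[] <- 0
  expect_equal(max(as.numeric(compute_wss_map(lum, img0, dm))), 0,
               tolerance = 1e-12)
  expect_error(compute_wss_map(lum, img, dm, viscosity = 0), "viscosity")
})

test_that("WSS is invariant under joint rigid rotation of mesh and image", {
  lum <- make_cylinder(r = 3, len = 12)
  img <- generate_velocity_image(lum, voxel_mm = rep(0.5, 3))
  img$corrected <- TRUE
  dm <- compute_diameter_map(lum, compute_centerline(lum))
  w1 <- compute_wss_map(lum, img, dm)
  R <- wallmap:::rotation_about_axis(c(0.3, 1, 0.2), 0.6)
  lum2 <- transform_mesh(lum, R)
  img2 <- img
  img2$affine <- rbind(cbind(R %*% img$affine[1:3, 1:3], R %*% img$affine[1:3, 4]),
                       c(0, 0, 0, 1))
  # rotate the velocity vectors themselves into the new frame
  vmat <- matrix(img$data, ncol = 3) %*% t(R)
  img2$data <- array(vmat, dim = dim(img$data))
  w2 <- compute_wss_map(lum2, img2, dm)
  rel <- abs(as.numeric(w2) - as.numeric(w1)) / pmax(as.numeric(w1), 0.05)
  expect_lt(stats::median(rel), 0.01)
})

test_that("offset-then-correct leaves the WSS map essentially unchanged", {
  lum <- make_cylinder(r = 3, len = 12)
  dm <- compute_diameter_map(lum, compute_centerline(lum))
  img_clean <- generate_velocity_image(lum, voxel_mm = rep(0.4, 3))
  img_off <- generate_velocity_image(lum, voxel_mm = rep(0.4, 3),
                                     background_offset = c(5, -3, 2))
  mask <- static_tissue_mask(img_off, lum, margin = 5)
  img_corr <- correct_background_offset(img_off, mask)
  img_clean$corrected <- TRUE
  w_clean <- compute_wss_map(lum, img_clean, dm)
  w_corr <- compute_wss_map(lum, img_corr, dm)
  rel <- abs(as.numeric(w_corr) - as.numeric(w_clean)) /
    pmax(as.numeric(w_clean), 0.05)
  expect_lt(stats::median(rel), 0.02)
})
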
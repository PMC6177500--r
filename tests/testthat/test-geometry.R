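test_that("wall thickness on concentric cylinders equals the radius gap", {
  lum <- make_cylinder(r = 3, len = 12)
  out <- make_cylinder(r = 4, len = 12)
  wt <- compute_wall_thickness(lum, out)
  tol <- 0.02 * 1 + mean_edge_length(out)
  expect_true(all(abs(as.numeric(wt) - 1) <= tol))
  # chordal faceting can only shrink the distance, never grow it
  expect_true(all(as.numeric(wt) <= 1 + 1e-9))
})

test_that("degenerate outer wall (zero distance) is rejected", {
  lum <- make_cylinder(r = 3, len = 12)
  expect_error(compute_wall_thickness(lum, lum), "intersects or touches")
})

test_that("wall thickness matches the generator truth on synthetic subjects", {
  cfg <- small_config(n_subjects = 2L, seed = 31)
  subs <- generate_cohort(cfg, velocity = FALSE)
  s <- subs[[2]]
  wt <- compute_wall_thickness(s$lumen, s$outer_wall)
  err <- abs(as.numeric(wt) - as.numeric(s$truth$wt))
  expect_true(all(err <= 0.02 * as.numeric(s$truth$wt) +
                    mean_edge_length(s$lumen)))
})

test_that("centerline of a straight cylinder recovers the axis and radius", {
  lum <- make_cylinder(r = 3, len = 12)
  cl <- compute_centerline(lum)
  expect_length(cl$paths, 1L)
  p <- cl$paths[[1]]
  expect_lt(max(sqrt(rowSums(p$points[, 1:2, drop = FALSE]^2))), 0.2)
  expect_true(all(abs(p$radius - 3) <= 0.15))
})

test_that("centerline of a bent tube keeps the inscribed radius constant", {
  tor <- make_torus_tube(r = 3, bend = 20)
  cl <- compute_centerline(tor)
  p <- cl$paths[[1]]
  expect_true(all(abs(p$radius / 3 - 1) <= 0.05))
  # path stays near the bend circle
  dev <- abs(sqrt(p$points[, 1]^2 + p$points[, 3]^2) - 20)
  expect_lt(stats::median(dev), 0.35)
})

test_that("bifurcation centerline returns one path per outlet", {
  cfg <- small_config(n_subjects = 2L, seed = 17)
  lum <- generate_cohort(cfg, velocity = FALSE)[[1]]$lumen
  cl <- compute_centerline(lum)
  expect_length(cl$paths, 2L)
  expect_setequal(vapply(cl$paths, `[[`, character(1), "branch"),
                  c("ica", "eca"))
  # both paths share the CCA inlet
  expect_equal(cl$paths[[1]]$points[1, ], cl$paths[[2]]$points[1, ])
})

test_that("a closed surface has no centerline endpoints", {
  # mesh with < 2 open boundaries cannot define endpoints
  tor <- make_torus_tube(r = 2, bend = 10, arc = 2 * pi * 0.999)
  # close the ring: weld last ring to first by faces
  expect_error(compute_centerline(vessel_mesh(tor$vertices[1:20, ],
                                              cbind(1:18, 2:19, 3:20))),
               "boundary|endpoint")
})

test_that("diameter map of a cylinder is twice the radius", {
  lum <- make_cylinder(r = 3, len = 12)
  d <- compute_diameter_map(lum, compute_centerline(lum))
  expect_true(all(abs(as.numeric(d) - 6) <= 0.05 * 6))
})

test_that("diameter increases monotonically along a tapered tube", {
  # build an explicit cone-ish tube: radius 2 -> 4 along z
  n_circ <- 24L; zs <- seq(0, 20, by = 1)
  phi <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  verts <- do.call(rbind, lapply(zs, function(z) {
    r <- 2 + 2 * z / 20
    cbind(r * cos(phi), r * sin(phi), z)
  }))
  faces <- NULL
  for (i in seq_along(zs)[-length(zs)]) {
    j <- seq_len(n_circ); jn <- c(seq_len(n_circ)[-1], 1L)
    a <- (i - 1L) * n_circ + j; b <- (i - 1L) * n_circ + jn
    c2 <- i * n_circ + jn; d2 <- i * n_circ + j
    faces <- rbind(faces, cbind(a, b, d2), cbind(b, c2, d2))
  }
  tube <- vessel_mesh(verts, faces)
  dm <- compute_diameter_map(tube, compute_centerline(tube))
  z <- tube$vertices[, 3]
  ring_d <- tapply(as.numeric(dm), round(z), mean)
  mid <- ring_d[3:(length(ring_d) - 2)]  # end rings see the cap centroid
  expect_true(all(diff(mid) > 0))
})

test_that("empty centerline is rejected", {
  lum <- make_cylinder(r = 3, len = 12)
  expect_error(compute_diameter_map(lum, structure(list(paths = list()),
                                                   class = "centerline")),
               "empty")
})

test_that("map extractors are invariant to rigid transformation", {
  cfg <- small_config(n_subjects = 2L, seed = 23)
  s <- generate_cohort(cfg, velocity = FALSE)[[1]]
  R <- wallmap:::rotation_about_axis(c(1, 2, 3), 0.7)
  tr <- c(10, -4, 2)
  lum2 <- transform_mesh(s$lumen, R, tr)
  out2 <- transform_mesh(s$outer_wall, R, tr)
  wt1 <- compute_wall_thickness(s$lumen, s$outer_wall)
  wt2 <- compute_wall_thickness(lum2, out2)
  expect_lt(max(abs(as.numeric(wt1) - as.numeric(wt2))), 1e-6)
  d1 <- compute_diameter_map(s$lumen, compute_centerline(s$lumen))
  d2 <- compute_diameter_map(lum2, compute_centerline(lum2))
  expect_lt(max(abs(as.numeric(d1) - as.numeric(d2))), 1e-6)
})

test_that("swapping lumen and outer wall gives consistent branch-mean thickness", {
  cfg <- small_config(n_subjects = 2L, seed = 37)
  s <- generate_cohort(cfg, velocity = FALSE)[[1]]
  wt_fwd <- compute_wall_thickness(s$lumen, s$outer_wall)
  wt_rev <- compute_wall_thickness(s$outer_wall, s$lumen, check = FALSE)
  for (b in c("cca", "ica", "eca")) {
    fwd <- mean(as.numeric(wt_fwd)[s$lumen$branch == b])
    rev <- mean(as.numeric(wt_rev)[s$outer_wall$branch == b])
    expect_lt(abs(fwd - rev) / fwd, 0.1)
  }
})
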
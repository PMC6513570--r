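test_that("MCI and sphericity match analytic shapes exactly", {
  # unit sphere: SA = 4*pi, V = 4*pi/3 -> the isoperimetric floor
  expect_equal(mci(4 * pi, 4 * pi / 3), 9 / (4 * pi), tolerance = 1e-12)
  expect_equal(sphericity(4 * pi, 4 * pi / 3), 1, tolerance = 1e-12)

  # capsule r = 1, L = 10: SA = 24*pi, V = 34*pi/3
  sa <- capsule_sa(1, 10); v <- capsule_v(1, 10)
  expect_equal(sa, 24 * pi)
  expect_equal(v, 34 * pi / 3)
  expect_equal(mci(sa, v), 2.1412, tolerance = 1e-4)
  expect_equal(sphericity(sa, v), 0.6942, tolerance = 1e-4)

  expect_error(mci(-1, 1), "positive")
  expect_error(mci(1, 0), "positive")
  expect_error(sphericity(0, 1), "positive")
})

test_that("MCI is exactly scale-invariant and tied to sphericity", {
  set.seed(42)
  for (i in 1:20) {
    sa <- exp(runif(1, -2, 8)); v <- exp(runif(1, -2, 8))
    for (cc in c(0.1, 10, 1e3))
      expect_equal(mci(cc^2 * sa, cc^3 * v), mci(sa, v),
                   tolerance = 1e-12)
    # mci * sphericity^3 = 9/(4*pi), an algebraic identity
    expect_equal(mci(sa, v) * sphericity(sa, v)^3, 9 / (4 * pi),
                 tolerance = 1e-12)
  }
})

test_that("organelle extraction follows 26-connectivity and border rules", {
  a <- array(0L, c(8, 8, 5))
  a[2:3, 2:3, 2] <- 1L          # blob 1 of label 1
  a[6:7, 6:7, 4] <- 1L          # blob 2 of the same label
  vol <- labeled_volume(a)
  oset <- extract_organelles(vol, min_voxels = 1)
  expect_equal(nrow(oset$table), 2L)

  # diagonal contact merges into one organelle
  b <- array(0L, c(6, 6, 6))
  b[2, 2, 2] <- 1L
  b[3, 3, 3] <- 1L
  expect_equal(nrow(extract_organelles(labeled_volume(b),
                                       min_voxels = 1)$table), 1L)

  # border-touching components are flagged and excludable
  d <- array(0L, c(6, 6, 6))
  d[1:2, 3, 3] <- 1L
  d[4:5, 4, 4] <- 2L
  vol <- labeled_volume(d)
  all_of <- extract_organelles(vol, min_voxels = 1)
  expect_equal(all_of$table$touches_border, c(TRUE, FALSE))
  kept <- extract_organelles(vol, exclude_border = TRUE, min_voxels = 1)
  expect_equal(nrow(kept$table), 1L)
  expect_equal(kept$table$label, 2L)

  expect_warning(
    empty <- extract_organelles(labeled_volume(array(0L, c(3, 3, 3)))),
    "empty")
  expect_equal(nrow(empty$table), 0L)
})

test_that("voxel volume is count times voxel cell volume", {
  m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
  expect_equal(voxel_volume(m, c(10, 10, 30)), 24000)
})

test_that("meshed spheres and capsules track analytic SA and V", {
  r <- 500
  vol <- sphere_volume(r)
  got <- measure_phantom(vol)
  expect_true(mesh_is_closed(got$mesh))
  expect_lt(rel_err(got$sa, sphere_sa(r)), 0.02)
  expect_lt(rel_err(got$v, sphere_v(r)), 0.02)

  cap <- capsule_volume(300, 2000)
  gotc <- measure_phantom(cap)
  expect_lt(rel_err(gotc$sa, capsule_sa(300, 2000)), 0.02)
  expect_lt(rel_err(gotc$v, capsule_v(300, 2000)), 0.02)
})

test_that("mesh refinement converges toward analytic values", {
  r <- 400
  coarse <- measure_phantom(sphere_volume(r, voxel_size = c(20, 20, 60)))
  fine <- measure_phantom(sphere_volume(r, voxel_size = c(10, 10, 30)))
  expect_lt(rel_err(fine$sa, sphere_sa(r)),
            rel_err(coarse$sa, sphere_sa(r)) + 1e-12)
  expect_lt(rel_err(fine$v, sphere_v(r)),
            rel_err(coarse$v, sphere_v(r)) + 1e-12)
  # refining the grid 2x moves SA by little
  expect_lt(rel_err(fine$sa, coarse$sa), 0.03)
})

test_that("a single voxel still meshes closed with positive volume", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  mesh <- mesh_from_mask(m, c(10, 10, 30))
  expect_true(mesh_is_closed(mesh))
  v <- mesh_volume(mesh)
  expect_gt(v, 0)
  # the contour of an isolated grid point encloses about half the voxel
  expect_gt(v, 0.3 * 3000)
  expect_lt(v, 3000)
  expect_error(mesh_from_mask(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("mesh volume is positive regardless of face orientation", {
  tet <- surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
  flipped <- surface_mesh(tet$vertices, tet$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), mesh_volume(tet))
  expect_gt(mesh_volume(flipped), 0)
})

test_that("the morphometry pipeline measures phantoms end to end", {
  vx <- c(20, 20, 40)
  # three spheres under one roof, distinct labels
  specs <- list(c(r = 300), c(r = 350), c(r = 400))
  dims <- c(80, 80, 45)
  a <- array(0L, dims)
  centers <- list(c(20, 20, 12), c(20, 58, 30), c(58, 40, 16))
  for (q in seq_along(specs)) {
    r <- specs[[q]][["r"]]
    cc <- centers[[q]]
    ii <- ((seq_len(dims[1]) - cc[1]) * vx[1])^2
    jj <- ((seq_len(dims[2]) - cc[2]) * vx[2])^2
    kk <- ((seq_len(dims[3]) - cc[3]) * vx[3])^2
    m <- outer(outer(ii, jj, "+"), kk, "+") <= r^2
    a[m] <- q
  }
  vol <- labeled_volume(a, vx)
  cfg <- default_config(); cfg$voxel_size <- vx
  met <- compute_morphometrics(vol, config = cfg)
  expect_equal(nrow(met), 3L)
  expect_true(all(met$ok))
  expect_true(all(abs(met$mci - 9 / (4 * pi)) / (9 / (4 * pi)) < 0.02))
  expect_true(all(met$sphericity > 0.97 & met$sphericity < 1.01))

  # a capsule is more complex than a sphere
  cap <- capsule_volume(200, 1500, voxel_size = vx)
  capm <- compute_morphometrics(cap, config = cfg)
  expect_gt(capm$mci[1], max(met$mci))

  # per-organelle units are um^3 / um^2 and agree with the voxel count
  expect_equal(met$volume_um3, met$voxel_volume_um3, tolerance = 0.1)
  expect_true(all(met$volume_um3 > 0.05 & met$volume_um3 < 0.5))
})

test_that("border exclusion drops rows from the pipeline", {
  vx <- c(20, 20, 40)
  a <- array(0L, c(50, 50, 30))
  a[1:8, 5:13, 10:18] <- 1L        # touches the x = 1 face
  ii <- ((seq_len(50) - 30) * vx[1])^2
  jj <- ((seq_len(50) - 30) * vx[2])^2
  kk <- ((seq_len(30) - 15) * vx[3])^2
  a[outer(outer(ii, jj, "+"), kk, "+") <= 250^2] <- 2L
  vol <- labeled_volume(a, vx)
  cfg <- default_config(); cfg$voxel_size <- vx
  met_all <- suppressWarnings(compute_morphometrics(vol, config = cfg))
  cfg$exclude_border <- TRUE
  met_inner <- suppressWarnings(compute_morphometrics(vol,
                                                      config = cfg))
  expect_equal(nrow(met_all) - nrow(met_inner), 1L)
  expect_false(any(met_inner$touches_border))
})
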
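test_that("trimesh validation catches bad input", {
  v <- matrix(rnorm(9), 3, 3)
  expect_error(trimesh(v, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(trimesh(v, matrix(c(1, 1, 2), 1)), "degenerate")
})

test_that("sphere mesh minimum height converges to the analytic bottom", {
  geo <- gen_implant_geometry(condyle_radius = 25, intercondylar_distance = 49,
                              n_seg = 24L)
  min_h <- min(geo$femur$vertices[, 2])
  expect_equal(min_h, geo$params$bottom_height, tolerance = 0.5)
  err24 <- abs(min_h - geo$params$bottom_height)
  geo48 <- gen_implant_geometry(condyle_radius = 25,
                                intercondylar_distance = 49, n_seg = 48L)
  err48 <- abs(min(geo48$femur$vertices[, 2]) - geo48$params$bottom_height)
  expect_lt(err48, err24)   # refinement reduces the discretization error
})

test_that("low points equal the brute-force vertex minimum per condyle", {
  set.seed(7)
  geo <- gen_implant_geometry(n_seg = 16L)
  p <- pose(rot_z(-20), c(3, 1, -2))
  tray <- tray_frame(origin = c(0, -1, 0), anterior = c(1, 0, 0),
                     up = c(0, 1, 0), medial_hint = c(0, 0, 1))
  lp <- low_points(geo$femur, p, tray)
  pts <- pose_apply(p, geo$femur$vertices)
  tc <- kneebc:::tray_coords(tray, pts)
  med <- tc[, "ml"] > 0
  expect_equal(lp$height_medial, min(tc[med, "height"]))
  expect_equal(lp$height_lateral, min(tc[!med, "height"]))
  im <- which(med)[which.min(tc[med, "height"])]
  expect_equal(lp$medial_ap, unname(tc[im, "ap"]))
})

test_that("posed spheres give analytic low points and translation equivariance", {
  geo <- gen_implant_geometry(condyle_radius = 25, intercondylar_distance = 49,
                              n_seg = 64L)
  tray <- tray_frame(medial_hint = c(0, 0, 1))
  lp0 <- low_points(geo$femur, pose(), tray)
  # analytic bottoms: (ap, ml) = (0, +/-24.5), height 0; mesh resolution
  # limits the agreement
  tol <- 25 * (pi / 32)            # chord error bound at this refinement
  expect_lt(abs(lp0$medial_ap), tol)
  expect_lt(abs(lp0$medial_ml - 24.5), tol)
  expect_lt(abs(lp0$height_medial), tol)
  shifted <- low_points(geo$femur, pose(diag(3), c(5, 0, 0)), tray)
  expect_equal(shifted$medial_ap, lp0$medial_ap + 5, tolerance = 1e-10)
  expect_equal(shifted$lateral_ap, lp0$lateral_ap + 5, tolerance = 1e-10)
  expect_equal(shifted$height_medial, lp0$height_medial, tolerance = 1e-10)
})

test_that("an empty condyle partition is an error", {
  geo <- gen_implant_geometry(n_seg = 12L)
  tray <- tray_frame(medial_hint = c(0, 0, 1))
  expect_error(low_points(geo$femur, pose(diag(3), c(0, 0, 200)), tray),
               "empty condyle partition")
})

test_that("STL write/read round trips both dialects", {
  geo <- gen_implant_geometry(n_seg = 8L)
  m <- geo$femur
  for (binary in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, path, binary = binary)
    back <- read_stl(path)
    expect_equal(nrow(back$faces), nrow(m$faces))
    # same triangle soup (vertex welding may renumber)
    orig <- m$vertices[t(m$faces), ]
    got <- back$vertices[t(back$faces), ]
    expect_equal(got, orig, tolerance = 1e-5)  # float32 storage
  }
})

test_that("degenerate implant geometry parameters are rejected", {
  expect_error(gen_implant_geometry(intercondylar_distance = 0), "> 0")
  expect_error(gen_implant_geometry(condyle_radius = -1), "> 0")
  expect_error(gen_implant_geometry(dish_radius = 10, condyle_radius = 25),
               ">=")
})
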
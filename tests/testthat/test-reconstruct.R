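test_that("calibration derives focal lengths from the fields of view", {
  calib <- csl_calibration()
  expect_equal(calib$cam_focal_px,
               (3328 / 2) / tan(78.7 * pi / 360), tolerance = 1e-12)
  expect_equal(calib$proj_focal_px,
               (1920 / 2) / tan(42.5 * pi / 360), tolerance = 1e-12)
  expect_error(csl_calibration(baseline_cm = 0), "positive")
})

test_that("principal-point rays run along the optical axes", {
  calib <- csl_calibration(convergence_deg = 0)
  cam <- pixel_to_ray("camera", calib$cam_pp, calib)
  expect_equal(unname(cam$dir[1, ]), c(0, 0, 1), tolerance = 1e-12)
  expect_identical(cam$origin, c(0, 0, 0))
  prj <- pixel_to_ray("projector", calib$proj_pp, calib)
  expect_equal(unname(prj$dir[1, ]), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(prj$origin, c(53.4, 0, 0))
  expect_error(pixel_to_ray("camera", c(-5, 10), calib), "outside")
})

test_that("the sensor edge subtends exactly half the field of view", {
  calib <- csl_calibration(convergence_deg = 0)
  edge <- pixel_to_ray("camera", cbind(3327.5, calib$cam_pp[2L]), calib)
  ang <- atan2(edge$dir[1, 1L], edge$dir[1, 3L]) * 180 / pi
  expect_lt(abs(ang - 78.7 / 2), 1e-6)
  pedge <- pixel_to_ray("projector", cbind(-0.5, calib$proj_pp[2L]), calib)
  pang <- atan2(pedge$dir[1, 1L], pedge$dir[1, 3L]) * 180 / pi
  expect_lt(abs(pang + 42.5 / 2), 1e-6)
})

test_that("projection and back-projection are mutually inverse", {
  calib <- csl_calibration()
  set.seed(12)
  px <- cbind(runif(50, 0, 3327), runif(50, 0, 2495))
  cam <- pixel_to_ray("camera", px, calib)
  pts <- cam$dir * runif(50, 50, 100)
  expect_equal(project_to_pixels("camera", pts, calib), unname(px),
               tolerance = 1e-9, ignore_attr = TRUE)
  ppx <- cbind(runif(50, 0, 1919), runif(50, 0, 1079))
  prj <- pixel_to_ray("projector", ppx, calib)
  pts2 <- sweep(prj$dir * runif(50, 50, 100), 2, prj$origin, "+")
  expect_equal(project_to_pixels("projector", pts2, calib), unname(ppx),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("exact plane correspondences triangulate to the plane depth", {
  p <- test_pattern_small()
  calib <- csl_calibration()
  sc <- render_scene(scene_config("plane", snr_db = Inf, blur_sigma_px = 0),
                     p, calib)
  gt <- sc$gt_correspondences
  corr <- data.frame(pattern_x = gt$pattern_x, pattern_y = gt$pattern_y,
                     image_x = gt$image_x, image_y = gt$image_y)
  cloud <- triangulate_correspondences(corr, calib)
  expect_identical(nrow(cloud$points), nrow(gt))
  expect_lt(max(abs(cloud$points[, 3L] - 72)), 1e-6)
  expect_lt(max(cloud$skew_cm), 1e-9)
})

test_that("depth error from centroid noise is bounded and monotone", {
  p <- test_pattern_small()
  calib <- csl_calibration()
  sc <- render_scene(scene_config("plane", snr_db = Inf, blur_sigma_px = 0),
                     p, calib)
  gt <- sc$gt_correspondences
  rmse <- vapply(c(0, 0.5, 1, 2), function(s) {
    set.seed(13)
    corr <- data.frame(pattern_x = gt$pattern_x, pattern_y = gt$pattern_y,
                       image_x = gt$image_x + rnorm(nrow(gt), 0, s),
                       image_y = gt$image_y + rnorm(nrow(gt), 0, s))
    cloud <- triangulate_correspondences(corr, calib)
    sqrt(mean((cloud$points[, 3L] - 72)^2))
  }, 0)
  expect_true(all(diff(rmse) > 0))
  # analytic first-order sensitivity: dz = z^2 / (f_cam * baseline) per px
  bound <- 72^2 / (calib$cam_focal_px * calib$baseline_cm)
  expect_lt(rmse[3L], 1.2 * bound)
})

test_that("near-parallel rays are rejected", {
  calib <- csl_calibration(convergence_deg = 0)
  corr <- data.frame(pattern_x = calib$proj_pp[1L], pattern_y = calib$proj_pp[2L],
                     image_x = calib$cam_pp[1L], image_y = calib$cam_pp[2L])
  cloud <- triangulate_correspondences(corr, calib)
  expect_identical(nrow(cloud$points), 0L)
})

test_that("morphometrics recover known extents and are rotation invariant", {
  ax <- c(15, 5.5, 2)
  u <- seq(-1, 1, length.out = 150)
  g <- expand.grid(x = u, y = u)
  g <- g[g$x^2 + g$y^2 < 1, ]
  pts <- cbind(ax[1] * g$x, ax[2] * g$y,
               74 - ax[3] * sqrt(1 - g$x^2 - g$y^2))
  m <- measure_cloud(pts)
  expect_lt(abs(m$total_length_cm - 30), 0.5)
  expect_lt(abs(m$height_cm - 11), 0.5)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- measure_cloud(pts %*% R)
  expect_equal(m2$total_length_cm, m$total_length_cm, tolerance = 1e-9)
  expect_equal(m2$height_cm, m$height_cm, tolerance = 1e-9)
  # axis-aligned box: exact dimensions
  b <- as.matrix(expand.grid(seq(0, 10, 1), seq(0, 4, 0.5), seq(0, 2, 0.5)))
  mb <- measure_cloud(b)
  expect_equal(mb$total_length_cm, 10, tolerance = 1e-9)
  expect_equal(mb$height_cm, 4, tolerance = 1e-9)
  expect_error(measure_cloud(matrix(1:9, 3, 3)), "at least 10")
  line <- cbind(1:20, 1:20 * 2, 0)
  expect_error(measure_cloud(line), "degenerate")
})

test_that("cloud and calibration files round-trip", {
  pts <- matrix(runif(60), 20, 3)
  d <- withr::local_tempdir()
  ply <- file.path(d, "c.ply"); xyz <- file.path(d, "c.xyz")
  write_ply(pts, ply); write_xyz(pts, xyz)
  lines <- readLines(ply)
  expect_identical(lines[1L], "ply")
  expect_identical(lines[3L], "element vertex 20")
  expect_identical(length(lines), 7L + 20L)
  back <- as.matrix(utils::read.table(xyz))
  expect_equal(unname(back), unname(pts), tolerance = 1e-12)
  yml <- file.path(d, "calib.yaml")
  calib <- csl_calibration(baseline_cm = 40, convergence_deg = 10)
  write_calibration_yaml(calib, yml)
  back2 <- read_calibration_yaml(yml)
  expect_equal(back2$baseline_cm, 40)
  expect_equal(back2$convergence_deg, 10)
  expect_equal(back2$cam_focal_px, calib$cam_focal_px)
})
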
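#' Projector-camera calibration model
#'
#' Pinhole models for both devices in a camera-centred right-handed frame:
#' x right, y down, z along the camera optical axis. The projector sits at
#' `(baseline_cm, 0, 0)` and is yawed ("toed in") towards the camera axis by
#' `convergence_deg`. Focal lengths in pixels follow from the horizontal
#' fields of view: `f = (width / 2) / tan(hfov / 2)`; pixels are square and
#' principal points are the image centres.
#'
#' The default geometry matches the reference capture rig: 53.4 cm
#' baseline, 3328 x 2496 camera at 78.7 degrees hfov, 1920 x 1080 projector
#' at 42.5 degrees hfov, subjects at about 72 cm. The default convergence
#' aims the projector axis at the point of the camera axis at the working
#' distance, so both frusta cover the subject.
#'
#' @param baseline_cm Camera-projector separation in cm.
#' @param cam_resolution,proj_resolution `(width, height)` in pixels.
#' @param cam_hfov_deg,proj_hfov_deg Horizontal fields of view in degrees.
#' @param convergence_deg Projector toe-in towards the camera axis, degrees.
#'   Default aims the projector at the camera axis at `working_distance_cm`.
#' @param working_distance_cm Nominal subject distance used for the default
#'   convergence (cm).
#' @return A `csl_calibration` object.
#' @export
csl_calibration <- function(baseline_cm = 53.4,
                            cam_resolution = c(3328L, 2496L),
                            proj_resolution = c(1920L, 1080L),
                            cam_hfov_deg = 78.7,
                            proj_hfov_deg = 42.5,
                            convergence_deg = NULL,
                            working_distance_cm = 72) {
  if (baseline_cm <= 0) stop("baseline must be positive")
  if (is.null(convergence_deg)) {
    convergence_deg <- atan2(baseline_cm, working_distance_cm) * 180 / pi
  }
  f <- function(res, hfov) (res[1L] / 2) / tan(hfov * pi / 360)
  structure(
    list(baseline_cm = baseline_cm,
         cam_resolution = as.integer(cam_resolution),
         proj_resolution = as.integer(proj_resolution),
         cam_hfov_deg = cam_hfov_deg, proj_hfov_deg = proj_hfov_deg,
         cam_focal_px = f(cam_resolution, cam_hfov_deg),
         proj_focal_px = f(proj_resolution, proj_hfov_deg),
         cam_pp = (cam_resolution - 1) / 2,
         proj_pp = (proj_resolution - 1) / 2,
         convergence_deg = convergence_deg,
         working_distance_cm = working_distance_cm),
    class = "csl_calibration"
  )
}

#' @export
print.csl_calibration <- function(x, ...) {
  cat(sprintf(
    "<csl_calibration> baseline %.1f cm, camera %dx%d (hfov %.1f deg), projector %dx%d (hfov %.1f deg), convergence %.1f deg\n",
    x$baseline_cm, x$cam_resolution[1L], x$cam_resolution[2L], x$cam_hfov_deg,
    x$proj_resolution[1L], x$proj_resolution[2L], x$proj_hfov_deg,
    x$convergence_deg
  ))
  invisible(x)
}

# Yaw matrix mapping projector-local directions to world: local +z goes to
# (-sin a, 0, cos a) for toe-in a towards the camera axis.
.proj_rotation <- function(calib) {
  a <- -calib$convergence_deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3L, 3L, byrow = TRUE)
}

.proj_origin <- function(calib) c(calib$baseline_cm, 0, 0)

#' Back-project pixels of a device into world rays
#'
#' Pixel coordinates are 0-based with pixel centres at integer positions;
#' `x` is the column and `y` the row. Coordinates are continuous over the
#' physical sensor extent `[-0.5, resolution - 0.5]`, so the frustum edge
#' (half a pixel beyond the outermost centre) subtends exactly half the
#' field of view.
#'
#' @param device `"camera"` or `"projector"`.
#' @param px Numeric vector `(x, y)` or n x 2 matrix of pixel coordinates.
#' @param calib A `csl_calibration`.
#' @return List with `origin` (3-vector) and `dir` (n x 3 matrix of unit
#'   direction vectors in the world frame).
#' @export
pixel_to_ray <- function(device = c("camera", "projector"), px, calib) {
  device <- match.arg(device)
  if (is.null(dim(px))) px <- matrix(px, ncol = 2L, byrow = TRUE)
  res <- if (device == "camera") calib$cam_resolution else calib$proj_resolution
  if (any(px[, 1L] < -0.5 | px[, 1L] > res[1L] - 0.5 |
          px[, 2L] < -0.5 | px[, 2L] > res[2L] - 0.5)) {
    stop("pixel outside device resolution")
  }
  f <- if (device == "camera") calib$cam_focal_px else calib$proj_focal_px
  pp <- if (device == "camera") calib$cam_pp else calib$proj_pp
  d <- cbind((px[, 1L] - pp[1L]) / f, (px[, 2L] - pp[2L]) / f, 1)
  if (device == "projector") d <- d %*% t(.proj_rotation(calib))
  d <- d / sqrt(rowSums(d^2))
  origin <- if (device == "camera") c(0, 0, 0) else .proj_origin(calib)
  list(origin = origin, dir = d)
}

#' Project world points into a device's pixel grid
#'
#' Inverse of [pixel_to_ray()] for points in front of the device.
#'
#' @inheritParams pixel_to_ray
#' @param pts n x 3 matrix of world points.
#' @return n x 2 matrix of 0-based `(x, y)` pixel coordinates (not clipped
#'   to the sensor).
#' @export
project_to_pixels <- function(device = c("camera", "projector"), pts, calib) {
  device <- match.arg(device)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  if (device == "projector") {
    pts <- sweep(pts, 2L, .proj_origin(calib)) %*% .proj_rotation(calib)
  }
  f <- if (device == "camera") calib$cam_focal_px else calib$proj_focal_px
  pp <- if (device == "camera") calib$cam_pp else calib$proj_pp
  cbind(x = f * pts[, 1L] / pts[, 3L] + pp[1L],
        y = f * pts[, 2L] / pts[, 3L] + pp[2L])
}

#' Triangulate correspondences into 3D points
#'
#' For each correspondence the camera ray (through the image point) and the
#' projector ray (through the pattern point) are intersected as the midpoint
#' of their common perpendicular segment; the segment length (skew distance)
#' is kept as a per-point quality metric. Near-parallel ray pairs are
#' rejected.
#'
#' @param corr Correspondence data.frame from [extract_correspondences()]
#'   (columns `pattern_x`, `pattern_y`, `image_x`, `image_y`).
#' @param calib A `csl_calibration`.
#' @param max_skew_cm Reject points whose rays pass farther apart than this.
#' @return A `csl_cloud`: list with `points` (n x 3 matrix, cm), `skew_cm`,
#'   and the retained rows of `corr`.
#' @export
triangulate_correspondences <- function(corr, calib, max_skew_cm = 1) {
  if (nrow(corr) == 0L) {
    return(structure(list(points = matrix(0, 0, 3),
                          skew_cm = numeric(0), corr = corr),
                     class = "csl_cloud"))
  }
  cam <- pixel_to_ray("camera", cbind(corr$image_x, corr$image_y), calib)
  prj <- pixel_to_ray("projector", cbind(corr$pattern_x, corr$pattern_y), calib)
  o1 <- cam$origin; o2 <- prj$origin
  pts <- matrix(NA_real_, nrow(corr), 3L)
  skew <- rep(NA_real_, nrow(corr))
  w0 <- o1 - o2
  for (i in seq_len(nrow(corr))) {
    u <- cam$dir[i, ]; v <- prj$dir[i, ]
    b <- sum(u * v)
    denom <- 1 - b^2
    if (denom < 1e-12) next  # near-parallel rays
    d <- sum(u * w0); e <- sum(v * w0)
    s <- (b * e - d) / denom
    t <- (e - b * d) / denom
    p1 <- o1 + s * u
    p2 <- o2 + t * v
    sk <- sqrt(sum((p1 - p2)^2))
    if (s <= 0 || t <= 0 || sk > max_skew_cm) next
    pts[i, ] <- (p1 + p2) / 2
    skew[i] <- sk
  }
  keep <- !is.na(pts[, 1L])
  structure(list(points = pts[keep, , drop = FALSE], skew_cm = skew[keep],
                 corr = corr[keep, , drop = FALSE]),
            class = "csl_cloud")
}

#' @export
print.csl_cloud <- function(x, ...) {
  cat(sprintf("<csl_cloud> %d points", nrow(x$points)))
  if (nrow(x$points) > 0L) {
    cat(sprintf(", depth %.2f..%.2f cm", min(x$points[, 3L]), max(x$points[, 3L])))
  }
  cat("\n")
  invisible(x)
}

#' Morphometric measurements from a point cloud
#'
#' Computes the principal axes of the point set from its covariance and
#' reports the extent (max minus min of the projections) along the first
#' axis as total length and along the second as height. For noisy clouds a
#' trimmed extent (1st-99th percentile) can be requested.
#'
#' @param cloud A `csl_cloud` or an n x 3 matrix of points (n >= 10).
#' @param trim If `TRUE`, use the 1st-99th percentile extent instead of the
#'   full range.
#' @return List with `total_length_cm`, `height_cm` and `axes` (3 x 3
#'   principal axis matrix, columns in decreasing-variance order).
#' @export
measure_cloud <- function(cloud, trim = FALSE) {
  pts <- if (inherits(cloud, "csl_cloud")) cloud$points else cloud
  if (nrow(pts) < 10L) stop("need at least 10 points for morphometrics")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] < 1e-12) stop("degenerate (collinear) point cloud")
  proj <- sweep(pts, 2L, ctr) %*% eg$vectors
  extent <- function(x) {
    if (trim) diff(stats::quantile(x, c(0.01, 0.99), names = FALSE)) else diff(range(x))
  }
  list(total_length_cm = extent(proj[, 1L]),
       height_cm = extent(proj[, 2L]),
       axes = eg$vectors)
}

#' Sparse depth map at decoded symbol positions
#'
#' @param cloud A `csl_cloud` from [triangulate_correspondences()].
#' @return A data.frame with `image_x`, `image_y`, `depth_cm`.
#' @export
depth_map <- function(cloud) {
  data.frame(image_x = cloud$corr$image_x, image_y = cloud$corr$image_y,
             depth_cm = cloud$points[, 3L])
}

#' Render a sparse depth map to a colour PNG with a colour bar
#'
#' @param dm Depth map from [depth_map()].
#' @param path Output PNG path.
#' @param size `(width, height)` of the output image in pixels; defaults to
#'   the extent of the depth samples.
#' @param dot Radius of the dot drawn per sample, pixels.
#' @return The depth range mapped onto the colour scale, invisibly.
#' @export
write_depth_map_png <- function(dm, path, size = NULL, dot = 3L) {
  if (nrow(dm) == 0L) stop("empty depth map")
  if (is.null(size)) {
    size <- c(ceiling(max(dm$image_x)) + 10L, ceiling(max(dm$image_y)) + 10L)
  }
  bar_w <- 24L
  w <- size[1L] + bar_w + 8L; h <- size[2L]
  img <- array(0, dim = c(h, w, 3L))
  zr <- range(dm$depth_cm)
  pal <- grDevices::colorRamp(c("blue", "cyan", "green", "yellow", "red"))
  rel <- if (diff(zr) > 0) (dm$depth_cm - zr[1L]) / diff(zr) else rep(0.5, nrow(dm))
  cols <- pal(rel) / 255
  for (i in seq_len(nrow(dm))) {
    r0 <- max(1L, round(dm$image_y[i]) - dot); r1 <- min(h, round(dm$image_y[i]) + dot)
    c0 <- max(1L, round(dm$image_x[i]) - dot); c1 <- min(size[1L], round(dm$image_x[i]) + dot)
    for (ch in 1:3) img[r0:r1, c0:c1, ch] <- cols[i, ch]
  }
  bar <- pal(seq(1, 0, length.out = h)) / 255
  for (ch in 1:3) img[, (size[1L] + 9L):(size[1L] + 8L + bar_w), ch] <- bar[, ch]
  png::writePNG(img, path)
  invisible(zr)
}

#' Write a point cloud as ASCII PLY
#'
#' @param cloud A `csl_cloud` or n x 3 matrix.
#' @param path Output path.
#' @export
write_ply <- function(cloud, path) {
  pts <- if (inherits(cloud, "csl_cloud")) cloud$points else cloud
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(pts, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a point cloud as whitespace-separated XYZ
#'
#' @inheritParams write_ply
#' @export
write_xyz <- function(cloud, path) {
  pts <- if (inherits(cloud, "csl_cloud")) cloud$points else cloud
  utils::write.table(pts, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read calibration as YAML
#'
#' @param calib A `csl_calibration`.
#' @param path File path.
#' @export
write_calibration_yaml <- function(calib, path) {
  yaml::write_yaml(unclass(calib)[c("baseline_cm", "cam_resolution",
                                    "proj_resolution", "cam_hfov_deg",
                                    "proj_hfov_deg", "convergence_deg",
                                    "working_distance_cm")], path)
  invisible(path)
}

#' @rdname write_calibration_yaml
#' @export
read_calibration_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  csl_calibration(baseline_cm = y$baseline_cm,
                  cam_resolution = y$cam_resolution,
                  proj_resolution = y$proj_resolution,
                  cam_hfov_deg = y$cam_hfov_deg,
                  proj_hfov_deg = y$proj_hfov_deg,
                  convergence_deg = y$convergence_deg,
                  working_distance_cm = y$working_distance_cm)
}
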
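#' Synthetic capture-scene configuration
#'
#' Describes a parametric surface in front of the projector-camera rig plus
#' the degradations applied to the rendered camera view. Defaults emulate
#' the reference capture conditions: subject at about 72 cm, image SNR in
#' the 13-16 dB band, mild blur, moderate scene contrast (ambient light
#' lifts the background and limits projector contrast on a matte surface).
#'
#' @param surface `"plane"` (fronto-parallel at `depth_cm`) or
#'   `"ellipsoid"` (fusiform stand-in).
#' @param depth_cm Nominal distance of the surface from the camera (cm).
#'   For the ellipsoid this is the depth of its front face.
#' @param ellipsoid_semiaxes_cm Semi-axes `(a, b, c)` along `(x, y, z)` in
#'   cm; the default (15, 5.5, 2) matches a fish of about 30 cm total
#'   length and 11 cm height.
#' @param pose Optional list with `center` (3-vector, cm; default centred on
#'   the camera axis with the front face at `depth_cm`) and `roll_deg`
#'   (rotation of the semi-axes about the camera axis).
#' @param snr_db Target signal-to-noise ratio of the camera image in dB,
#'   defined as `10 log10(var(signal) / var(noise))` with the noiseless
#'   render as signal; `Inf` disables noise. Default 14, inside the
#'   observed 13-16 dB capture band.
#' @param blur_sigma_px Gaussian optical blur sigma in camera pixels.
#' @param illumination_gradient Multiplicative left-to-right ramp: the right
#'   edge is this factor brighter than the left edge (1 = uniform).
#' @param fg_level,bg_level Scene radiance (8-bit) of illuminated symbol and
#'   background surface before ramp/blur/noise.
#' @param seed Integer; all simulator randomness derives from it.
#' @return A `csl_scene_config`.
#' @export
scene_config <- function(surface = c("plane", "ellipsoid"),
                         depth_cm = 72,
                         ellipsoid_semiaxes_cm = c(15, 5.5, 2),
                         pose = NULL,
                         snr_db = 14,
                         blur_sigma_px = 1,
                         illumination_gradient = 1,
                         fg_level = 180, bg_level = 45,
                         seed = 0L) {
  surface <- match.arg(surface)
  if (!is.infinite(snr_db) && snr_db <= 0) stop("snr_db must be positive")
  if (is.null(pose)) pose <- list()
  if (is.null(pose$roll_deg)) pose$roll_deg <- 0
  if (is.null(pose$center)) {
    pose$center <- c(0, 0, depth_cm + ellipsoid_semiaxes_cm[3L])
  }
  structure(
    list(surface = surface, depth_cm = depth_cm,
         ellipsoid_semiaxes_cm = ellipsoid_semiaxes_cm, pose = pose,
         snr_db = snr_db, blur_sigma_px = blur_sigma_px,
         illumination_gradient = illumination_gradient,
         fg_level = fg_level, bg_level = bg_level,
         seed = as.integer(seed)),
    class = "csl_scene_config"
  )
}

# First intersection of rays (origin o, directions D: n x 3) with the
# configured surface. Returns n-vector of ray parameters t (NA = miss).
.surface_hit <- function(config, o, D) {
  if (config$surface == "plane") {
    t <- (config$depth_cm - o[3L]) / D[, 3L]
    t[t <= 0] <- NA_real_
    return(t)
  }
  ax <- config$ellipsoid_semiaxes_cm
  ctr <- config$pose$center
  a <- config$pose$roll_deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3L, 3L,
              byrow = TRUE)  # roll about the camera axis
  # into ellipsoid frame, scaled to the unit sphere
  os <- as.vector(R %*% (o - ctr)) / ax
  Ds <- sweep(D %*% t(R), 2L, ax, "/")
  A <- rowSums(Ds^2)
  B <- 2 * (Ds %*% os)[, 1L]
  C <- sum(os^2) - 1
  disc <- B^2 - 4 * A * C
  t <- rep(NA_real_, nrow(D))
  ok <- disc >= 0
  sq <- sqrt(disc[ok])
  t1 <- (-B[ok] - sq) / (2 * A[ok])
  t2 <- (-B[ok] + sq) / (2 * A[ok])
  tt <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, NA_real_))
  t[ok] <- tt
  t
}

#' Render a synthetic camera view of the projected pattern
#'
#' Inverse rendering: each camera pixel is back-projected to the surface;
#' the hit point is projected into the projector and, if it is illuminated
#' (not self-shadowed), the pattern raster is sampled there. Foreground is
#' shaded `fg_level`, everything else `bg_level`; then the illumination
#' ramp, Gaussian blur and additive Gaussian noise (scaled to the target
#' SNR) are applied. Exact ground truth (per-symbol correspondences and
#' per-pixel depth) is computed from the same geometry.
#'
#' Rendering is restricted to a camera-frame region of interest (ROI)
#' bounding the projected pattern plus `crop_margin_px`; ground-truth and
#' correspondence coordinates are reported in full-frame pixels and the ROI
#' offset is stored in the scene.
#'
#' @param config A `csl_scene_config`.
#' @param pattern A `csl_pattern`.
#' @param calib A `csl_calibration`.
#' @param crop_margin_px Margin around the projected pattern's camera-frame
#'   bounding box (pixels); keep it below half the binarization window so
#'   local statistics at the ROI edge still mix the two populations.
#' @param crop If `FALSE`, render the full camera frame.
#' @return A `csl_scene`: list with `camera_image` (ROI, 0..255), `clean`
#'   (noiseless ROI render), `roi` (0-based `(x0, y0)` full-frame offset),
#'   `gt_correspondences` (data.frame: grid `row`/`col`, `class`,
#'   `pattern_x/y`, `image_x/y` full-frame, `depth_cm`, `interior`),
#'   `gt_depth` (ROI matrix, NA where no surface), `measured_snr_db`,
#'   `config`, `calib`.
#' @export
render_scene <- function(config, pattern, calib, crop_margin_px = 12L,
                         crop = TRUE) {
  pres <- calib$proj_resolution
  canvas <- render_pattern(pattern, pres[1L], pres[2L])
  ppts <- pattern_centroids(pattern, pres[1L], pres[2L])

  # ground-truth correspondences: projector ray through each symbol centroid
  prj <- pixel_to_ray("projector", cbind(ppts$x, ppts$y), calib)
  t_sym <- .surface_hit(config, prj$origin, prj$dir)
  hit <- !is.na(t_sym)
  P <- sweep(prj$dir * t_sym, 2L, prj$origin, "+")
  cam_px <- matrix(NA_real_, nrow(ppts), 2L)
  vis <- hit
  if (any(hit)) {
    cam_px[hit, ] <- project_to_pixels("camera", P[hit, , drop = FALSE], calib)
    if (config$surface == "ellipsoid") {
      # camera-side occlusion: the camera ray to the point must hit it first
      dirs <- P[hit, , drop = FALSE]
      nd <- dirs / sqrt(rowSums(dirs^2))
      t_cam <- .surface_hit(config, c(0, 0, 0), nd)
      vis[hit] <- abs(t_cam - sqrt(rowSums(dirs^2))) < 1e-6
    }
    inframe <- hit & cam_px[, 1L] >= 0 & cam_px[, 1L] <= calib$cam_resolution[1L] - 1 &
      cam_px[, 2L] >= 0 & cam_px[, 2L] <= calib$cam_resolution[2L] - 1
    vis <- vis & inframe
  }
  gt <- data.frame(row = ppts$row, col = ppts$col, class = ppts$class,
                   pattern_x = ppts$x, pattern_y = ppts$y,
                   image_x = cam_px[, 1L], image_y = cam_px[, 2L],
                   depth_cm = P[, 3L])[vis, , drop = FALSE]
  if (nrow(gt) == 0L) stop("surface outside both frusta: no symbol is visible")
  rendered <- paste(gt$row, gt$col)
  neigh_ok <- function(r, cc) {
    all(paste(rep(r + (-1:1), each = 3), rep(cc + (-1:1), times = 3)) %in% rendered)
  }
  gt$interior <- mapply(neigh_ok, gt$row, gt$col)

  cres <- calib$cam_resolution
  if (crop) {
    x0 <- max(0L, floor(min(gt$image_x)) - crop_margin_px)
    y0 <- max(0L, floor(min(gt$image_y)) - crop_margin_px)
    x1 <- min(cres[1L] - 1L, ceiling(max(gt$image_x)) + crop_margin_px)
    y1 <- min(cres[2L] - 1L, ceiling(max(gt$image_y)) + crop_margin_px)
  } else {
    x0 <- 0L; y0 <- 0L; x1 <- cres[1L] - 1L; y1 <- cres[2L] - 1L
  }
  W <- x1 - x0 + 1L; H <- y1 - y0 + 1L

  # inverse render of the ROI
  px <- cbind(rep(x0:x1, each = H), rep(y0:y1, times = W))
  cam <- pixel_to_ray("camera", px, calib)
  t_hit <- .surface_hit(config, cam$origin, cam$dir)
  Phit <- cam$dir * t_hit
  img <- matrix(config$bg_level, H, W)
  depth <- matrix(NA_real_, H, W)
  ok <- !is.na(t_hit)
  depth[ok[seq_len(H * W)]] <- Phit[ok, 3L]
  if (any(ok)) {
    proj_px <- project_to_pixels("projector", Phit[ok, , drop = FALSE], calib)
    xi <- round(proj_px[, 1L]); yi <- round(proj_px[, 2L])
    inp <- xi >= 0 & xi < pres[1L] & yi >= 0 & yi < pres[2L]
    lit <- inp
    if (config$surface == "ellipsoid" && any(inp)) {
      # projector-side shadowing
      pd <- sweep(Phit[ok, , drop = FALSE][inp, , drop = FALSE], 2L,
                  .proj_origin(calib))
      dist <- sqrt(rowSums(pd^2))
      t_pr <- .surface_hit(config, .proj_origin(calib), pd / dist)
      lit[inp] <- abs(t_pr - dist) < 1e-6
    }
    fgval <- rep(0, sum(ok))
    sel <- which(lit)
    fgval[sel] <- canvas[cbind(yi[sel] + 1L, xi[sel] + 1L)]
    v <- img[ok[seq_len(H * W)]]
    v[fgval > 0] <- config$fg_level
    img[ok[seq_len(H * W)]] <- v
  }

  g <- config$illumination_gradient
  if (g != 1) {
    ramp <- seq(1 / g, 1, length.out = W)
    img <- sweep(img, 2L, ramp, "*")
  }
  if (config$blur_sigma_px > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = config$blur_sigma_px,
                                             boundary = "replicate"))
  }
  clean <- img
  measured_snr <- Inf
  if (is.finite(config$snr_db)) {
    sd_sig <- stats::sd(clean)
    sd_noise <- sd_sig / 10^(config$snr_db / 20)
    noise <- .with_seed(config$seed, matrix(stats::rnorm(H * W, 0, sd_noise), H, W))
    img <- clean + noise
    measured_snr <- 10 * log10(stats::var(as.vector(clean)) /
                               stats::var(as.vector(noise)))
  }
  img <- pmin(pmax(img, 0), 255)

  structure(
    list(camera_image = img, clean = clean, roi = c(x0 = x0, y0 = y0),
         gt_correspondences = gt, gt_depth = depth,
         measured_snr_db = measured_snr,
         config = config, calib = calib, pattern = pattern),
    class = "csl_scene"
  )
}

#' @export
print.csl_scene <- function(x, ...) {
  cat(sprintf(
    "<csl_scene> %s at %.0f cm; ROI %d x %d px at (%d, %d); %d ground-truth symbols; SNR %.1f dB\n",
    x$config$surface, x$config$depth_cm,
    ncol(x$camera_image), nrow(x$camera_image), x$roi[["x0"]], x$roi[["y0"]],
    nrow(x$gt_correspondences), x$measured_snr_db
  ))
  invisible(x)
}

#' Score a reconstruction against scene ground truth
#'
#' A decoded symbol is a true match when its pattern grid position equals
#' the ground-truth grid position of the nearest ground-truth symbol in the
#' image (within half a symbol pitch), and a false match otherwise.
#'
#' @param result A `csl_result` from [reconstruct_image()].
#' @param scene The `csl_scene` the result was computed from.
#' @return List of metrics: `decode_rate` (decoded true symbols over
#'   rendered symbols), `interior_decode_rate` (same, over symbols whose
#'   full 3x3 neighbourhood is rendered), `false_match_rate` (false matches
#'   over decoded symbols), `mean_centroid_err_px`, `depth_rmse_cm`,
#'   `n_decoded`.
#' @export
evaluate_scene <- function(result, scene) {
  gt <- scene$gt_correspondences
  corr <- result$correspondences
  # camera-frame half pitch: use the ground-truth nearest-neighbour spacing
  d <- as.matrix(stats::dist(gt[, c("image_x", "image_y")]))
  diag(d) <- Inf
  half_pitch <- stats::median(apply(d, 1L, min)) / 2
  n_true <- 0L; n_false <- 0L
  errs <- numeric(0); derr <- numeric(0)
  if (nrow(corr) > 0L) {
    for (i in seq_len(nrow(corr))) {
      dx <- gt$image_x - corr$image_x[i]
      dy <- gt$image_y - corr$image_y[i]
      j <- which.min(dx^2 + dy^2)
      dist_px <- sqrt(dx[j]^2 + dy[j]^2)
      if (dist_px <= half_pitch && gt$row[j] == corr$grid_row[i] &&
          gt$col[j] == corr$grid_col[i]) {
        n_true <- n_true + 1L
        errs <- c(errs, dist_px)
        if (!is.null(result$cloud) && i <= nrow(corr)) {
          k <- which(result$cloud$corr$component == corr$component[i])
          if (length(k) == 1L) {
            derr <- c(derr, result$cloud$points[k, 3L] - gt$depth_cm[j])
          }
        }
      } else {
        n_false <- n_false + 1L
      }
    }
  }
  matched_interior <- 0L
  if (nrow(corr) > 0L) {
    key_gt <- paste(gt$row, gt$col)
    key_corr <- paste(corr$grid_row, corr$grid_col)
    matched_interior <- sum(key_gt[gt$interior] %in% key_corr)
  }
  list(
    decode_rate = n_true / nrow(gt),
    interior_decode_rate = if (any(gt$interior)) {
      matched_interior / sum(gt$interior)
    } else NA_real_,
    false_match_rate = if (nrow(corr) > 0L) n_false / nrow(corr) else NA_real_,
    mean_centroid_err_px = if (length(errs)) mean(errs) else NA_real_,
    depth_rmse_cm = if (length(derr)) sqrt(mean(derr^2)) else NA_real_,
    n_decoded = nrow(corr)
  )
}

#' Save a rendered scene to a directory
#'
#' Writes `camera_image.png`, `gt_depth.csv`, `gt_correspondences.csv` and
#' `config.yaml`.
#'
#' @param scene A `csl_scene`.
#' @param dir Output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_png(scene$camera_image, file.path(dir, "camera_image.png"))
  utils::write.csv(scene$gt_correspondences,
                   file.path(dir, "gt_correspondences.csv"), row.names = FALSE)
  utils::write.csv(scene$gt_depth, file.path(dir, "gt_depth.csv"),
                   row.names = FALSE)
  cfg <- unclass(scene$config)
  cfg$roi <- as.list(scene$roi)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
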
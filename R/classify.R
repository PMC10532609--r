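#' Normalized sum of absolute differences between two binary rasters
#'
#' The SAD between the rasters is divided by the larger of the two
#' foreground (white pixel) counts, giving a dissimilarity in `[0, 2]`:
#' 0 for identical rasters, 2 for disjoint rasters of equal area. Rasters
#' of unequal size are first centred on a common background canvas.
#'
#' @param X,Y Binary rasters (0/1 or logical matrices), not both empty.
#' @return Numeric dissimilarity in `[0, 2]`.
#' @export
normalized_sad <- function(X, Y) {
  X <- X * 1; Y <- Y * 1
  fx <- sum(X); fy <- sum(Y)
  if (fx == 0 && fy == 0) stop("normalized SAD undefined for two empty rasters")
  if (!all(dim(X) == dim(Y))) {
    h <- max(nrow(X), nrow(Y)); w <- max(ncol(X), ncol(Y))
    X <- .pad_center(X, h, w)
    Y <- .pad_center(Y, h, w)
  }
  sum(abs(X - Y)) / max(fx, fy)
}

.pad_center <- function(m, h, w) {
  out <- matrix(0, h, w)
  r0 <- (h - nrow(m)) %/% 2L
  c0 <- (w - ncol(m)) %/% 2L
  out[(r0 + 1L):(r0 + nrow(m)), (c0 + 1L):(c0 + ncol(m))] <- m
  out
}

#' Rotate a binary raster about its centre
#'
#' Nearest-neighbour resampling after inverse mapping, thresholded back to
#' binary, so rotation is deterministic and preserves binarity. The output
#' canvas is enlarged to the rotated bounding box of the input canvas, so no
#' foreground is clipped.
#'
#' @param raster Binary matrix.
#' @param theta Rotation angle in degrees (positive = counter-clockwise in
#'   image coordinates).
#' @return Binary integer matrix.
#' @export
rotate_raster <- function(raster, theta) {
  m <- raster * 1
  if (theta == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  a <- theta * pi / 180
  ca <- cos(a); sa <- sin(a)
  H <- ceiling(h * abs(ca) + w * abs(sa))
  W <- ceiling(w * abs(ca) + h * abs(sa))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  CY <- (H + 1) / 2; CX <- (W + 1) / 2
  out_r <- rep(seq_len(H), times = W) - CY
  out_c <- rep(seq_len(W), each = H) - CX
  # inverse rotation of output coordinates into the source raster
  src_c <- round(ca * out_c - sa * out_r + cx)
  src_r <- round(sa * out_c + ca * out_r + cy)
  ok <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  vals <- numeric(H * W)
  vals[ok] <- m[cbind(src_r[ok], src_c[ok])]
  matrix(as.integer(vals > 0.5), H, W)
}

#' Crop a binary raster to its foreground bounding box
#'
#' @param raster Binary matrix with at least one foreground pixel.
#' @return Binary matrix covering exactly the content bounding box.
#' @export
crop_to_content <- function(raster) {
  idx <- which(raster > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot crop an empty raster")
  raster[min(idx[, 1L]):max(idx[, 1L]), min(idx[, 2L]):max(idx[, 2L]), drop = FALSE]
}

#' Anisotropically resize a binary raster to a target bounding box
#'
#' Nearest-neighbour resize of the raster to `target_h` x `target_w`,
#' thresholded to binary. Used to bring a rotated template to the scale of a
#' detected component's bounding box before comparison.
#'
#' @param raster Binary matrix.
#' @param target_h,target_w Target dimensions (both >= 3).
#' @return Binary integer matrix of the requested size.
#' @export
scale_to_bbox <- function(raster, target_h, target_w) {
  if (target_h < 3L || target_w < 3L) stop("degenerate target dimensions")
  m <- raster * 1
  h <- nrow(m); w <- ncol(m)
  src_r <- pmin(pmax(ceiling((seq_len(target_h) - 0.5) * h / target_h), 1L), h)
  src_c <- pmin(pmax(ceiling((seq_len(target_w) - 0.5) * w / target_w), 1L), w)
  out <- m[src_r, src_c, drop = FALSE]
  matrix(as.integer(out > 0.5), target_h, target_w)
}

#' Build the rotated-template cache for symbol classification
#'
#' Generates, for each of the six symbol classes, one variant per rotation
#' angle (default -22..22 degrees in 1-degree steps, i.e. 45 variants per
#' class), each cropped to its content bounding box. Angles are ordered by
#' increasing magnitude so that ties in the dissimilarity search resolve to
#' the smallest rotation.
#'
#' @param rasters Symbol rasters from [build_symbol_rasters()].
#' @param theta_min,theta_max,theta_step Rotation sweep in degrees.
#' @return A `csl_classifier` configuration object.
#' @export
classifier_config <- function(rasters = build_symbol_rasters(),
                              theta_min = -22, theta_max = 22, theta_step = 1) {
  angles <- seq(theta_min, theta_max, by = theta_step)
  angles <- angles[order(abs(angles), angles)]
  templates <- lapply(rasters, function(rst) {
    lapply(angles, function(th) crop_to_content(rotate_raster(rst, th)))
  })
  structure(
    list(angles = angles, templates = templates,
         classes = symbol_classes(), scaled_cache = new.env(parent = emptyenv())),
    class = "csl_classifier"
  )
}

#' Classify one detected component
#'
#' Every rotated template of every class is resized to the component's
#' bounding box and scored with [normalized_sad()]; the component is
#' assigned the class of the global minimum. Ties resolve to the lowest
#' class id, then the smallest rotation magnitude.
#'
#' @param component A component from [extract_components()].
#' @param config A `csl_classifier` from [classifier_config()].
#' @return List with `class` (id), `dissimilarity` and `angle` (degrees).
#' @export
classify_component <- function(component, config) {
  mask <- component$mask * 1L
  bh <- nrow(mask); bw <- ncol(mask)
  fg_comp <- sum(mask)
  best <- list(class = NA_integer_, dissimilarity = Inf, angle = NA_real_)
  cache <- config$scaled_cache
  for (ci in seq_along(config$templates)) {
    tmpls <- config$templates[[ci]]
    for (ai in seq_along(config$angles)) {
      key <- paste0(ci, "|", ai, "|", bh, "x", bw)
      tm <- cache[[key]]
      if (is.null(tm)) {
        tm <- scale_to_bbox(tmpls[[ai]], bh, bw)
        cache[[key]] <- tm
      }
      d <- sum(abs(tm - mask)) / max(sum(tm), fg_comp)
      if (d < best$dissimilarity) {
        best <- list(class = ci - 1L, dissimilarity = d,
                     angle = config$angles[ai])
      }
    }
  }
  best
}

#' Classify all components of an image
#'
#' @param components Output of [extract_components()].
#' @param config A `csl_classifier`.
#' @return A data.frame with columns `id`, `class`, `dissimilarity`, `angle`.
#' @export
classify_components <- function(components, config) {
  res <- lapply(components, function(comp) {
    cl <- classify_component(comp, config)
    data.frame(id = comp$id, class = cl$class,
               dissimilarity = cl$dissimilarity, angle = cl$angle)
  })
  do.call(rbind, res)
}
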
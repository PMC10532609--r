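#' Convert an RGB raster to 8-bit grayscale
#'
#' Uses the ITU-R 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param image An H x W x 3 numeric array with values in 0..255.
#' @return An H x W numeric matrix in 0..255.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("expected a 3-channel RGB image")
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

# Clipped-window box sums via an integral image.
.box_stats <- function(img, rad) {
  h <- nrow(img); w <- ncol(img)
  P <- matrix(0, h + 1L, w + 1L)
  P[-1L, -1L] <- t(apply(apply(img, 2L, cumsum), 1L, cumsum))
  r0 <- pmax(seq_len(h) - rad, 1L); r1 <- pmin(seq_len(h) + rad, h)
  c0 <- pmax(seq_len(w) - rad, 1L); c1 <- pmin(seq_len(w) + rad, w)
  s <- P[r1 + 1L, c1 + 1L] - P[r0, c1 + 1L] - P[r1 + 1L, c0] + P[r0, c0]
  cnt <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  list(sum = s, count = cnt)
}

#' Sauvola adaptive binarization (bright foreground)
#'
#' Sauvola's local threshold `t = m * (1 + k * (s / R - 1))`, with `m` and
#' `s` the mean and standard deviation over a square window and `R` the
#' dynamic-range constant, is defined for dark foreground on a light
#' background. The projected symbols are bright on dark, so the threshold
#' is computed on the photometrically inverted image: a pixel is foreground
#' when `max_value - pixel` falls at or below the inverted-image threshold,
#' i.e. `pixel >= max_value - (max_value - m) * (1 + k * (s / R - 1))`.
#' Because the threshold tracks local statistics, symbols survive strong
#' illumination gradients that defeat any single global threshold; in
#' regions of constant intensity (`s = 0`) the threshold sits above the
#' local level and the region is uniformly background, so a constant image
#' yields a single class as its degenerate output.
#'
#' @param image Grayscale numeric matrix in 0..255.
#' @param window Odd window side length in pixels; the default 31 exceeds
#'   the symbol pitch so local statistics always mix the two populations.
#' @param k Sensitivity parameter in (0, 1) (default 0.2).
#' @param R Dynamic-range constant (default 128).
#' @param max_value Top of the intensity scale (default 255).
#' @return A `csl_mask`: logical H x W matrix.
#' @export
sauvola_binarize <- function(image, window = 31L, k = 0.2, R = 128,
                             max_value = 255) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (k <= 0 || k >= 1) stop("k must be in (0, 1)")
  rad <- (window - 1L) %/% 2L
  b1 <- .box_stats(image, rad)
  b2 <- .box_stats(image^2, rad)
  m <- b1$sum / b1$count
  v <- pmax(b2$sum / b2$count - m^2, 0)
  thr <- max_value - (max_value - m) * (1 + k * (sqrt(v) / R - 1))
  structure(image >= thr, class = c("csl_mask", "matrix"))
}

#' Otsu global binarization
#'
#' Thresholds the whole image at the single integer level in 0..254
#' maximizing the between-class variance `w0 * w1 * (mu0 - mu1)^2` of the
#' 8-bit intensity histogram (ties resolve to the lowest level). Provided as
#' the global-threshold baseline against which the adaptive method is
#' compared under uneven illumination.
#'
#' @param image Grayscale numeric matrix in 0..255 (non-constant).
#' @return A `csl_mask`: logical H x W matrix (foreground = above threshold),
#'   with the chosen level stored in attribute `threshold`.
#' @export
otsu_binarize <- function(image) {
  if (max(image) == min(image)) stop("Otsu threshold undefined for a constant image")
  g <- pmin(pmax(round(image), 0), 255)
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- sum(counts)
  lv <- 0:255
  w0 <- cumsum(counts)                 # pixels <= t
  m0 <- cumsum(counts * lv)            # intensity mass <= t
  tot <- m0[256L]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (tot - m0) / w1
  bcv <- ifelse(valid, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  th <- lv[which.max(bcv)]
  structure(image > th, class = c("csl_mask", "matrix"), threshold = th)
}

#' Extract connected components from a binary mask
#'
#' Labels 8-connected foreground regions and discards those with fewer than
#' `min_area` pixels as noise (default 50, so a 49-pixel blob is rejected
#' and a 50-pixel blob kept). Components are returned in reading order of
#' their bounding-box top-left corners.
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param min_area Minimum retained component area in pixels.
#' @return A list of components; each is a list with `id`, `area`,
#'   `centroid` (0-based `(row, col)` means), `bbox` (0-based inclusive
#'   `(top, left, bottom, right)`) and `mask` (cropped logical matrix).
#' @export
extract_components <- function(mask, min_area = 50L) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  rank <- integer(h * w)
  rank[fg] <- seq_along(fg)
  fr <- (fg - 1L) %% h + 1L
  fc <- (fg - 1L) %/% h + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- fr + off[1L]; nc <- fc + off[2L]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    nb <- rank[nidx]
    keep <- nb > 0L
    if (any(keep)) {
      edges <- c(edges, rbind(rank[fg[ok]][keep], nb[keep]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- list()
  for (grp in split(seq_along(fg), memb)) {
    if (length(grp) < min_area) next
    rr <- fr[grp]; cc <- fc[grp]
    top <- min(rr); left <- min(cc); bottom <- max(rr); right <- max(cc)
    sub <- matrix(FALSE, bottom - top + 1L, right - left + 1L)
    sub[cbind(rr - top + 1L, cc - left + 1L)] <- TRUE
    comps[[length(comps) + 1L]] <- list(
      area = length(grp),
      centroid = c(row = mean(rr) - 1, col = mean(cc) - 1),
      bbox = c(top = top - 1L, left = left - 1L,
               bottom = bottom - 1L, right = right - 1L),
      mask = sub
    )
  }
  if (length(comps) == 0L) return(list())
  ord <- order(vapply(comps, function(x) x$bbox[["top"]], 0L),
               vapply(comps, function(x) x$bbox[["left"]], 0L))
  comps <- comps[ord]
  for (i in seq_along(comps)) comps[[i]]$id <- i
  comps
}

#' Summarize components as a data.frame
#'
#' @param components Output of [extract_components()].
#' @return A data.frame with one row per component (id, area, centroid and
#'   bounding box, 0-based).
#' @export
components_table <- function(components) {
  do.call(rbind, lapply(components, function(x) {
    data.frame(id = x$id, area = x$area,
               centroid_r = x$centroid[["row"]], centroid_c = x$centroid[["col"]],
               top = x$bbox[["top"]], left = x$bbox[["left"]],
               bottom = x$bbox[["bottom"]], right = x$bbox[["right"]])
  }))
}
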
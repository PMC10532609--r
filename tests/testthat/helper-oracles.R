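# Independent oracles and small fixture builders used across the suite.

# Brute-force normalized SAD: explicit double loop over pixels, with the
# same centred padding convention as the implementation under test.
sad_oracle <- function(X, Y) {
  X <- X * 1; Y <- Y * 1
  h <- max(nrow(X), nrow(Y)); w <- max(ncol(X), ncol(Y))
  pad <- function(m) {
    out <- matrix(0, h, w)
    r0 <- (h - nrow(m)) %/% 2; c0 <- (w - ncol(m)) %/% 2
    out[(r0 + 1):(r0 + nrow(m)), (c0 + 1):(c0 + ncol(m))] <- m
    out
  }
  X <- pad(X); Y <- pad(Y)
  s <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) s <- s + abs(X[i, j] - Y[i, j])
  }
  s / max(sum(X), sum(Y))
}

# Exhaustive minimum-total-distance bijection between 4 points and the
# corners of their bounding box (all 4! assignments).
corner_oracle <- function(pts) {
  corners <- rbind(c(min(pts[, 1]), min(pts[, 2])),
                   c(min(pts[, 1]), max(pts[, 2])),
                   c(max(pts[, 1]), min(pts[, 2])),
                   c(max(pts[, 1]), max(pts[, 2])))
  best <- NULL; bv <- Inf
  for (p in asplit(perms4, 1)) {
    v <- sum(sqrt(rowSums((pts - corners[p, ])^2)))
    if (v < bv - 1e-12) { bv <- v; best <- as.integer(p) }
  }
  best
}
perms4 <- local({
  out <- NULL
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    v <- c(a, b, cc, d)
    if (length(unique(v)) == 4L) out <- rbind(out, v)
  }
  out
})

# Quadruple drawn from the method's operating envelope: a unit square under
# bounded rotation, anisotropic scale, and centroid jitter.
random_grid_quad <- function(jitter_sd = 0.05, max_rot_deg = 22) {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  th <- stats::runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  s <- stats::runif(2, 0.7, 1.4)
  sweep(sq %*% R, 2, s, "*") + matrix(stats::rnorm(8, 0, jitter_sd), 4, 2)
}

# Regular n x n unit-pitch lattice of points with optional Gaussian jitter.
lattice_points <- function(n, jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  pts <- cbind(g$r, g$c)
  if (jitter_sd > 0) pts <- pts + matrix(stats::rnorm(2 * n^2, 0, jitter_sd), ncol = 2)
  attr(pts, "grid") <- g
  pts
}

# Warp a symbol raster with EBImage (bilinear rotate + resize), an
# implementation independent of the package's nearest-neighbour warps.
warp_symbol_ebimage <- function(raster, theta, scale_h, scale_w) {
  rot <- EBImage::rotate(EBImage::Image(t(raster * 1)), -theta, bg.col = 0)
  m <- t(EBImage::imageData(rot)) > 0.5
  idx <- which(m, arr.ind = TRUE)
  m <- m[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  th <- max(3L, round(nrow(m) * scale_h)); tw <- max(3L, round(ncol(m) * scale_w))
  t(EBImage::imageData(EBImage::resize(EBImage::Image(t(m * 1)), w = tw, h = th))) > 0.5
}

# Embed a binary symbol mask in a noisy shaded patch and run the
# binarize/extract front end, returning the largest component (or NULL).
noisy_symbol_component <- function(mask, snr_db, canvas = 71L,
                                   fg = 180, bg = 45) {
  cv <- matrix(bg, canvas, canvas)
  r0 <- (canvas - nrow(mask)) %/% 2L; c0 <- (canvas - ncol(mask)) %/% 2L
  cv[r0 + seq_len(nrow(mask)), c0 + seq_len(ncol(mask))][mask] <- fg
  sdn <- stats::sd(cv) / 10^(snr_db / 20)
  img <- cv + matrix(stats::rnorm(canvas^2, 0, sdn), canvas, canvas)
  comps <- extract_components(sauvola_binarize(img), 50L)
  if (length(comps) == 0L) return(NULL)
  comps[[which.max(vapply(comps, function(x) x$area, 0L))]]
}

# Shared small fixtures (built once per test run).
test_pattern_small <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_pattern(12, 16, seed = 0)
    val
  }
})
test_classifier <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- classifier_config()
    val
  }
})
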
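#' The six symbol classes of the coded pattern
#'
#' The projected pattern is built from six binary geometric glyphs: a
#' rectangle, an 'L', a 'T', a triangle, an 'X' and a 'Pi'. Class ids are
#' the integers 0..5 in that order; they are the alphabet over which
#' codewords are formed.
#'
#' @return A data.frame with columns `id` (integer, 0..5) and `name`.
#' @export
symbol_classes <- function() {
  data.frame(
    id = 0:5,
    name = c("rectangle", "L", "T", "triangle", "X", "Pi"),
    stringsAsFactors = FALSE
  )
}

# Glyph geometry (rows/cols are 1-based on the size x size cell). Strokes are
# 4 px wide at the native 20 px cell; the triangle is filled. The layout was
# chosen so that all 15 pairs clear the separability floor checked in
# build_symbol_rasters().
.draw_symbol <- function(name, size = 20L) {
  m <- matrix(0L, size, size)
  s <- function(x) as.integer(round(x * size / 20))
  switch(name,
    rectangle = {
      m[s(8):s(13), s(4):s(17)] <- 1L
    },
    L = {
      m[s(2):s(19), s(2):s(5)] <- 1L
      m[s(16):s(19), s(6):s(19)] <- 1L
    },
    T = {
      m[s(2):s(5), s(2):s(19)] <- 1L
      m[s(6):s(19), s(9):s(12)] <- 1L
    },
    triangle = {
      for (r in s(3):s(18)) {
        half <- floor((r - s(3)) * (s(17) / 2) / (s(18) - s(3)))
        m[r, max(1L, s(10) - half):min(size, s(11) + half)] <- 1L
      }
    },
    X = {
      for (r in seq_len(size)) {
        for (cc in seq_len(size)) {
          if (abs(r - cc) <= 1 || abs(r + cc - size - 1L) <= 1) m[r, cc] <- 1L
        }
      }
    },
    Pi = {
      m[s(2):s(5), s(2):s(19)] <- 1L
      m[s(6):s(14), s(2):s(5)] <- 1L
      m[s(6):s(14), s(16):s(19)] <- 1L
    },
    stop("unknown symbol name: ", name)
  )
  m
}

#' Build the six binary symbol rasters
#'
#' Draws one `size` x `size` binary raster per symbol class and verifies the
#' pairwise separability of the set: every pair of distinct rasters must be
#' at normalized SAD of at least `min_separation` (see [normalized_sad()]).
#' High mutual dissimilarity of the alphabet is what makes template
#' classification of distorted image symbols reliable.
#'
#' @param size Side length of the square symbol cell in pixels (default 20).
#' @param min_separation Separability floor for pairwise normalized SAD.
#' @return A named list of six 0/1 integer matrices, in class-id order.
#' @export
build_symbol_rasters <- function(size = 20L, min_separation = 0.7) {
  cls <- symbol_classes()
  rasters <- lapply(cls$name, .draw_symbol, size = as.integer(size))
  names(rasters) <- cls$name
  for (r in rasters) {
    if (sum(r) == 0L) stop("symbol raster has no foreground pixels")
  }
  n <- length(rasters)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- normalized_sad(rasters[[i]], rasters[[j]])
      if (d < min_separation) {
        stop(sprintf(
          "symbol rasters '%s' and '%s' are not separable (normalized SAD %.3f < %.2f)",
          names(rasters)[i], names(rasters)[j], d, min_separation
        ))
      }
    }
  }
  rasters
}

#' Pairwise normalized-SAD matrix of a raster set
#'
#' @param rasters A list of binary rasters, e.g. from [build_symbol_rasters()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
symbol_separability <- function(rasters = build_symbol_rasters()) {
  n <- length(rasters)
  M <- matrix(0, n, n, dimnames = list(names(rasters), names(rasters)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) M[i, j] <- normalized_sad(rasters[[i]], rasters[[j]])
    }
  }
  M
}
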
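#' Hamming distance between two codewords
#'
#' Counts the positions at which two 9-symbol codewords hold different
#' symbols. The pattern is designed so that any two of its codewords are at
#' distance >= 3, which permits correcting one classification error per
#' codeword.
#'
#' @param a,b Integer vectors of length 9 (symbol class ids).
#' @return Non-negative integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != 9L || length(b) != 9L) {
    stop("codewords must have length 9")
  }
  sum(a != b)
}

#' @export
print.csl_pattern <- function(x, ...) {
  cat(sprintf(
    "<csl_pattern> %d x %d symbols (%d px cells, %d px gaps), seed %d\n",
    x$rows, x$cols, x$symbol_px, x$gap_px, x$seed
  ))
  invisible(x)
}

# Run expr with a private RNG stream so pattern generation is reproducible
# and does not disturb the caller's random state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a coded pattern grid with window Hamming distance >= 3
#'
#' Fills a `rows` x `cols` lattice of symbol class labels so that every 3x3
#' window, read as a 9-symbol codeword, is at Hamming distance >= 3 from
#' every other 3x3 window. The fill is a seeded randomized greedy scan in
#' raster order: each placement that completes a window is accepted only if
#' the new codeword keeps distance >= 3 to all previously completed windows;
#' dead ends trigger bounded backtracking, and exhausted attempts restart
#' from a derived seed.
#'
#' @param rows,cols Symbol-grid dimensions (both >= 3). Defaults are the
#'   full projector pattern, 43 rows x 76 columns.
#' @param seed Integer generation seed; the label matrix is a deterministic
#'   function of `(rows, cols, seed)`.
#' @param symbol_px,gap_px Symbol cell side and inter-symbol gap in rendered
#'   pixels (defaults 20 and 5).
#' @param max_restarts Number of fresh randomized attempts before giving up.
#' @param max_backtracks Backtracking budget within one attempt.
#' @return A `csl_pattern` object: list with `labels` (integer matrix of
#'   class ids 0..5), `rows`, `cols`, `symbol_px`, `gap_px`, `seed`.
#' @export
generate_pattern <- function(rows = 43L, cols = 76L, seed = 0L,
                             symbol_px = 20L, gap_px = 5L,
                             max_restarts = 25L, max_backtracks = 20000L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 3L || cols < 3L) stop("rows and cols must both be >= 3")
  labels <- .with_seed(as.integer(seed), {
    res <- NULL
    for (attempt in seq_len(max_restarts)) {
      res <- .greedy_fill(rows, cols, max_backtracks)
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(labels)) {
    stop(sprintf(
      "pattern search failed for %d x %d after %d restarts; size/alphabet combination may be infeasible",
      rows, cols, max_restarts
    ))
  }
  structure(
    list(labels = labels, rows = rows, cols = cols,
         symbol_px = as.integer(symbol_px), gap_px = as.integer(gap_px),
         seed = as.integer(seed)),
    class = "csl_pattern"
  )
}

# One randomized greedy attempt; returns the label matrix or NULL on budget
# exhaustion. Uses the caller's RNG stream.
.greedy_fill <- function(rows, cols, max_backtracks) {
  ncell <- rows * cols
  labels <- matrix(NA_integer_, rows, cols)
  nwin <- (rows - 2L) * (cols - 2L)
  book <- matrix(0L, nwin, 9L)   # completed-window codewords, in close order
  nb <- 0L
  perms <- vector("list", ncell) # candidate order per cell, fixed per attempt
  ptr <- integer(ncell)          # next untried candidate index per cell
  closed <- logical(ncell)       # did this cell close a window when placed
  backtracks <- 0L
  cell_rc <- function(i) c((i - 1L) %/% cols + 1L, (i - 1L) %% cols + 1L)

  i <- 1L
  while (i <= ncell) {
    if (is.null(perms[[i]])) perms[[i]] <- sample.int(6L) - 1L
    rc <- cell_rc(i); r <- rc[1L]; cc <- rc[2L]
    closes <- (r >= 3L && cc >= 3L)
    allowed <- perms[[i]]
    if (closes && nb > 0L) {
      # first 8 codeword positions of the closing window are already fixed
      win <- labels[(r - 2L):r, (cc - 2L):cc]
      fixed8 <- as.vector(t(win))[1:8]
      prior <- book[seq_len(nb), , drop = FALSE]
      mm8 <- rowSums(prior[, 1:8, drop = FALSE] !=
                       matrix(fixed8, nb, 8L, byrow = TRUE))
      if (any(mm8 <= 1L)) {
        allowed <- integer(0)            # no symbol can reach distance 3
      } else {
        blocked <- prior[mm8 == 2L, 9L]
        allowed <- allowed[!(allowed %in% blocked)]
      }
    }
    k <- ptr[i] + 1L
    # advance to the next allowed candidate in this cell's fixed order
    pick <- NA_integer_
    while (k <= 6L) {
      cand <- perms[[i]][k]
      if (cand %in% allowed) { pick <- cand; break }
      k <- k + 1L
    }
    if (!is.na(pick)) {
      ptr[i] <- k
      labels[r, cc] <- pick
      if (closes) {
        nb <- nb + 1L
        book[nb, ] <- as.vector(t(labels[(r - 2L):r, (cc - 2L):cc]))
        closed[i] <- TRUE
      } else closed[i] <- FALSE
      i <- i + 1L
    } else {
      # dead end: unwind the previous placement and retry it
      ptr[i] <- 0L
      i <- i - 1L
      if (i < 1L) return(NULL)
      if (closed[i]) { nb <- nb - 1L; closed[i] <- FALSE }
      rc <- cell_rc(i)
      labels[rc[1L], rc[2L]] <- NA_integer_
      backtracks <- backtracks + 1L
      if (backtracks > max_backtracks) return(NULL)
    }
  }
  labels
}

#' Extract the 3x3 label window whose top-left symbol is at (r, c)
#'
#' @param pattern A `csl_pattern`.
#' @param r,c 1-based row/column of the window's top-left symbol;
#'   `r <= rows - 2`, `c <= cols - 2`.
#' @return A 3x3 integer matrix of class ids.
#' @export
subpattern_at <- function(pattern, r, c) {
  if (r < 1L || c < 1L || r > pattern$rows - 2L || c > pattern$cols - 2L) {
    stop("subpattern origin out of range")
  }
  pattern$labels[r:(r + 2L), c:(c + 2L)]
}

#' Flatten a 3x3 symbol window into a 9-symbol codeword
#'
#' The traversal is row-major (left to right, then top to bottom). Any fixed
#' bijection between window cells and codeword positions preserves Hamming
#' distances; this one is used consistently by the encoder and the decoder.
#'
#' @param window A 3x3 matrix of class ids.
#' @return Integer vector of length 9.
#' @export
flatten_subpattern <- function(window) {
  if (!all(dim(window) == c(3L, 3L))) stop("window must be 3x3")
  as.vector(t(window))
}

#' Inverse of [flatten_subpattern()]
#'
#' @param codeword Integer vector of length 9.
#' @return A 3x3 matrix of class ids.
#' @export
unflatten_codeword <- function(codeword) {
  if (length(codeword) != 9L) stop("codeword must have length 9")
  matrix(codeword, 3L, 3L, byrow = TRUE)
}

#' Enumerate all codewords of a pattern
#'
#' @param pattern A `csl_pattern`.
#' @return A `csl_codebook`: list with `words` ((rows-2)(cols-2) x 9 integer
#'   matrix, one codeword per row) and `origins` (matching 2-column matrix of
#'   1-based top-left window positions).
#' @export
codeword_book <- function(pattern) {
  nr <- pattern$rows - 2L; nc <- pattern$cols - 2L
  words <- matrix(0L, nr * nc, 9L)
  origins <- matrix(0L, nr * nc, 2L, dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1L
      words[k, ] <- flatten_subpattern(pattern$labels[r:(r + 2L), cc:(cc + 2L)])
      origins[k, ] <- c(r, cc)
    }
  }
  structure(list(words = words, origins = origins, count = k),
            class = "csl_codebook")
}

#' @export
print.csl_codebook <- function(x, ...) {
  cat(sprintf("<csl_codebook> %d codewords of length 9\n", x$count))
  invisible(x)
}

#' Exact minimum pairwise Hamming distance over all 3x3 windows
#'
#' Exhaustively compares every pair of codewords of the pattern (about 4.6
#' million pairs for the default 43 x 76 grid) and returns the minimum
#' distance. A valid coded pattern returns >= 3.
#'
#' @param pattern A `csl_pattern` (or a `csl_codebook`).
#' @return Integer: the minimum pairwise Hamming distance.
#' @export
verify_min_distance <- function(pattern) {
  book <- if (inherits(pattern, "csl_codebook")) pattern else codeword_book(pattern)
  W <- book$words
  n <- nrow(W)
  if (n < 2L) return(9L)  # vacuous: single codeword
  # pairwise matches via one indicator cross-product per symbol class
  matches <- matrix(0, n, n)
  for (cls in 0:5) {
    I <- (W == cls) * 1
    matches <- matches + tcrossprod(I)
  }
  diag(matches) <- -Inf
  as.integer(9 - max(matches))
}

#' Render a pattern grid to a binary raster
#'
#' Places the white symbol rasters on a black canvas at pitch
#' `symbol_px + gap_px`, centred on the canvas. With the default pattern and
#' a 1920 x 1080 canvas this reproduces the projected image: 76 x 43 symbol
#' cells of 20 px with 5 px gaps.
#'
#' @param pattern A `csl_pattern`.
#' @param canvas_w,canvas_h Canvas (projector) size in pixels.
#' @param rasters Symbol rasters; defaults to [build_symbol_rasters()] at the
#'   pattern's `symbol_px`.
#' @return A `canvas_h` x `canvas_w` 0/1 integer matrix with attributes
#'   `offset` (0-based (x, y) of the top-left symbol cell) and `pitch`.
#' @export
render_pattern <- function(pattern, canvas_w = 1920L, canvas_h = 1080L,
                           rasters = build_symbol_rasters(pattern$symbol_px)) {
  sp <- pattern$symbol_px; gp <- pattern$gap_px
  pitch <- sp + gp
  w <- pattern$cols * pitch - gp
  h <- pattern$rows * pitch - gp
  if (w > canvas_w || h > canvas_h) {
    stop(sprintf("canvas %dx%d too small for rendered pattern %dx%d",
                 canvas_w, canvas_h, w, h))
  }
  ox <- (canvas_w - w) %/% 2L   # 0-based canvas offsets
  oy <- (canvas_h - h) %/% 2L
  canvas <- matrix(0L, canvas_h, canvas_w)
  for (r in seq_len(pattern$rows)) {
    r0 <- oy + (r - 1L) * pitch      # 0-based top row of the cell
    for (cc in seq_len(pattern$cols)) {
      c0 <- ox + (cc - 1L) * pitch
      glyph <- rasters[[pattern$labels[r, cc] + 1L]]
      canvas[(r0 + 1L):(r0 + sp), (c0 + 1L):(c0 + sp)] <- glyph
    }
  }
  attr(canvas, "offset") <- c(x = ox, y = oy)
  attr(canvas, "pitch") <- pitch
  canvas
}

#' Foreground centroids of every symbol cell of a rendered pattern
#'
#' Returns, for each grid position, the centroid of the symbol's white
#' pixels in canvas coordinates. These are the pattern-side feature points
#' of the correspondences. Coordinates are 0-based with pixel centres at
#' integer positions; `x` is the column and `y` the row.
#'
#' @inheritParams render_pattern
#' @return A data.frame with columns `row`, `col` (1-based grid position),
#'   `x`, `y` (0-based canvas coordinates) and `class` (symbol id).
#' @export
pattern_centroids <- function(pattern, canvas_w = 1920L, canvas_h = 1080L,
                              rasters = build_symbol_rasters(pattern$symbol_px)) {
  sp <- pattern$symbol_px; gp <- pattern$gap_px
  pitch <- sp + gp
  w <- pattern$cols * pitch - gp
  h <- pattern$rows * pitch - gp
  ox <- (canvas_w - w) %/% 2L
  oy <- (canvas_h - h) %/% 2L
  # per-class centroid within the cell (0-based)
  cent <- t(vapply(rasters, function(g) {
    idx <- which(g == 1L, arr.ind = TRUE)
    c(mean(idx[, 2L]) - 1, mean(idx[, 1L]) - 1)
  }, numeric(2)))
  grid <- expand.grid(row = seq_len(pattern$rows), col = seq_len(pattern$cols))
  cls <- pattern$labels[cbind(grid$row, grid$col)]
  data.frame(
    row = grid$row, col = grid$col,
    x = ox + (grid$col - 1L) * pitch + cent[cls + 1L, 1L],
    y = oy + (grid$row - 1L) * pitch + cent[cls + 1L, 2L],
    class = cls
  )
}
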
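#' Indices of the eight nearest components to a centre component
#'
#' Nearest by Euclidean distance between centroids; ties broken
#' lexicographically by (row, col). Components with fewer than eight
#' neighbours (image-boundary symbols) raise an error and form no
#' subpattern.
#'
#' @param center Index of the centre component (row of `centroids`).
#' @param centroids Numeric n x 2 matrix of component centroids (row, col).
#' @return Integer vector of 8 component indices, nearest first.
#' @export
eight_nearest <- function(center, centroids) {
  n <- nrow(centroids)
  if (n - 1L < 8L) stop("fewer than 8 candidate neighbours")
  d <- sqrt((centroids[, 1L] - centroids[center, 1L])^2 +
            (centroids[, 2L] - centroids[center, 2L])^2)
  d[center] <- Inf
  ord <- order(d, centroids[, 1L], centroids[, 2L])
  ord[1:8]
}

#' Order the eight neighbours by successive nearest-unvisited traversal
#'
#' Starting from the centre symbol, repeatedly visits the nearest unvisited
#' member of the neighbour set, measuring from the symbol last visited. On a
#' regular lattice each step moves to a directly adjacent symbol and the
#' visit order closes the four overlapping 2x2 grids after 3, +2, +2 and +1
#' visits.
#'
#' @param center Centre component index.
#' @param neighbors Integer vector of 8 neighbour indices.
#' @param centroids Numeric n x 2 centroid matrix.
#' @return List with `visits` (the 8 indices in visit order) and
#'   `step_dist` (distance moved at each of the 8 steps).
#' @export
chain_traverse <- function(center, neighbors, centroids) {
  remaining <- neighbors
  visits <- integer(0)
  steps <- numeric(0)
  at <- center
  while (length(remaining) > 0L) {
    d <- sqrt((centroids[remaining, 1L] - centroids[at, 1L])^2 +
              (centroids[remaining, 2L] - centroids[at, 2L])^2)
    ord <- order(d, centroids[remaining, 1L], centroids[remaining, 2L])
    nxt <- remaining[ord[1L]]
    visits <- c(visits, nxt)
    steps <- c(steps, d[ord[1L]])
    remaining <- setdiff(remaining, nxt)
    at <- nxt
  }
  list(visits = visits, step_dist = steps)
}

#' Assign four points to the corners of their common bounding box
#'
#' Greedy exclusion: the (point, corner) pair at global minimum distance is
#' fixed first, both are removed, and the process repeats until all four
#' points are assigned. Corners are those of the minimal axis-aligned
#' rectangle of the four points.
#'
#' @param points Numeric 4 x 2 matrix of (row, col) positions.
#' @return Integer vector of length 4: for each input point, its corner
#'   (1 = top-left, 2 = top-right, 3 = bottom-left, 4 = bottom-right).
#' @export
assign_corners <- function(points) {
  if (!all(dim(points) == c(4L, 2L))) stop("expected 4 points")
  if (anyDuplicated(split(points, row(points)))) stop("coincident points")
  for (trip in utils::combn(4L, 3L, simplify = FALSE)) {
    p <- points[trip, , drop = FALSE]
    area2 <- abs((p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
                 (p[3L, 1L] - p[1L, 1L]) * (p[2L, 2L] - p[1L, 2L]))
    if (area2 < 1e-9) stop("degenerate (collinear) point set")
  }
  rmin <- min(points[, 1L]); rmax <- max(points[, 1L])
  cmin <- min(points[, 2L]); cmax <- max(points[, 2L])
  corners <- rbind(c(rmin, cmin), c(rmin, cmax), c(rmax, cmin), c(rmax, cmax))
  D <- outer(seq_len(4L), seq_len(4L), Vectorize(function(i, j) {
    sqrt(sum((points[i, ] - corners[j, ])^2))
  }))
  assignment <- integer(4L)
  for (step in seq_len(4L)) {
    best <- which(D == min(D), arr.ind = TRUE)[1L, ]
    assignment[best[1L]] <- best[2L]
    D[best[1L], ] <- Inf
    D[, best[2L]] <- Inf
  }
  assignment
}

#' Assemble and validate a 3x3 subpattern candidate from a neighbour chain
#'
#' The chain's visit order closes four overlapping 2x2 grids (centre plus
#' visits 1-3, then +2, +2, +1). Corner roles are determined at two levels
#' with [assign_corners()]: among the four grid centroids, and among the
#' four members of each grid. The corner symbols of the 3x3 arrangement come
#' from the matching corner of the matching grid; each edge-middle symbol is
#' determined twice (once from each adjacent grid) and the centre four
#' times, and any disagreement invalidates the candidate.
#'
#' A candidate is also invalidated (`chain_break`) when some visit step
#' travels farther than `break_factor` times the local symbol pitch
#' (median centre-to-neighbour distance of the four nearest neighbours),
#' which signals that the eight-nearest assumption failed.
#'
#' @param center Centre component index.
#' @param chain Output of [chain_traverse()].
#' @param centroids Numeric n x 2 centroid matrix.
#' @param break_factor Chain-break multiplier (default 1.8).
#' @return A list: `center`, `arrangement` (3x3 matrix of component indices,
#'   row-major orientation as projected), `valid`, `failure_reason` (one of
#'   "none", "chain_break", "dual_check", "quadruple_check").
#' @export
assemble_subpattern <- function(center, chain, centroids, break_factor = 1.8) {
  fail <- function(reason) {
    list(center = center, arrangement = NULL, valid = FALSE,
         failure_reason = reason)
  }
  v <- chain$visits
  d_center <- sqrt((centroids[v, 1L] - centroids[center, 1L])^2 +
                   (centroids[v, 2L] - centroids[center, 2L])^2)
  pitch <- stats::median(sort(d_center)[1:4])
  if (any(chain$step_dist > break_factor * pitch)) return(fail("chain_break"))

  quads <- list(c(center, v[1:3]), c(center, v[3:5]),
                c(center, v[5:7]), c(center, v[c(7, 8, 1)]))
  quad_cent <- t(vapply(quads, function(q) colMeans(centroids[q, , drop = FALSE]),
                        numeric(2L)))
  roles <- tryCatch(assign_corners(quad_cent), error = function(e) NULL)
  if (is.null(roles)) return(fail("dual_check"))
  # quad_by_role[k]: which quad sits at corner role k (TL, TR, BL, BR)
  quad_by_role <- order(roles)
  member_roles <- vector("list", 4L)
  for (qi in seq_len(4L)) {
    mr <- tryCatch(assign_corners(centroids[quads[[qi]], , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(mr)) return(fail("dual_check"))
    member_roles[[qi]] <- quads[[qi]][order(mr)]  # members in TL,TR,BL,BR order
  }
  m <- function(quad_role, member_role) {
    member_roles[[quad_by_role[quad_role]]][member_role]
  }
  TL <- 1L; TR <- 2L; BL <- 3L; BR <- 4L
  arr <- matrix(NA_integer_, 3L, 3L)
  arr[1L, 1L] <- m(TL, TL)
  arr[1L, 3L] <- m(TR, TR)
  arr[3L, 1L] <- m(BL, BL)
  arr[3L, 3L] <- m(BR, BR)
  dual <- function(a, b) if (a == b) a else NA_integer_
  arr[1L, 2L] <- dual(m(TL, TR), m(TR, TL))
  arr[2L, 1L] <- dual(m(TL, BL), m(BL, TL))
  arr[2L, 3L] <- dual(m(TR, BR), m(BR, TR))
  arr[3L, 2L] <- dual(m(BL, BR), m(BR, BL))
  if (anyNA(arr[cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))])) return(fail("dual_check"))
  quad_view <- c(m(TL, BR), m(TR, BL), m(BL, TR), m(BR, TL))
  if (!all(quad_view == center)) return(fail("quadruple_check"))
  arr[2L, 2L] <- center
  if (length(unique(as.vector(arr))) != 9L) return(fail("dual_check"))
  list(center = center, arrangement = arr, valid = TRUE, failure_reason = "none")
}

#' Extract subpattern candidates for every component of an image
#'
#' @param centroids Numeric n x 2 matrix of component centroids (row, col).
#' @param break_factor Passed to [assemble_subpattern()].
#' @return A list of candidates (one per component with at least eight
#'   neighbours), each as returned by [assemble_subpattern()].
#' @export
extract_subpatterns <- function(centroids, break_factor = 1.8) {
  n <- nrow(centroids)
  out <- list()
  if (n < 9L) return(out)
  for (i in seq_len(n)) {
    nb <- eight_nearest(i, centroids)
    chain <- chain_traverse(i, nb, centroids)
    out[[length(out) + 1L]] <- assemble_subpattern(i, chain, centroids,
                                                   break_factor = break_factor)
  }
  out
}
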
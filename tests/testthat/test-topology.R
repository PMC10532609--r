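test_that("eight nearest neighbours are the true ring on a lattice", {
  pts <- lattice_points(5)
  g <- attr(pts, "grid")
  ctr <- which(g$r == 3 & g$c == 3)
  truth <- setdiff(which(abs(g$r - 3) <= 1 & abs(g$c - 3) <= 1), ctr)
  expect_setequal(eight_nearest(ctr, pts), truth)
  # a corner symbol has too few neighbours only when the image is tiny
  expect_error(eight_nearest(1L, lattice_points(3)[1:8, ]),
               "fewer than 8")
})

test_that("eight nearest neighbours survive moderate centroid jitter", {
  hits <- 0L
  for (s in 1:100) {
    pts <- lattice_points(5, jitter_sd = 0.05, seed = s)
    g <- attr(pts, "grid")
    ctr <- which(g$r == 3 & g$c == 3)
    truth <- setdiff(which(abs(g$r - 3) <= 1 & abs(g$c - 3) <= 1), ctr)
    hits <- hits + setequal(eight_nearest(ctr, pts), truth)
  }
  expect_identical(hits, 100L)
})

test_that("chain traversal closes the four 2x2 grids on schedule", {
  pts <- lattice_points(5)
  g <- attr(pts, "grid")
  ctr <- which(g$r == 3 & g$c == 3)
  nb <- eight_nearest(ctr, pts)
  ch <- chain_traverse(ctr, nb, pts)
  # each step moves to a directly adjacent symbol (distance 1 on unit pitch)
  expect_true(all(abs(ch$step_dist - 1) < 1e-9))
  # visits 1-3 with the centre form a true 2x2 cell, and so on per the
  # +2, +2, +1 schedule
  quads <- list(c(ctr, ch$visits[1:3]), c(ctr, ch$visits[3:5]),
                c(ctr, ch$visits[5:7]), c(ctr, ch$visits[c(7, 8, 1)]))
  for (q in quads) {
    rr <- g$r[q]; cc <- g$c[q]
    expect_identical(diff(range(rr)), 1L)
    expect_identical(diff(range(cc)), 1L)
    expect_identical(length(unique(paste(rr, cc))), 4L)
  }
})

test_that("corner assignment is exact for corner points and rotated squares", {
  sq <- rbind(c(0, 0), c(0, 4), c(4, 0), c(4, 4))
  expect_identical(assign_corners(sq), 1:4)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rot <- sq %*% R
  expect_identical(assign_corners(rot), corner_oracle(rot))
  expect_error(assign_corners(rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 3))),
               "collinear")
  expect_error(assign_corners(rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))),
               "coincident")
})

test_that("greedy corner assignment matches the exhaustive bijection", {
  set.seed(9)
  n_ok <- 0L; n <- 200L
  for (i in seq_len(n)) {
    pts <- random_grid_quad(jitter_sd = 0.05)
    a <- tryCatch(assign_corners(pts), error = function(e) NULL)
    if (is.null(a)) { n_ok <- n_ok + 1L; next }  # degenerate draws don't count
    n_ok <- n_ok + identical(a, corner_oracle(pts))
  }
  expect_identical(n_ok, n)
})

test_that("ideal-lattice subpatterns assemble into the true arrangement", {
  pts <- lattice_points(5)
  g <- attr(pts, "grid")
  ctr <- which(g$r == 3 & g$c == 3)
  ch <- chain_traverse(ctr, eight_nearest(ctr, pts), pts)
  sp <- assemble_subpattern(ctr, ch, pts)
  expect_true(sp$valid)
  expect_identical(sp$failure_reason, "none")
  # arrangement must reproduce the geometric 3x3 layout
  truth <- matrix(NA_integer_, 3, 3)
  for (dr in 0:2) for (dc in 0:2) {
    truth[dr + 1, dc + 1] <- which(g$r == 2 + dr & g$c == 2 + dc)
  }
  expect_identical(sp$arrangement, truth)
  expect_identical(sp$arrangement[2, 2], ctr)
})

test_that("a displaced neighbour invalidates the candidate", {
  pts <- lattice_points(5)
  g <- attr(pts, "grid")
  ctr <- which(g$r == 3 & g$c == 3)
  # move the (2,2) symbol onto the wrong grid row
  bad <- which(g$r == 2 & g$c == 2)
  pts2 <- pts
  pts2[bad, ] <- pts[bad, ] + c(1.1, 0.15)
  nb <- eight_nearest(ctr, pts2)
  sp <- assemble_subpattern(ctr, chain_traverse(ctr, nb, pts2), pts2)
  expect_false(sp$valid)
  expect_true(sp$failure_reason %in%
                c("dual_check", "quadruple_check", "chain_break"))
})

test_that("a long chain jump is flagged as chain break", {
  pts <- lattice_points(7)
  g <- attr(pts, "grid")
  ctr <- which(g$r == 4 & g$c == 4)
  # delete one ring member so a far symbol is pulled into the eight-set
  drop <- which(g$r == 3 & g$c == 3)
  pts2 <- pts[-drop, ]
  g2 <- g[-drop, ]
  ctr2 <- which(g2$r == 4 & g2$c == 4)
  nb <- eight_nearest(ctr2, pts2)
  sp <- assemble_subpattern(ctr2, chain_traverse(ctr2, nb, pts2), pts2)
  expect_false(sp$valid)
})

test_that("validity is monotone non-increasing in centroid jitter", {
  rates <- vapply(c(0, 0.05, 0.10, 0.20), function(j) {
    pts <- lattice_points(7, jitter_sd = j, seed = 3)
    g <- attr(pts, "grid")
    sp <- extract_subpatterns(pts)
    interior <- which(g$r %in% 2:6 & g$c %in% 2:6)
    mean(vapply(sp[interior], function(x) x$valid, TRUE))
  }, 0)
  expect_identical(rates[1L], 1)
  expect_true(all(diff(rates) <= 0))
})
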
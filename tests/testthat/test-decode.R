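# Build components on an exact lattice carrying the labels of a pattern
# sub-block, so decoding can be exercised without the imaging front end.
lattice_scene <- function(pattern, rows, cols, origin = c(1L, 1L)) {
  g <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  pts <- cbind(g$r, g$c)
  labels <- pattern$labels[cbind(origin[1L] + g$r - 1L, origin[2L] + g$c - 1L)]
  list(pts = pts, labels = labels, grid = g)
}

test_that("book codewords decode verbatim at distance zero", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  set.seed(10)
  for (k in sample(book$count, 25)) {
    arr <- unflatten_codeword(1:9)  # component ids 1..9 in codeword order
    dec <- decode_codeword(arr, book$words[k, ], book)
    expect_identical(dec$hd, 0L)
    expect_identical(unname(dec$origin), unname(book$origins[k, ]))
    expect_true(is.na(dec$corrected_position))
  }
})

test_that("single errors are corrected to the true origin, double rejected", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  set.seed(11)
  arr <- unflatten_codeword(1:9)
  for (i in 1:60) {
    k <- sample(book$count, 1)
    w <- book$words[k, ]
    pos <- sample(9, 1)
    w[pos] <- (w[pos] + sample(5, 1)) %% 6L
    dec <- decode_codeword(arr, w, book)
    expect_identical(dec$hd, 1L)
    expect_identical(unname(dec$origin), unname(book$origins[k, ]))
    expect_identical(dec$corrected_position, pos)
    expect_identical(dec$word, book$words[k, ])
  }
  # a double error is never accepted at the true origin: it is either
  # rejected outright or, when both flips land on the differing positions
  # of a codeword at distance exactly 3, miscorrected to that alias --
  # the standard behaviour of a minimum-distance-3 code under two errors
  for (i in 1:60) {
    k <- sample(book$count, 1)
    w <- book$words[k, ]
    pos <- sample(9, 2)
    w[pos] <- (w[pos] + sample(5, 2, replace = TRUE)) %% 6L
    dec <- decode_codeword(arr, w, book)
    if (is.null(dec)) next
    expect_false(all(dec$origin == book$origins[k, ]))
    expect_identical(dec$hd, 1L)
    expect_identical(hamming_distance(dec$word, book$words[k, ]), 3L)
  }
})

test_that("a shared misclassification is corrected and propagates", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  ls <- lattice_scene(p, 5, 5, origin = c(3L, 4L))
  cands <- extract_subpatterns(ls$pts)
  labels <- ls$labels
  # central symbol of the 5x5 block appears in all nine interior codewords
  ctr <- which(ls$grid$r == 3 & ls$grid$c == 3)
  truth <- labels[ctr]
  labels[ctr] <- (truth + 1L) %% 6L
  out <- propagate_corrections(cands, labels, book)
  expect_identical(out$labels[ctr], truth)
  expect_identical(out$n_corrected, 1L)
  expect_length(out$decoded, 9L)
  # after correction every decoded codeword sits at distance <= 1, and the
  # fixed point would re-decode them all at 0
  out2 <- propagate_corrections(cands, out$labels, book)
  expect_true(all(vapply(out2$decoded, function(d) d$hd, 0L) == 0L))
})

test_that("no misclassifications means a one-pass fixed point", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  ls <- lattice_scene(p, 4, 4)
  out <- propagate_corrections(extract_subpatterns(ls$pts), ls$labels, book)
  expect_identical(out$n_corrected, 0L)
  expect_length(out$decoded, 4L)  # 2x2 interior centres
  expect_lte(out$iterations, 2L)
})

test_that("two errors in one codeword are recovered via propagation", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  ls <- lattice_scene(p, 5, 7, origin = c(5L, 2L))
  labels <- ls$labels
  # corrupt two symbols of the codeword centred at (3, 4); each is also
  # covered by cleaner codewords centred further left/right
  s1 <- which(ls$grid$r == 3 & ls$grid$c == 3)
  s2 <- which(ls$grid$r == 3 & ls$grid$c == 5)
  labels[s1] <- (labels[s1] + 1L) %% 6L
  labels[s2] <- (labels[s2] + 2L) %% 6L
  out <- propagate_corrections(extract_subpatterns(ls$pts), labels, book)
  expect_identical(out$labels[s1], ls$labels[s1])
  expect_identical(out$labels[s2], ls$labels[s2])
  expect_gte(out$iterations, 2L)
  # the double-error codeword itself ends up decoded
  centres <- vapply(out$decoded, function(d) d$members[5L], 0L)
  ctr34 <- which(ls$grid$r == 3 & ls$grid$c == 4)
  expect_true(ctr34 %in% centres)
})

test_that("conflicting corrections leave the symbol unchanged", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  # two disjoint windows; graft one component of the first into the second
  # so its label is wrong for both, with different implied corrections
  w1 <- c(2L, 2L); w2 <- c(6L, 8L)
  if (p$labels[w1[1] + 1, w1[2] + 1] == p$labels[w2[1] + 1, w2[2] + 1]) {
    w2 <- c(6L, 9L)
  }
  expect_false(p$labels[w1[1] + 1, w1[2] + 1] == p$labels[w2[1] + 1, w2[2] + 1])
  arr1 <- unflatten_codeword(1:9)     # components 1..9
  arr2 <- unflatten_codeword(c(10:13, 5L, 14:17))  # component 5 grafted in
  labels <- c(flatten_subpattern(subpattern_at(p, w1[1], w1[2])),
              flatten_subpattern(subpattern_at(p, w2[1], w2[2])))[c(1:9, 10:13, 15:18)]
  third <- setdiff(0:5, c(p$labels[w1[1] + 1, w1[2] + 1],
                          p$labels[w2[1] + 1, w2[2] + 1]))[1L]
  labels[5L] <- third
  cands <- list(
    list(center = 5L, arrangement = arr1, valid = TRUE, failure_reason = "none"),
    list(center = 14L, arrangement = arr2, valid = TRUE, failure_reason = "none")
  )
  out <- propagate_corrections(cands, labels, book)
  expect_identical(out$labels[5L], third)   # abstention
  expect_true(5L %in% out$conflicts)
  expect_length(out$decoded, 2L)            # both still accepted at hd = 1
})

test_that("correspondences are one per decoded symbol with set-union counts", {
  p <- test_pattern_small()
  book <- codeword_book(p)
  ppts <- pattern_centroids(p, 640, 480)
  ls <- lattice_scene(p, 3, 4, origin = c(2L, 5L))
  cands <- extract_subpatterns(ls$pts)
  out <- propagate_corrections(cands, ls$labels, book)
  # 3x4 lattice: two interior centres -> two overlapping codewords sharing 6
  expect_length(out$decoded, 2L)
  corr <- extract_correspondences(out$decoded, ppts, ls$pts)
  expect_identical(nrow(corr), 12L)
  one <- extract_correspondences(out$decoded[1L], ppts, ls$pts)
  expect_identical(nrow(one), 9L)
  # grid positions match the block origin
  expect_setequal(unique(corr$grid_row), 2:4)
  expect_setequal(unique(corr$grid_col), 5:8)
})

test_that("participation counts follow the border-distance formula", {
  p <- generate_pattern(10, 10, seed = 2)
  book <- codeword_book(p)
  ls <- lattice_scene(p, 10, 10)
  out <- propagate_corrections(extract_subpatterns(ls$pts), ls$labels, book)
  counts <- codeword_participation(nrow(ls$pts), out$decoded)
  # closed form: centres live on 2..9; a symbol at (r, c) belongs to the
  # codewords centred in the intersection of its 3x3 ring with that range
  for (i in seq_len(nrow(ls$pts))) {
    r <- ls$grid$r[i]; cc <- ls$grid$c[i]
    nr <- length(intersect((r - 1):(r + 1), 2:9))
    nc <- length(intersect((cc - 1):(cc + 1), 2:9))
    expect_identical(counts[i], as.integer(nr * nc))
  }
  expect_identical(max(counts), 9L)
  expect_true(all(counts[ls$grid$r == 1] < 9L))
})
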
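#' Decode one subpattern candidate against the codeword book
#'
#' The candidate arrangement is flattened in the fixed encoder order and
#' compared to every book codeword. It is accepted when the minimum Hamming
#' distance is 0 or 1 with a unique minimizer; at distance 1 the mismatching
#' position identifies the single misclassified symbol. Because the book has
#' pairwise distance >= 3, two book entries can never both lie within
#' distance 1 of the same word.
#'
#' @param arrangement 3x3 matrix of component indices.
#' @param labels Integer vector of class ids, indexed by component.
#' @param book A `csl_codebook` from [codeword_book()].
#' @return `NULL` if rejected, else a list with `origin` (1-based pattern
#'   (row, col) of the window), `hd` (0 or 1), `corrected_position`
#'   (codeword index 1..9, or `NA`), `members` (the 9 component indices in
#'   codeword order) and `word` (the corrected codeword).
#' @export
decode_codeword <- function(arrangement, labels, book) {
  members <- as.vector(t(arrangement))
  word <- labels[members]
  hd <- rowSums(book$words != matrix(word, nrow(book$words), 9L, byrow = TRUE))
  mn <- min(hd)
  if (mn > 1L) return(NULL)
  hits <- which(hd == mn)
  if (length(hits) != 1L) {
    stop("non-unique minimizer at Hamming distance <= 1; codeword book violates the distance-3 property")
  }
  truth <- book$words[hits, ]
  pos <- which(word != truth)
  list(origin = book$origins[hits, ], hd = as.integer(mn),
       corrected_position = if (mn == 1L) pos else NA_integer_,
       members = members, word = truth)
}

#' Decode all candidates with iterative single-error correction
#'
#' First pass: every valid candidate within Hamming distance 0 or 1 of a
#' book codeword is accepted. Each distance-1 acceptance identifies one
#' misclassified image symbol, whose class label is then corrected globally,
#' which can bring further codewords within decoding distance; passes repeat
#' until no new correction is possible. Conflicting corrections for the same
#' symbol (different target classes in the same pass) leave that symbol
#' unchanged. Accepted codewords are never revoked, so the accepted set
#' grows monotonically and the loop terminates.
#'
#' @param candidates List of subpattern candidates from
#'   [extract_subpatterns()].
#' @param labels Integer vector of class ids per component (from
#'   [classify_components()]).
#' @param book A `csl_codebook`.
#' @return List with `decoded` (list of acceptances as in
#'   [decode_codeword()], keyed by candidate), `labels` (corrected labels),
#'   `n_corrected` (symbols whose class was rewritten), `conflicts`
#'   (component indices with conflicting corrections), `iterations`.
#' @export
propagate_corrections <- function(candidates, labels, book) {
  valid <- Filter(function(x) isTRUE(x$valid), candidates)
  decoded <- vector("list", length(valid))
  labels <- as.integer(labels)
  corrected <- integer(0)
  conflicts <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    proposals <- list()
    for (i in seq_along(valid)) {
      if (!is.null(decoded[[i]])) next
      dec <- decode_codeword(valid[[i]]$arrangement, labels, book)
      if (is.null(dec)) next
      decoded[[i]] <- dec
      if (dec$hd == 1L) {
        comp <- dec$members[dec$corrected_position]
        proposals[[length(proposals) + 1L]] <-
          c(comp = comp, class = dec$word[dec$corrected_position])
      }
    }
    if (length(proposals) == 0L) break
    pr <- unique(do.call(rbind, proposals))
    changed <- FALSE
    for (comp in unique(pr[, "comp"])) {
      cls <- unique(pr[pr[, "comp"] == comp, "class"])
      if (length(cls) > 1L) {
        conflicts <- union(conflicts, comp)
      } else if (labels[comp] != cls) {
        labels[comp] <- cls
        corrected <- union(corrected, comp)
        changed <- TRUE
      }
    }
    if (!changed) break
    if (iter > length(labels)) break  # safety; cannot trigger with monotone acceptance
  }
  list(decoded = Filter(Negate(is.null), decoded), labels = labels,
       n_corrected = length(corrected), conflicts = conflicts,
       iterations = iter)
}

#' Pattern-image correspondences from the decoded codeword set
#'
#' Each image symbol that belongs to at least one decoded codeword is
#' decoded; its pattern grid position must agree across all codewords that
#' contain it, otherwise it is dropped. One correspondence is emitted per
#' distinct decoded symbol, pairing the symbol-cell centroid in the rendered
#' pattern with the detected component centroid in the image.
#'
#' @param decoded `decoded` element of [propagate_corrections()].
#' @param pattern_pts Pattern centroids from [pattern_centroids()].
#' @param centroids Image component centroid matrix (row, col), 0-based.
#' @return A data.frame with one row per decoded symbol: `component`,
#'   `grid_row`, `grid_col`, `pattern_x`, `pattern_y`, `image_x`, `image_y`,
#'   `hd` (best codeword distance for that symbol).
#' @export
extract_correspondences <- function(decoded, pattern_pts, centroids) {
  if (length(decoded) == 0L) {
    return(data.frame(component = integer(0), grid_row = integer(0),
                      grid_col = integer(0), pattern_x = numeric(0),
                      pattern_y = numeric(0), image_x = numeric(0),
                      image_y = numeric(0), hd = integer(0)))
  }
  rows <- list()
  for (dec in decoded) {
    offs <- expand.grid(dr = 0:2, dc = 0:2)
    # members are in row-major codeword order
    ord <- order(offs$dr, offs$dc)
    for (k in seq_len(9L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        component = dec$members[k],
        grid_row = dec$origin[["row"]] + offs$dr[ord][k],
        grid_col = dec$origin[["col"]] + offs$dc[ord][k],
        hd = dec$hd
      )
    }
  }
  tab <- do.call(rbind, rows)
  out <- list()
  for (comp in unique(tab$component)) {
    sub <- tab[tab$component == comp, , drop = FALSE]
    pos <- unique(sub[, c("grid_row", "grid_col")])
    if (nrow(pos) != 1L) next  # inconsistent grid position: drop symbol
    pp <- pattern_pts[pattern_pts$row == pos$grid_row &
                      pattern_pts$col == pos$grid_col, ]
    if (nrow(pp) != 1L) next
    out[[length(out) + 1L]] <- data.frame(
      component = comp, grid_row = pos$grid_row, grid_col = pos$grid_col,
      pattern_x = pp$x, pattern_y = pp$y,
      image_x = centroids[comp, 2L], image_y = centroids[comp, 1L],
      hd = min(sub$hd)
    )
  }
  res <- do.call(rbind, out)
  res[order(res$grid_row, res$grid_col), , drop = FALSE]
}

#' Number of decoded codewords each component participates in
#'
#' Symbols deep inside the lattice can appear in up to nine codewords;
#' symbols near the object outline in fewer, which is why decoding losses
#' concentrate at boundaries.
#'
#' @param n_components Total number of components.
#' @param decoded `decoded` element of [propagate_corrections()].
#' @return Integer vector of per-component counts in 0..9.
#' @export
codeword_participation <- function(n_components, decoded) {
  counts <- integer(n_components)
  for (dec in decoded) {
    counts[dec$members] <- counts[dec$members] + 1L
  }
  counts
}
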
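#' Decode a captured image and reconstruct the 3D point cloud
#'
#' Runs the full one-shot decoding pipeline: grayscale conversion (if
#' needed), binarization (adaptive Sauvola by default, or global Otsu for
#' comparison), connected-component noise filtering, rotation/scale template
#' classification, 3x3 subpattern assembly with consistency checks,
#' error-correcting codeword decoding with iterative correction propagation,
#' correspondence extraction, and triangulation with morphometrics.
#'
#' @param image A `csl_scene` from [render_scene()], a grayscale matrix
#'   (0..255), an RGB array, or a file path readable by [read_image()].
#' @param pattern The projected `csl_pattern`.
#' @param calib A `csl_calibration`.
#' @param binarization `"sauvola"` or `"otsu"`.
#' @param window,k Sauvola parameters (see [sauvola_binarize()]).
#' @param min_area Connected-component noise floor in pixels.
#' @param break_factor Chain-break multiplier (see [assemble_subpattern()]).
#' @param roi_offset 0-based `(x0, y0)` of the image within the full camera
#'   frame; taken from the scene when `image` is a `csl_scene`.
#' @param classifier Optional prebuilt [classifier_config()] (reused across
#'   calls to share the template cache).
#' @return A `csl_result`: list with `components`, `classification`,
#'   `subpatterns`, `decode` (output of [propagate_corrections()]),
#'   `correspondences`, `cloud`, `morphometrics` (or `NULL` if too few
#'   points), `participation`, and `counts` (per-stage tallies).
#' @export
reconstruct_image <- function(image, pattern, calib,
                              binarization = c("sauvola", "otsu"),
                              window = 31L, k = 0.2, min_area = 50L,
                              break_factor = 1.8, roi_offset = c(0L, 0L),
                              classifier = NULL) {
  binarization <- match.arg(binarization)
  if (inherits(image, "csl_scene")) {
    roi_offset <- c(image$roi[["x0"]], image$roi[["y0"]])
    gray <- image$camera_image
  } else if (is.character(image)) {
    gray <- read_image(image)
    if (length(dim(gray)) == 3L) gray <- to_grayscale(gray)
  } else if (length(dim(image)) == 3L) {
    gray <- to_grayscale(image)
  } else {
    gray <- image
  }
  mask <- if (binarization == "sauvola") {
    sauvola_binarize(gray, window = window, k = k)
  } else {
    otsu_binarize(gray)
  }
  components <- extract_components(mask, min_area = min_area)
  if (length(components) == 0L) {
    stop("no components: binarized image contains no symbol candidates")
  }
  if (is.null(classifier)) classifier <- classifier_config()
  classification <- classify_components(components, classifier)
  centroids <- t(vapply(components, function(x) x$centroid, numeric(2L)))
  labels <- classification$class
  # Neighbourhood topology runs on bounding-box centres: unlike the
  # foreground centroid, the bbox centre is nearly class-independent, so the
  # reference lattice stays regular whatever symbol occupies a cell.
  # Correspondence feature points remain the true foreground centroids.
  refpts <- t(vapply(components, function(x) {
    c((x$bbox[["top"]] + x$bbox[["bottom"]]) / 2,
      (x$bbox[["left"]] + x$bbox[["right"]]) / 2)
  }, numeric(2L)))
  subpatterns <- extract_subpatterns(refpts, break_factor = break_factor)
  book <- codeword_book(pattern)
  decode <- propagate_corrections(subpatterns, labels, book)
  ppts <- pattern_centroids(pattern, calib$proj_resolution[1L],
                            calib$proj_resolution[2L])
  cent_full <- centroids
  cent_full[, 1L] <- cent_full[, 1L] + roi_offset[2L]  # row += y0
  cent_full[, 2L] <- cent_full[, 2L] + roi_offset[1L]  # col += x0
  corr <- extract_correspondences(decode$decoded, ppts, cent_full)
  cloud <- triangulate_correspondences(corr, calib)
  morph <- if (nrow(cloud$points) >= 10L) {
    tryCatch(measure_cloud(cloud), error = function(e) NULL)
  } else NULL
  counts <- c(
    components = length(components),
    symbols_classified = nrow(classification),
    subpatterns_valid = sum(vapply(subpatterns, function(x) x$valid, TRUE)),
    codewords_decoded = length(decode$decoded),
    corresponding_points = nrow(corr),
    points_triangulated = nrow(cloud$points)
  )
  structure(
    list(mask = mask, components = components, classification = classification,
         subpatterns = subpatterns, decode = decode, correspondences = corr,
         cloud = cloud, morphometrics = morph,
         participation = codeword_participation(length(components),
                                                decode$decoded),
         counts = counts),
    class = "csl_result"
  )
}

#' @export
print.csl_result <- function(x, ...) {
  cat("<csl_result>\n")
  print(stage_counts(x))
  invisible(x)
}

#' Per-stage tallies of a pipeline run
#'
#' Three headline rows mirror the standard reporting of one-shot decoders:
#' symbols found in the binarized image, valid codewords, and the final
#' number of corresponding points.
#'
#' @param result A `csl_result`.
#' @return A data.frame with columns `stage` and `count`.
#' @export
stage_counts <- function(result) {
  data.frame(
    stage = c("Number of symbols in the image",
              "Number of valid codewords",
              "Final number of corresponding points",
              "Components detected", "Subpatterns valid",
              "Points triangulated"),
    count = unname(c(result$counts[["symbols_classified"]],
                     result$counts[["codewords_decoded"]],
                     result$counts[["corresponding_points"]],
                     result$counts[["components"]],
                     result$counts[["subpatterns_valid"]],
                     result$counts[["points_triangulated"]]))
  )
}

#' Write every inspectable artifact of a pipeline run to a directory
#'
#' @param result A `csl_result`.
#' @param dir Output directory.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_png(result$mask, file.path(dir, "mask.png"))
  utils::write.csv(components_table(result$components),
                   file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(result$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(result$subpatterns, function(x) {
    data.frame(center = x$center, valid = x$valid, reason = x$failure_reason)
  }))
  utils::write.csv(sp, file.path(dir, "subpatterns.csv"), row.names = FALSE)
  utils::write.csv(result$correspondences,
                   file.path(dir, "correspondences.csv"), row.names = FALSE)
  if (nrow(result$cloud$points) > 0L) {
    write_ply(result$cloud, file.path(dir, "cloud.ply"))
    write_xyz(result$cloud, file.path(dir, "cloud.xyz"))
    utils::write.csv(depth_map(result$cloud), file.path(dir, "depth_map.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(stage_counts(result), file.path(dir, "stage_counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}
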
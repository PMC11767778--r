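#' Analyze one calibrated field
#'
#' The full single-field pipeline: threshold, refine boundaries, label
#' connected components, measure particles, apply the detection gate,
#' classify into size populations, and compute the field's aggregation
#' indices.
#'
#' @param image a \code{\link{calibrated_image}}.
#' @param method,fixed_threshold,polarity passed to \code{\link{binarize}}.
#' @param connectivity passed to \code{\link{label_components}}.
#' @param binning a \code{\link{population_binning}}.
#' @param overlay logical: also render the color-coded overlay?
#' @param verbose logical: log the per-population counts and areas?
#' @return list with \code{result} (one-row field-result data frame),
#'   \code{records} (classified particle table), \code{labeled},
#'   \code{mask}, and \code{overlay} (or \code{NULL}).
#' @export
analyze_image <- function(image, method = "otsu", fixed_threshold = NULL,
                          polarity = "auto", connectivity = 8L,
                          binning = population_binning(), overlay = FALSE,
                          verbose = FALSE) {
  mask <- refine(binarize(image, method = method,
                          fixed_threshold = fixed_threshold,
                          polarity = polarity))
  labeled <- label_components(mask, connectivity = connectivity)
  records <- classify_records(measure_particles(labeled, image), binning)
  result <- compute_field_result(records, image)
  if (verbose) {
    message(sprintf("[%s] threshold=%s (%s, %s), %d particles after gate",
                    image$source_id,
                    format(attr(mask, "threshold"), digits = 5),
                    attr(mask, "method"), attr(mask, "polarity"),
                    nrow(records)))
    for (p in paste0("P", 0:5)) {
      sel <- records$population == p
      message(sprintf("  %s: NA=%d, total area=%d px (%.1f um^2)", p,
                      sum(sel), sum(records$area_px[sel]),
                      sum(records$area_um2[sel])))
    }
  }
  ov <- if (overlay) colorize(labeled, records) else NULL
  list(result = result, records = records, labeled = labeled, mask = mask,
       overlay = ov)
}

#' Run the pipeline over a batch of images
#'
#' Applies \code{\link{analyze_image}} to each input and collects the
#' per-field results into one table. Inputs may be file paths (read with
#' \code{um_per_px} and \code{group_labels}) or ready
#' \code{\link{calibrated_image}} objects. Per-image failures are logged and
#' skipped; the call errors only if every image fails.
#'
#' @param inputs character vector of image paths, or a list of
#'   \code{calibrated_image} objects.
#' @param um_per_px spatial calibration used when reading paths.
#' @param group_labels group label(s), recycled over the inputs (paths only).
#' @param out_dir optional directory: writes \code{results.csv},
#'   per-image particle tables and PNG overlays there.
#' @inheritParams analyze_image
#' @return the results data frame (one row per successfully analyzed field),
#'   with the per-image outputs in attribute \code{details}.
#' @export
run_pipeline <- function(inputs, um_per_px = NULL, group_labels = "",
                         method = "otsu", fixed_threshold = NULL,
                         polarity = "auto", connectivity = 8L,
                         binning = population_binning(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(inputs)) {
    if (is.null(um_per_px))
      stop("'um_per_px' is required when 'inputs' are file paths")
    labels <- rep_len(group_labels, length(inputs))
    images <- Map(function(p, g) try(read_image(p, um_per_px, g),
                                     silent = TRUE),
                  inputs, labels)
  } else {
    images <- inputs
  }
  if (!length(images)) stop("no input images")
  results <- list(); details <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    res <- if (inherits(img, "try-error")) img else
      try(analyze_image(img, method = method,
                        fixed_threshold = fixed_threshold,
                        polarity = polarity, connectivity = connectivity,
                        binning = binning, overlay = !is.null(out_dir),
                        verbose = verbose), silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("image ", i, " failed and was skipped: ",
              attr(res, "condition")$message %||% as.character(res))
      next
    }
    results[[length(results) + 1L]] <- res$result
    details[[res$result$source_id]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      base <- tools::file_path_sans_ext(res$result$source_id)
      write_overlay(res$overlay, file.path(out_dir,
                                           paste0(base, "_overlay.png")))
      write.csv(res$records, file.path(out_dir,
                                       paste0(base, "_particles.csv")),
                row.names = FALSE)
    }
  }
  if (!length(results)) stop("all input images failed")
  tab <- do.call(rbind, results)
  if (!is.null(out_dir)) write_results(tab, file.path(out_dir, "results.csv"))
  attr(tab, "details") <- details
  tab
}
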
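#' Size-population binning for RBC aggregates
#'
#' The six area-defined populations used throughout the pipeline, in square
#' micrometres of projected area:
#' \itemize{
#'   \item P0 \[50, 100): individual unaggregated cells,
#'   \item P1 \[100, 331): small linear rouleaux,
#'   \item P2 \[331, 661): branched rouleaux,
#'   \item P3 \[661, 1321) and P4 \[1321, 2701): 3-D clusters,
#'   \item P5 \[2701, Inf): large aggregate networks.
#' }
#' Bins are half-open, mutually exclusive and jointly cover
#' \[\code{min_detect_um2}, Inf). Particles below the 50 um^2 detection gate
#' are never measured as aggregates. Display colors: P0 white, P1 green,
#' P2 blue, P3 cyan, P4 magenta, P5 yellow.
#'
#' @param edges increasing numeric vector of lower bin boundaries, one per
#'   population (the last bin is unbounded above).
#' @param min_detect_um2 detection gate in um^2 (inclusive).
#' @return An object of class \code{population_binning}.
#' @export
population_binning <- function(edges = c(50, 100, 331, 661, 1321, 2701),
                               min_detect_um2 = 50) {
  if (length(edges) != 6L || any(diff(edges) <= 0))
    stop("'edges' must be 6 strictly increasing lower boundaries (P0..P5)")
  if (min_detect_um2 > edges[1L])
    stop("'min_detect_um2' cannot exceed the first bin edge")
  structure(
    list(edges = as.numeric(edges),
         labels = paste0("P", 0:5),
         colors = c(P0 = "white", P1 = "green", P2 = "blue",
                    P3 = "cyan", P4 = "magenta", P5 = "yellow"),
         min_detect_um2 = as.numeric(min_detect_um2)),
    class = "population_binning")
}

#' @export
print.population_binning <- function(x, ...) {
  up <- c(x$edges[-1L], Inf)
  cat("<population_binning> (um^2, half-open bins)\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %s [%g, %g)  %s\n", x$labels[i], x$edges[i], up[i],
                x$colors[i]))
  cat(sprintf("  detection gate: >= %g um^2\n", x$min_detect_um2))
  invisible(x)
}

#' Measure labeled particles
#'
#' One record per labeled region: exact pixel count, physical area
#' (\code{area_px * um_per_px^2}), centroid and bounding box. Population
#' assignment happens later, after the detection gate.
#'
#' @param labeled a \code{labeled_image} from \code{\link{label_components}}.
#' @param image the \code{\link{calibrated_image}} the labeling derives from
#'   (provides the calibration and shape check).
#' @return data frame with columns \code{label_id}, \code{area_px},
#'   \code{area_um2}, \code{centroid_row}, \code{centroid_col} (0-based pixel
#'   coordinates), \code{bbox_min_row}, \code{bbox_min_col},
#'   \code{bbox_max_row}, \code{bbox_max_col} (half-open, 0-based) and
#'   \code{population} (all \code{NA} at this stage).
#' @export
measure_particles <- function(labeled, image) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!identical(dim(labeled)[1:2], dim(image$pixels)[1:2]))
    stop("'labeled' and 'image' shapes differ")
  n <- attr(labeled, "n_labels")
  s2 <- image$um_per_px^2
  if (is.null(n) || n == 0L) return(empty_records())
  idx <- which(labeled != 0L)
  lab <- as.integer(labeled[idx])
  H <- nrow(labeled)
  r0 <- ((idx - 1L) %% H)          # 0-based row
  c0 <- ((idx - 1L) %/% H)         # 0-based col
  area_px <- as.integer(tabulate(lab, nbins = n))
  cen_r <- rowsum(as.numeric(r0), lab)[, 1L] / area_px
  cen_c <- rowsum(as.numeric(c0), lab)[, 1L] / area_px
  bb_minr <- tapply(r0, lab, min)
  bb_minc <- tapply(c0, lab, min)
  bb_maxr <- tapply(r0, lab, max) + 1L
  bb_maxc <- tapply(c0, lab, max) + 1L
  data.frame(
    label_id = seq_len(n),
    area_px = area_px,
    area_um2 = area_px * s2,
    centroid_row = as.numeric(cen_r),
    centroid_col = as.numeric(cen_c),
    bbox_min_row = as.integer(bb_minr),
    bbox_min_col = as.integer(bb_minc),
    bbox_max_row = as.integer(bb_maxr),
    bbox_max_col = as.integer(bb_maxc),
    population = NA_character_,
    stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(label_id = integer(0), area_px = integer(0),
             area_um2 = numeric(0), centroid_row = numeric(0),
             centroid_col = numeric(0), bbox_min_row = integer(0),
             bbox_min_col = integer(0), bbox_max_row = integer(0),
             bbox_max_col = integer(0), population = character(0),
             stringsAsFactors = FALSE)
}

#' Apply the particle-detection area gate
#'
#' Drops records below the detection gate (50 um^2 by default, inclusive:
#' particle analysis runs on the area interval \[gate, Inf)). Order is
#' preserved.
#'
#' @param records data frame from \code{\link{measure_particles}}.
#' @param binning a \code{\link{population_binning}}.
#' @return the gated data frame.
#' @export
apply_detection_gate <- function(records, binning = population_binning()) {
  stopifnot(inherits(binning, "population_binning"))
  records[records$area_um2 >= binning$min_detect_um2, , drop = FALSE]
}

#' Assign areas to size populations
#'
#' Maps each physical area to the unique half-open population bin containing
#' it. Vectorized.
#'
#' @param area_um2 numeric vector of areas, all at or above the detection
#'   gate.
#' @param binning a \code{\link{population_binning}}.
#' @return character vector of population labels (\code{"P0"}..\code{"P5"}).
#' @export
assign_population <- function(area_um2, binning = population_binning()) {
  stopifnot(inherits(binning, "population_binning"))
  if (any(area_um2 < binning$min_detect_um2))
    stop("area below the ", binning$min_detect_um2,
         " um^2 detection gate: gate before assigning populations")
  i <- findInterval(area_um2, binning$edges)   # half-open [edge_i, edge_{i+1})
  binning$labels[i]
}

#' Gate and classify particle records in one step
#'
#' @inheritParams apply_detection_gate
#' @return gated records with the \code{population} column filled in.
#' @export
classify_records <- function(records, binning = population_binning()) {
  gated <- apply_detection_gate(records, binning)
  if (nrow(gated)) gated$population <- assign_population(gated$area_um2, binning)
  gated
}
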
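#' Specification of a synthetic microscopy field
#'
#' Describes a calibrated synthetic phase-contrast field: isolated cell discs,
#' linear rouleaux chains (overlapping-disc "coin stacks"), and compact 3-D
#' cluster blobs on a uniform background with optional Gaussian noise. All
#' object geometry is defined in micrometres and rasterized at
#' \code{um_per_px}, so the same seed renders the same physical scene at any
#' resolution (the field extent in um must match, e.g. double
#' \code{field_shape} when halving \code{um_per_px}).
#'
#' @param field_shape (height, width) in pixels; default 300 x 1600, the
#'   native microfluidic field frame.
#' @param um_per_px micrometres per pixel (isotropic).
#' @param n_singles number of isolated cell discs.
#' @param rouleaux list of \code{c(n_cells, orientation)} pairs (orientation
#'   in radians).
#' @param clusters numeric vector of cluster target areas (um^2, each
#'   >= 100).
#' @param cell_diameter_um cell disc diameter (default 7.8 um, a typical
#'   RBC).
#' @param overlap_fraction center-to-center overlap of neighbouring cells in
#'   a rouleau (default 0.5).
#' @param foreground_level,background_level object and background
#'   intensities (default 70 on 190: dark cells on a bright background).
#' @param noise_sd Gaussian noise SD in intensity units (0 = noise-free).
#' @param gap_um minimum edge-to-edge clearance between objects in um
#'   (default 2; must be at least 2 pixels so ground truth and
#'   8-connectivity labeling agree).
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @param group_label group label stamped on the generated image.
#' @param bit_depth 8 or 16.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(field_shape = c(300L, 1600L), um_per_px = 0.5,
                           n_singles = 0L, rouleaux = list(),
                           clusters = numeric(0), cell_diameter_um = 7.8,
                           overlap_fraction = 0.5,
                           foreground_level = 70, background_level = 190,
                           noise_sd = 0, gap_um = 2, seed = 1L,
                           group_label = "synthetic", bit_depth = 8L) {
  stopifnot(length(field_shape) == 2L, all(field_shape >= 8L),
            um_per_px > 0, n_singles >= 0L, cell_diameter_um > 0,
            overlap_fraction > 0, overlap_fraction < 1, noise_sd >= 0)
  if (gap_um < 2 * um_per_px)
    stop("'gap_um' must be at least 2 pixels (", 2 * um_per_px,
         " um at this calibration) to keep objects separable")
  if (length(clusters) && any(clusters < 100))
    stop("cluster target areas must be >= 100 um^2")
  for (r in rouleaux)
    if (r[[1L]] < 2) stop("a rouleau needs at least 2 cells")
  maxval <- 2^bit_depth - 1
  stopifnot(foreground_level >= 0, foreground_level <= maxval,
            background_level >= 0, background_level <= maxval)
  structure(
    list(field_shape = as.integer(field_shape), um_per_px = um_per_px,
         n_singles = as.integer(n_singles), rouleaux = rouleaux,
         clusters = as.numeric(clusters),
         cell_diameter_um = cell_diameter_um,
         overlap_fraction = overlap_fraction,
         foreground_level = foreground_level,
         background_level = background_level,
         noise_sd = noise_sd, gap_um = gap_um, seed = as.integer(seed),
         group_label = group_label, bit_depth = as.integer(bit_depth)),
    class = "synthetic_spec")
}

# -- disc geometry (all in um, local frames centered near the origin) --------

single_discs <- function(d) cbind(x = 0, y = 0, r = d / 2)

rouleau_discs <- function(n_cells, orientation, d, overlap_fraction) {
  spacing <- d * (1 - overlap_fraction)
  t <- (seq_len(n_cells) - (n_cells + 1) / 2) * spacing
  cbind(x = t * cos(orientation), y = t * sin(orientation), r = d / 2)
}

# Random-walk cluster grown on a fixed internal reference raster (0.25 um/px)
# so the stopping decision — and hence the walk — is independent of the
# output resolution. Consumes the current RNG stream.
cluster_discs <- function(target_area_um2, ref_um_per_px = 0.25) {
  r_disc <- max(1.5, min(3, sqrt(target_area_um2) / 8))
  step <- r_disc
  # confine the walk so the blob stays compact and placeable in a channel
  # field: area pi R^2 >= target needs R >= sqrt(target/pi), 1.5x headroom
  r_max <- 1.5 * sqrt(target_area_um2 / pi) + 2 * r_disc
  s <- ref_um_per_px
  half <- ceiling((r_max + r_disc + 2) / s)
  n <- 2L * half + 1L
  acc <- matrix(FALSE, n, n)
  # reference-grid cell (i, j) has center ((j - 1 - half) s, (i - 1 - half) s)
  paint <- function(cx, cy) {
    jr <- max(1L, floor((cy - r_disc) / s) + half + 1L):
          min(n, ceiling((cy + r_disc) / s) + half + 1L)
    jc <- max(1L, floor((cx - r_disc) / s) + half + 1L):
          min(n, ceiling((cx + r_disc) / s) + half + 1L)
    py <- (jr - 1L - half) * s
    px <- (jc - 1L - half) * s
    hit <- outer((py - cy)^2, (px - cx)^2, `+`) <= r_disc^2
    sub <- acc[jr, jc, drop = FALSE]
    new <- hit & !sub
    acc[jr, jc] <<- sub | hit
    sum(new)
  }
  pos <- c(0, 0)
  centers <- matrix(pos, 1L, 2L)
  count <- paint(pos[1L], pos[2L])
  # the blob is hole-filled when rasterized, so the stopping rule tracks the
  # filled area: cheap unfilled count plus a fill surplus re-measured at
  # checkpoints once the target is near
  fill_extra <- 0
  for (i in 1:5000) {
    if ((count + fill_extra) * s^2 >= target_area_um2) {
      filled <- sum(EBImage::fillHull(acc) > 0)
      fill_extra <- filled - count
      if (filled * s^2 >= target_area_um2) break
    }
    ang <- runif(1, 0, 2 * pi)
    cand <- pos + step * c(cos(ang), sin(ang))
    if (sqrt(sum(cand^2)) > r_max) next
    pos <- cand
    centers <- rbind(centers, pos)
    count <- count + paint(pos[1L], pos[2L])
  }
  # recenter on the bounding-box midpoint: caps the bounding radius at
  # r_max + r_disc whatever shape the walk took
  ctr <- c(mean(range(centers[, 1L])), mean(range(centers[, 2L])))
  cbind(x = centers[, 1L] - ctr[1L], y = centers[, 2L] - ctr[2L], r = r_disc)
}

# -- rasterization -----------------------------------------------------------

# Pixel (i, j) (1-based row/col) covers x in [(j-1)s, js), y in [(i-1)s, is);
# its center is ((j-0.5)s, (i-0.5)s). A pixel belongs to an object when its
# center lies inside any of the object's discs.
rasterize_discs <- function(discs, um_per_px, fill_holes = TRUE) {
  s <- um_per_px
  xmin <- min(discs[, "x"] - discs[, "r"]); xmax <- max(discs[, "x"] + discs[, "r"])
  ymin <- min(discs[, "y"] - discs[, "r"]); ymax <- max(discs[, "y"] + discs[, "r"])
  j0 <- floor(xmin / s); j1 <- ceiling(xmax / s) + 1L
  i0 <- floor(ymin / s); i1 <- ceiling(ymax / s) + 1L
  jj <- j0:j1; ii <- i0:i1
  cx <- (jj - 0.5) * s; cy <- (ii - 0.5) * s
  m <- matrix(FALSE, length(ii), length(jj))
  for (k in seq_len(nrow(discs))) {
    dy2 <- (cy - discs[k, "y"])^2
    dx2 <- (cx - discs[k, "x"])^2
    m <- m | (outer(dy2, dx2, `+`) <= discs[k, "r"]^2)
  }
  if (fill_holes) m <- EBImage::fillHull(m) > 0
  w <- which(m, arr.ind = TRUE)
  # absolute 1-based pixel indices in a field whose pixel (1,1) covers [0,s)^2
  cbind(row = ii[w[, 1L]], col = jj[w[, 2L]])
}

#' Rasterize a linear rouleau chain
#'
#' A rouleau is modelled as \code{n_cells} overlapping discs with centers
#' spaced \code{cell_diameter_um * (1 - overlap_fraction)} along the chain
#' direction. The pixel set is connected and its area grows affinely with
#' the number of cells.
#'
#' @inheritParams synthetic_spec
#' @param n_cells number of cells (>= 2).
#' @param orientation chain direction in radians.
#' @return integer matrix of (row, col) pixel coordinates (0-based, local
#'   frame).
#' @export
render_rouleau <- function(n_cells, orientation, cell_diameter_um = 7.8,
                           overlap_fraction = 0.5, um_per_px = 0.5) {
  if (n_cells < 2) stop("a rouleau needs at least 2 cells")
  if (overlap_fraction <= 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must be in (0, 1)")
  px <- rasterize_discs(rouleau_discs(n_cells, orientation, cell_diameter_um,
                                      overlap_fraction),
                        um_per_px, fill_holes = FALSE)
  normalize_coords(px)
}

#' Rasterize a compact 3-D cluster blob
#'
#' A connected random blob (a dilated random walk of overlapping discs,
#' hole-filled) whose realized pixel area lies within 10\% of
#' \code{target_area_um2}. Consumes the current RNG stream: call
#' \code{set.seed} first for reproducibility.
#'
#' @inheritParams synthetic_spec
#' @param target_area_um2 target projected area (>= 100 um^2).
#' @return integer matrix of (row, col) pixel coordinates (0-based, local
#'   frame).
#' @export
render_cluster <- function(target_area_um2, um_per_px = 0.5) {
  if (target_area_um2 < 100)
    stop("'target_area_um2' must be >= 100")
  px <- rasterize_discs(cluster_discs(target_area_um2), um_per_px,
                        fill_holes = TRUE)
  normalize_coords(px)
}

normalize_coords <- function(px) {
  cbind(row = px[, "row"] - min(px[, "row"]),
        col = px[, "col"] - min(px[, "col"]))
}

# -- field generation --------------------------------------------------------

#' Generate a synthetic field with exact ground truth
#'
#' Builds the objects described by the spec, places them uniformly at random
#' in the field with at least \code{gap_um} edge-to-edge clearance (rejection
#' sampling in continuous um coordinates, so placement is identical across
#' rasterization resolutions), rasterizes them, and adds Gaussian noise. The
#' ground truth records each object's exact pre-noise pixel set, area,
#' centroid and size population.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param binning \code{\link{population_binning}} used for the true
#'   population labels.
#' @return list with elements \code{image} (a
#'   \code{\link{calibrated_image}}) and \code{truth} (class
#'   \code{synthetic_truth}: \code{$objects} per-object data frame with
#'   \code{true_area_px}, \code{true_area_um2}, \code{population},
#'   \code{detectable}, centroid; \code{$totals} per-population counts and
#'   areas over detectable objects).
#' @export
generate_field <- function(spec, binning = population_binning()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  s <- spec$um_per_px
  H <- spec$field_shape[1L]; W <- spec$field_shape[2L]
  H_um <- H * s; W_um <- W * s

  # geometry first: clusters consume RNG, rouleaux and singles do not
  objects <- list()
  for (a in spec$clusters)
    objects[[length(objects) + 1L]] <-
      list(kind = "cluster", discs = cluster_discs(a), target_um2 = a)
  for (r in spec$rouleaux)
    objects[[length(objects) + 1L]] <-
      list(kind = "rouleau",
           discs = rouleau_discs(r[[1L]], r[[2L]], spec$cell_diameter_um,
                                 spec$overlap_fraction),
           n_cells = r[[1L]])
  for (i in seq_len(spec$n_singles))
    objects[[length(objects) + 1L]] <-
      list(kind = "single", discs = single_discs(spec$cell_diameter_um))
  for (i in seq_along(objects)) objects[[i]]$id <- i

  # place largest first (stable order on ties)
  bound_r <- vapply(objects, function(o)
    max(sqrt(o$discs[, "x"]^2 + o$discs[, "y"]^2) + o$discs[, "r"]),
    numeric(1))
  ord <- order(-bound_r, seq_along(objects))
  placed <- matrix(numeric(0), 0L, 3L,
                   dimnames = list(NULL, c("x", "y", "r")))
  centers <- vector("list", length(objects))
  for (oi in ord) {
    o <- objects[[oi]]
    br <- bound_r[oi]
    margin <- br + spec$gap_um
    if (2 * margin >= W_um || 2 * margin >= H_um)
      stop("object ", oi, " (", o$kind, ", bounding radius ",
           round(br, 1), " um) cannot fit in a ", W_um, " x ", H_um,
           " um field")
    done <- FALSE
    for (try in 1:500) {
      cx <- runif(1, margin, W_um - margin)
      cy <- runif(1, margin, H_um - margin)
      cand <- cbind(x = o$discs[, "x"] + cx, y = o$discs[, "y"] + cy,
                    r = o$discs[, "r"])
      if (nrow(placed)) {
        dmin <- min(outer(cand[, "x"], placed[, "x"], `-`)^2 +
                    outer(cand[, "y"], placed[, "y"], `-`)^2 -
                    (outer(cand[, "r"], placed[, "r"], `+`) + spec$gap_um)^2)
        if (dmin < 0) next
      }
      centers[[oi]] <- c(cx, cy)
      placed <- rbind(placed, cand)
      done <- TRUE
      break
    }
    if (!done)
      stop("could not place object ", oi, " (", o$kind,
           ", bounding radius ", round(br, 1),
           " um) after 500 attempts: field too crowded")
  }

  # rasterize
  img <- matrix(spec$background_level, H, W)
  rows <- vector("list", length(objects))
  for (oi in seq_along(objects)) {
    o <- objects[[oi]]
    ctr <- centers[[oi]]
    discs <- cbind(x = o$discs[, "x"] + ctr[1L],
                   y = o$discs[, "y"] + ctr[2L], r = o$discs[, "r"])
    px <- rasterize_discs(discs, s, fill_holes = (o$kind == "cluster"))
    stopifnot(all(px[, "row"] >= 1L), all(px[, "row"] <= H),
              all(px[, "col"] >= 1L), all(px[, "col"] <= W))
    img[cbind(px[, "row"], px[, "col"])] <- spec$foreground_level
    area_px <- nrow(px)
    area_um2 <- area_px * s^2
    pop <- if (area_um2 >= binning$min_detect_um2)
      assign_population(area_um2, binning) else NA_character_
    rows[[oi]] <- data.frame(
      object_id = o$id, kind = o$kind,
      n_cells = if (o$kind == "rouleau") o$n_cells else NA_integer_,
      true_area_px = area_px, true_area_um2 = area_um2,
      centroid_row = mean(px[, "row"]) - 1, centroid_col = mean(px[, "col"]) - 1,
      population = pop,
      detectable = area_um2 >= binning$min_detect_um2,
      stringsAsFactors = FALSE)
  }
  objects_df <- if (length(rows)) do.call(rbind, rows) else data.frame()

  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  maxval <- 2^spec$bit_depth - 1
  img <- round(pmin(pmax(img, 0), maxval))

  image <- calibrated_image(img, s,
                            source_id = paste0("synthetic_seed", spec$seed),
                            group_label = spec$group_label,
                            bit_depth = spec$bit_depth)
  labels <- paste0("P", 0:5)
  det <- objects_df[isTRUE_vec(objects_df$detectable), , drop = FALSE]
  totals <- data.frame(
    population = labels,
    n = unname(vapply(labels, function(p) sum(det$population %in% p),
                      integer(1))),
    area_px = unname(vapply(labels, function(p)
      sum(det$true_area_px[det$population %in% p]), numeric(1))),
    area_um2 = unname(vapply(labels, function(p)
      sum(det$true_area_um2[det$population %in% p]), numeric(1))),
    row.names = NULL, stringsAsFactors = FALSE)
  truth <- structure(list(objects = objects_df, totals = totals,
                          field_shape = spec$field_shape,
                          um_per_px = s),
                     class = "synthetic_truth")
  list(image = image, truth = truth)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d objects (%d detectable) in %d x %d px\n",
              nrow(x$objects), sum(x$objects$detectable),
              x$field_shape[1L], x$field_shape[2L]))
  print(x$totals)
  invisible(x)
}
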
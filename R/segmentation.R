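#' Threshold a calibrated image into a binary aggregate mask
#'
#' Separates candidate RBC aggregates from the channel background with a
#' single global threshold, the same operation ImageJ performs when a field is
#' "made binary". Two automatic threshold estimators are offered — Otsu
#' (between-class variance, the default for cross-ecosystem reproducibility)
#' and IsoData (the iterative intermeans method behind ImageJ's default) — or
#' a fixed intensity can be supplied.
#'
#' Aggregates may image darker or brighter than the background depending on
#' phase-contrast focus. With \code{polarity = "auto"} the minority pixel
#' class is taken as foreground: aggregates occupy well under half of a field.
#'
#' @param image a \code{\link{calibrated_image}}.
#' @param method \code{"otsu"}, \code{"isodata"} or \code{"fixed"}.
#' @param fixed_threshold intensity threshold, required when
#'   \code{method = "fixed"}.
#' @param polarity \code{"auto"}, \code{"dark_foreground"} (foreground =
#'   pixels at or below the threshold) or \code{"bright_foreground"}.
#' @return A \code{binary_mask}: integer 0/1 matrix of the image's shape with
#'   attributes \code{threshold}, \code{method} and \code{polarity}
#'   (the resolved polarity, never \code{"auto"}).
#' @export
binarize <- function(image,
                     method = c("otsu", "isodata", "fixed"),
                     fixed_threshold = NULL,
                     polarity = c("auto", "dark_foreground",
                                  "bright_foreground")) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- image$pixels
  maxval <- 2^image$bit_depth - 1

  if (method == "fixed") {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold))
      stop("method = 'fixed' requires 'fixed_threshold'")
    thr <- as.numeric(fixed_threshold)
  } else {
    if (diff(range(px)) == 0) {
      warning("constant image: no contrast, returning an empty mask")
      m <- matrix(0L, nrow(px), ncol(px))
      return(new_binary_mask(m, threshold = NA_real_, method = method,
                             polarity = if (polarity == "auto")
                               "dark_foreground" else polarity))
    }
    thr <- if (method == "otsu") {
      EBImage::otsu(px / maxval, range = c(0, 1), levels = 2^image$bit_depth) *
        maxval
    } else {
      isodata_threshold(px)
    }
  }

  dark <- px <= thr
  pol <- polarity
  if (pol == "auto")
    pol <- if (sum(dark) <= length(dark) / 2) "dark_foreground"
           else "bright_foreground"
  fg <- if (pol == "dark_foreground") dark else !dark
  m <- matrix(0L, nrow(px), ncol(px))
  m[fg] <- 1L
  new_binary_mask(m, threshold = thr, method = method, polarity = pol)
}

new_binary_mask <- function(m, threshold, method, polarity) {
  structure(m, threshold = threshold, method = method, polarity = polarity,
            class = c("binary_mask", class(m)))
}

#' IsoData (iterative intermeans) threshold
#'
#' Iterates t <- mean(mean below t, mean above t) to a fixed point, the
#' Ridler-Calvard scheme underlying ImageJ's default auto-threshold.
#'
#' @param px numeric matrix of intensities.
#' @return threshold intensity (scalar).
#' @keywords internal
isodata_threshold <- function(px) {
  t_old <- -Inf
  t_new <- mean(range(px))
  for (i in 1:200) {
    lo <- px[px <= t_new]; hi <- px[px > t_new]
    if (!length(lo) || !length(hi)) break
    t_old <- t_new
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 0.5) break
  }
  t_new
}

#' Refine aggregate boundaries in a binary mask
#'
#' Boundary refinement ensures each aggregate is a single solid region before
#' particle analysis: interior holes are filled, then one binary opening with
#' a 3x3 box structuring element removes single-pixel salt noise, and any
#' interior holes the opening exposes are filled again. The foreground never
#' grows except by hole filling and never shrinks except where the opening
#' removes noise-scale protrusions; the operation is idempotent.
#'
#' @param mask a \code{binary_mask} (any 0/1 matrix is accepted).
#' @return refined \code{binary_mask}, attributes preserved.
#' @export
refine <- function(mask) {
  m <- unclass_mask(mask)
  f <- EBImage::fillHull(m)
  o <- EBImage::opening(f, EBImage::makeBrush(3L, shape = "box"))
  r <- EBImage::fillHull(o)
  out <- matrix(as.integer(r > 0), nrow(m), ncol(m))
  new_binary_mask(out,
                  threshold = attr(mask, "threshold"),
                  method = attr(mask, "method") %||% "unknown",
                  polarity = attr(mask, "polarity") %||% "dark_foreground")
}

unclass_mask <- function(mask) {
  m <- matrix(as.integer(unclass(mask) != 0), nrow(mask), ncol(mask))
  m
}

#' Label connected foreground components
#'
#' Connected-component particle detection: maximal connected foreground
#' regions are labeled 1..n in raster-scan order (row by row, left to right)
#' of each region's first pixel. Default 8-connectivity matches ImageJ's
#' particle analysis; 4-connectivity is available for comparison.
#'
#' @param mask a \code{binary_mask}.
#' @param connectivity 4 or 8.
#' @return A \code{labeled_image}: integer matrix (0 = background, k >= 1 =
#'   particle id) with attributes \code{n_labels} and \code{connectivity}.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  m <- unclass_mask(mask)
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  fg <- which(m != 0L)
  if (length(fg)) {
    rr <- ((fg - 1L) %% H) + 1L
    cc <- ((fg - 1L) %/% H) + 1L
    ord <- fg[order(rr, cc)]   # raster-scan (row-major) seed order
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
    if (connectivity == 8L) {
      dr <- c(dr, -1L, -1L, 1L, 1L)
      dc <- c(dc, -1L, 1L, -1L, 1L)
    }
    nlab <- 0L
    for (seed in ord) {
      if (lab[seed] != 0L) next
      nlab <- nlab + 1L
      lab[seed] <- nlab
      frontier <- seed
      while (length(frontier)) {
        fr <- ((frontier - 1L) %% H) + 1L
        fc <- ((frontier - 1L) %/% H) + 1L
        nbr <- integer(0)
        for (k in seq_along(dr)) {
          nr <- fr + dr[k]; nc <- fc + dc[k]
          ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
          if (any(ok)) nbr <- c(nbr, (nc[ok] - 1L) * H + nr[ok])
        }
        nbr <- unique(nbr)
        nbr <- nbr[m[nbr] != 0L & lab[nbr] == 0L]
        lab[nbr] <- nlab
        frontier <- nbr
      }
    }
  } else nlab <- 0L
  structure(lab, n_labels = nlab, connectivity = as.integer(connectivity),
            class = c("labeled_image", class(lab)))
}
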
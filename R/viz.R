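#' Population color palette
#'
#' Exact RGB codes (0-255) for the six size populations: P0 white, P1 green,
#' P2 blue, P3 cyan, P4 magenta, P5 yellow; background renders black.
#'
#' @return 6 x 3 integer matrix with rownames P0..P5 and columns r, g, b.
#' @export
population_palette <- function() {
  pal <- rbind(P0 = c(255, 255, 255),
               P1 = c(0, 255, 0),
               P2 = c(0, 0, 255),
               P3 = c(0, 255, 255),
               P4 = c(255, 0, 255),
               P5 = c(255, 255, 0))
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Color-coded overlay of classified aggregates
#'
#' Paints every pixel of every gated, classified particle with its
#' population's color on a black background; particles below the detection
#' gate (labels absent from \code{records}) render as background.
#'
#' @param labeled a \code{labeled_image}.
#' @param records gated, classified records covering the surviving labels.
#' @return an \code{overlay_image}: H x W x 3 numeric array in \[0, 1\]
#'   (multiply by 255 for the integer RGB codes) with attribute
#'   \code{palette}.
#' @export
colorize <- function(labeled, records) {
  n <- attr(labeled, "n_labels") %||% max(labeled)
  if (nrow(records)) {
    if (any(!records$label_id %in% seq_len(n)))
      stop("records reference label ids absent from the labeled image")
    if (anyNA(records$population))
      stop("records must be classified before colorizing")
  }
  pal <- population_palette()
  H <- nrow(labeled); W <- ncol(labeled)
  out <- array(0, dim = c(H, W, 3L))
  lut <- matrix(0, nrow = max(n, 1L), ncol = 3L)   # label -> rgb, 0 = drop
  if (nrow(records))
    lut[records$label_id, ] <- pal[records$population, , drop = FALSE] / 255
  idx <- which(labeled != 0L)
  if (length(idx)) {
    lab <- as.integer(labeled[idx])
    for (ch in 1:3)
      out[idx + (ch - 1L) * H * W] <- lut[lab, ch]
  }
  structure(out, palette = pal, class = c("overlay_image", "array"))
}

#' Write an overlay to a PNG file
#'
#' @param overlay an \code{overlay_image} from \code{\link{colorize}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  png::writePNG(unclass(overlay), path)
  invisible(path)
}
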
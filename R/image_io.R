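#' Construct a calibrated image
#'
#' A calibrated image is an integer-valued intensity matrix together with the
#' isotropic spatial calibration (micrometres per pixel) and provenance
#' metadata that every downstream stage carries along unchanged.
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param um_per_px positive scalar, micrometres per pixel (isotropic).
#' @param source_id character scalar identifying the field (e.g. file name).
#' @param group_label character scalar, study group of the sample
#'   (e.g. \code{"control"}, \code{"untreated"}, \code{"obin_ven"},
#'   \code{"ibrutinib"}).
#' @param bit_depth 8 or 16; intensities must lie in \code{[0, 2^bit_depth - 1]}.
#' @return An object of class \code{calibrated_image}.
#' @export
calibrated_image <- function(pixels, um_per_px, source_id = "",
                             group_label = "", bit_depth = 8L) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a matrix with at least one row and column")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop("'um_per_px' must be a single positive number")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > maxval))
    stop("pixel intensities outside the declared ", bit_depth, "-bit range")
  structure(
    list(pixels = pixels,
         um_per_px = as.numeric(um_per_px),
         source_id = as.character(source_id),
         group_label = as.character(group_label),
         bit_depth = as.integer(bit_depth)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px, x$bit_depth))
  cat(sprintf("  source: '%s'  group: '%s'\n", x$source_id, x$group_label))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read a grayscale microscopy image with its spatial calibration
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG. RGB images are converted
#' to grayscale by the unweighted channel mean. Multi-frame stacks are
#' rejected: each analyzed field is a single snapshot, batching over frames is
#' the caller's job.
#'
#' @inheritParams calibrated_image
#' @param path path to a TIFF or PNG file.
#' @return A \code{\link{calibrated_image}}; \code{source_id} is the file name.
#' @export
read_image <- function(path, um_per_px, group_label = "") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: file not found: ", path)
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
    stop("'um_per_px' must be a single positive number")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(raw) > 1L)
      stop("multi-frame TIFF stacks are unsupported; split into single frames")
    arr <- raw[[1L]]
    bps <- attr(arr, "bits.per.sample")
    attr(arr, "src_bits") <- if (!is.null(bps)) as.integer(bps)
                             else if (max(arr) > 255) 16L else 8L
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    bits <- if (!is.null(info) && !is.null(info$bit.depth) &&
                info$bit.depth == 16) 16L else 8L
    # png::readPNG returns [0,1]; rescale to the integer intensity range
    arr <- round(raw * (2^bits - 1))
    attr(arr, "src_bits") <- bits
  } else {
    stop("unsupported image format '", ext, "': use single-channel TIFF or PNG")
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    arr2 <- apply(arr, c(1L, 2L), mean)
    src_bits <- attr(arr, "src_bits")
    arr <- arr2
    attr(arr, "src_bits") <- src_bits
  }
  bit_depth <- if (!is.null(attr(arr, "src_bits"))) attr(arr, "src_bits")
               else if (max(arr) > 255) 16L else 8L
  px <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  calibrated_image(px, um_per_px, source_id = basename(path),
                   group_label = group_label, bit_depth = bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calibrated image to TIFF or PNG
#'
#' Inverse of \code{\link{read_image}} for single-channel images: the pixel
#' grid round-trips exactly at the declared bit depth.
#'
#' @param image a \code{\link{calibrated_image}}.
#' @param path output path ending in \code{.tif}, \code{.tiff} or \code{.png}.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  maxval <- 2^image$bit_depth - 1
  norm <- image$pixels / maxval
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(norm, path, bits.per.sample = image$bit_depth)
    } else if (ext == "png") {
      png::writePNG(norm, path)
    } else stop("unsupported output format '", ext, "'")
    TRUE
  }, error = function(e) stop("cannot write image to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

# -- result tables -----------------------------------------------------------

#' Write a result table to CSV
#'
#' The table (one row per analyzed field, see
#' \code{\link{compute_field_result}}) is written with a header row. Reals are
#' printed with 15 significant digits so a round-trip through
#' \code{\link{read_results}} reproduces them to at least 12 significant
#' digits; text columns round-trip exactly.
#'
#' @param table a data frame of field results.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty data frame")
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, scientific = FALSE, trim = TRUE))
  })
  tryCatch(write.csv(tab, path, row.names = FALSE, quote = TRUE),
           error = function(e) stop("cannot write results to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a result table written by \code{write_results}
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# -- key=value config --------------------------------------------------------

#' Read a key=value configuration file
#'
#' Minimal INI-style configuration: one \code{key = value} pair per line,
#' \code{#} starts a comment, blank lines ignored. Values that parse as
#' numbers become numeric; comma-separated numeric lists become numeric
#' vectors. Recognized keys include \code{um_per_px}, \code{threshold_method},
#' \code{fixed_threshold}, \code{polarity}, \code{min_area_um2},
#' \code{bin_edges}, \code{alpha}.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  out
}
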
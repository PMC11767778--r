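#' Per-field aggregation indices
#'
#' Computes the Aggregation-Area Indicator for each aggregate population,
#' \deqn{AAI_i = S_i / S_V,}{AAI_i = S_i / S_V,}
#' where \eqn{S_i} is the summed pixel area of population-\eqn{i} aggregates
#' (i = 1..5) and \eqn{S_V} the total pixel area of the visual field, together
#' with the aggregate counts \eqn{NA_1..NA_5} and the analogous area ratio and
#' count for population P0 (unaggregated single cells). AAI is a pixel-area
#' ratio and therefore unit-free; population membership is decided on
#' physical areas (um^2) upstream.
#'
#' @param records gated, classified particle records
#'   (\code{\link{classify_records}}).
#' @param image the \code{\link{calibrated_image}} the records derive from.
#' @return one-row data frame (a field result) with columns
#'   \code{source_id}, \code{group_label}, \code{SV_px},
#'   \code{AAI_1..AAI_5}, \code{NA_1..NA_5}, \code{p0_area_ratio},
#'   \code{n_p0}.
#' @export
compute_field_result <- function(records, image) {
  stopifnot(inherits(image, "calibrated_image"))
  sv <- nrow(image$pixels) * ncol(image$pixels)
  labels <- paste0("P", 0:5)
  area <- stats::setNames(numeric(6), labels)
  cnt <- stats::setNames(integer(6), labels)
  if (nrow(records)) {
    if (anyNA(records$population))
      stop("records must be classified before computing field results")
    a <- tapply(records$area_px, factor(records$population, levels = labels),
                sum, default = 0)
    n <- table(factor(records$population, levels = labels))
    area[] <- as.numeric(a)
    cnt[] <- as.integer(n)
  }
  out <- data.frame(source_id = image$source_id,
                    group_label = image$group_label,
                    SV_px = as.integer(sv),
                    stringsAsFactors = FALSE)
  for (i in 1:5) out[[paste0("AAI_", i)]] <- area[[paste0("P", i)]] / sv
  for (i in 1:5) out[[paste0("NA_", i)]] <- cnt[[paste0("P", i)]]
  out$p0_area_ratio <- area[["P0"]] / sv
  out$n_p0 <- cnt[["P0"]]
  out
}

#' Summarize field results within a study group
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of every
#' index across the fields of one group. With a single field the SD is
#' reported as 0 by convention, with a warning.
#'
#' @param results data frame of field results (rows from
#'   \code{\link{compute_field_result}}, possibly several groups).
#' @param group_label group to summarize.
#' @return data frame with columns \code{group_label}, \code{index},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
summarize_group <- function(results, group_label) {
  sel <- results[results$group_label == group_label, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no results with group_label '", group_label, "'")
  idx <- index_columns(results)
  n <- nrow(sel)
  if (n == 1L) warning("single field in group '", group_label,
                       "': SD reported as 0")
  data.frame(
    group_label = group_label,
    index = idx,
    mean = vapply(idx, function(k) mean(sel[[k]]), numeric(1)),
    sd = vapply(idx, function(k) if (n > 1L) stats::sd(sel[[k]]) else 0,
                numeric(1)),
    n = n,
    row.names = NULL,
    stringsAsFactors = FALSE)
}

index_columns <- function(results) {
  std <- c(paste0("AAI_", 1:5), paste0("NA_", 1:5), "p0_area_ratio", "n_p0")
  intersect(std, names(results))
}
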
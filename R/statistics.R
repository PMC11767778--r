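#' Shapiro-Wilk normality screen
#'
#' Thin validated wrapper around the Shapiro-Wilk test used to screen index
#' distributions before the non-parametric group comparison.
#'
#' @param values numeric vector, 3 <= n <= 5000, not all identical.
#' @return list with elements \code{W} and \code{p_value}.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got n = ", length(values), ")")
  if (diff(range(values)) == 0)
    stop("Shapiro-Wilk is undefined for constant samples")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Wilcoxon rank-sum test for two independent groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test. The reported statistic is
#' the rank sum of the smaller group (ties in size resolved toward group a).
#' Exact p-values come from the full null distribution of the rank sum over
#' all \eqn{\binom{n_a+n_b}{n_a}} group assignments, computed by a subset-sum
#' recursion on doubled midranks so tied data are handled exactly. The normal
#' approximation applies the standard tie variance correction and a 0.5
#' continuity correction. Mode \code{"auto"} uses the exact distribution when
#' \eqn{n_a + n_b \le 20} and the data are tie-free, otherwise the
#' approximation.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @param alpha significance level (default 0.05).
#' @param index_name,group_a,group_b labels carried into the report.
#' @return one-row data frame (a test report): \code{index_name},
#'   \code{group_a}, \code{group_b}, \code{statistic}, \code{p_value},
#'   \code{significant} (\code{p_value <= alpha}), \code{alpha},
#'   \code{method}.
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                          alpha = 0.05, index_name = "",
                          group_a = "a", group_b = "b") {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks
  has_ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto")
    mode <- if (N <= 20L && !has_ties) "exact" else "normal_approx"

  # statistic: rank sum of the smaller group (group a on size ties)
  if (na <= nb) { m <- na; t_obs <- sum(rk[seq_len(na)]) }
  else          { m <- nb; t_obs <- sum(rk[na + seq_len(nb)]) }

  p <- if (mode == "exact") {
    ranksum_exact_p(rk, m, t_obs)
  } else {
    ranksum_normal_p(rk, m, t_obs, N)
  }
  data.frame(index_name = index_name, group_a = group_a, group_b = group_b,
             statistic = t_obs, p_value = p, significant = p <= alpha,
             alpha = alpha,
             method = paste0("wilcoxon_rank_sum_", mode),
             stringsAsFactors = FALSE)
}

# Exact two-sided p for the rank sum of a group of size m drawn from the
# pooled midranks rk. Doubled midranks are integers, so the number of
# size-k subsets attaining each doubled sum is built by the classic
# subset-sum recursion; p = P(|T - E[T]| >= |t - E[T]|).
ranksum_exact_p <- function(rk, m, t_obs) {
  r2 <- as.integer(round(2 * rk))
  S <- sum(r2)
  # counts[k + 1, s + 1] = number of size-k subsets with doubled sum s
  counts <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- min(m, nrow(counts) - 1L)
    for (k in kmax:1) {
      shifted <- c(rep(0, v), counts[k, seq_len(S + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[m + 1L, ]
  total <- sum(dist)
  sums <- (seq_along(dist) - 1L)          # doubled rank sums
  e <- sum(r2) * m / length(r2)           # E[2T]
  dev <- abs(sums - e)
  obs_dev <- abs(2 * t_obs - e)
  sum(dist[dev >= obs_dev - 1e-9]) / total
}

# Normal approximation with tie correction and continuity correction.
ranksum_normal_p <- function(rk, m, t_obs, N) {
  e <- m * (N + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- m * (N - m) / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (t_obs - e)
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(v)   # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Compare study groups index by index
#'
#' Runs a Wilcoxon rank-sum test for every aggregation index and every
#' requested group pair. When \code{pairs} is omitted the study's comparison
#' scheme is used: every other group against \code{"control"}, and every
#' treated group against \code{"untreated"} (for whichever of those labels
#' are present).
#'
#' @param results data frame of field results with a \code{group_label}
#'   column.
#' @param pairs list of 2-element character vectors, or \code{NULL} for the
#'   default scheme.
#' @param alpha significance level (default 0.05; differences are declared at
#'   \eqn{p \le \alpha}).
#' @param mode passed to \code{\link{rank_sum_test}}.
#' @return data frame of test reports, one row per (index, pair).
#' @export
compare_groups <- function(results, pairs = NULL, alpha = 0.05,
                           mode = "auto") {
  groups <- unique(results$group_label)
  if (is.null(pairs)) {
    pairs <- list()
    if ("control" %in% groups)
      for (g in setdiff(groups, "control"))
        pairs[[length(pairs) + 1L]] <- c(g, "control")
    if ("untreated" %in% groups)
      for (g in setdiff(groups, c("control", "untreated")))
        pairs[[length(pairs) + 1L]] <- c(g, "untreated")
    if (!length(pairs))
      stop("no default comparison pairs: supply 'pairs' explicitly")
  }
  idx <- index_columns(results)
  out <- list()
  for (pr in pairs) {
    if (!all(pr %in% groups))
      stop("unknown group label(s): ", paste(setdiff(pr, groups),
                                             collapse = ", "))
    ra <- results[results$group_label == pr[1L], , drop = FALSE]
    rb <- results[results$group_label == pr[2L], , drop = FALSE]
    for (k in idx) {
      out[[length(out) + 1L]] <- rank_sum_test(
        ra[[k]], rb[[k]], mode = mode, alpha = alpha,
        index_name = k, group_a = pr[1L], group_b = pr[2L])
    }
  }
  do.call(rbind, out)
}
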
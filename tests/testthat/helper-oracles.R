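# Independent oracles used across the suite. These deliberately use different
# algorithms from the package implementation.

# Connected components by iterative minimum-label propagation to a fixed
# point (each foreground pixel repeatedly takes the smallest positive label
# among itself and its neighbours).
prop_label_oracle <- function(m, conn) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(seq_along(m), H, W)
  lab[m == 0] <- 0L
  shift <- function(x, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (conn == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    new <- lab
    for (o in offs) {
      s <- shift(lab, o[1], o[2])
      w <- m != 0 & s > 0 & (s < new | new == 0)
      new[w] <- s[w]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Do two labelings induce the same partition of the foreground?
partitions_equal <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fa <- a[a > 0]; fb <- b[b > 0]
  identical(as.integer(factor(fa, levels = unique(fa))),
            as.integer(factor(fb, levels = unique(fb))))
}

# Exact two-sided rank-sum p by literal enumeration of all group assignments
# (midranks), independent of the package's subset-sum recursion.
brute_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  rk <- rank(c(a, b))
  m <- min(na, nb)
  t_obs <- if (na <= nb) sum(rk[seq_len(na)]) else sum(rk[na + seq_len(nb)])
  e <- m * sum(rk) / N
  sets <- utils::combn(N, m)
  sums <- apply(sets, 2L, function(ix) sum(rk[ix]))
  mean(abs(sums - e) >= abs(t_obs - e) - 1e-9)
}

# A mixed-content synthetic field specification used by end-to-end checks:
# sub-gate singles, P0 doublets, P1/P2 chains, plus clusters spanning P3-P5
# when the field is large enough to hold them.
mixed_field_spec <- function(seed, noise_sd = 0,
                             field_shape = c(300L, 1600L), um_per_px = 0.5) {
  small <- min(field_shape * um_per_px) < 120
  # cluster targets sit well inside their bins so rasterization and boundary
  # erosion cannot flip a population
  clusters <- if (small) {
    c(c(450, 550, 900)[(seed %% 3) + 1])
  } else {
    c(700, c(900, 2000, 3500)[(seed %% 3) + 1])
  }
  rouleaux <- if (small) {
    list(c(2, 0.3), c(2, 2.1), c(5, 1.0), c(10, 0.7))
  } else {
    list(c(2, 0.3), c(2, 2.1), c(5, 1.0), c(5, 2.6), c(12, 0.7), c(16, 1.9))
  }
  synthetic_spec(field_shape = field_shape, um_per_px = um_per_px,
                 n_singles = 3L, rouleaux = rouleaux, clusters = clusters,
                 noise_sd = noise_sd, seed = seed)
}

# Run the fixed-threshold pipeline used by the ground-truth comparisons.
analyze_noise_free <- function(image) {
  analyze_image(image, method = "fixed", fixed_threshold = 130,
                polarity = "dark_foreground")
}

na_vector <- function(result) {
  as.integer(c(result$n_p0, result$NA_1, result$NA_2, result$NA_3,
               result$NA_4, result$NA_5))
}

# Minimal particle-record table for unit tests that bypass the image stages.
# area_px is taken at um_per_px = 1 so area_um2 == area_px.
stub_records <- function(areas, population = NA_character_) {
  n <- length(areas)
  data.frame(label_id = seq_len(n), area_px = as.integer(round(areas)),
             area_um2 = as.numeric(areas),
             centroid_row = rep(0, n), centroid_col = rep(0, n),
             bbox_min_row = rep(0L, n), bbox_min_col = rep(0L, n),
             bbox_max_row = rep(1L, n), bbox_max_col = rep(1L, n),
             population = rep_len(population, n),
             stringsAsFactors = FALSE)
}

area_px_vector <- function(result) {
  c(result$p0_area_ratio, result$AAI_1, result$AAI_2, result$AAI_3,
    result$AAI_4, result$AAI_5) * result$SV_px
}
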
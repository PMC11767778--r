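test_that("an empty spec yields a blank noisy field with empty truth", {
  spec <- synthetic_spec(field_shape = c(64, 128), noise_sd = 5, seed = 9)
  gf <- generate_field(spec)
  expect_identical(dim(gf$image$pixels), c(64L, 128L))
  expect_identical(nrow(gf$truth$objects), 0L)
  expect_true(all(gf$truth$totals$n == 0))
  expect_gt(sd(gf$image$pixels), 0)   # noise present
})

test_that("a single cell disc rasterizes to its analytic area, below gate", {
  spec <- synthetic_spec(field_shape = c(64, 64), um_per_px = 0.5,
                         n_singles = 1L, seed = 10)
  gf <- generate_field(spec)
  obj <- gf$truth$objects
  expect_identical(nrow(obj), 1L)
  analytic <- pi * 3.9^2                      # ~47.8 um^2
  expect_lt(abs(obj$true_area_um2 - analytic) / analytic, 0.05)
  # a resting single cell sits below the 50 um^2 detection gate
  expect_false(obj$detectable)
  expect_identical(obj$true_area_px * 0.25, obj$true_area_um2)
})

test_that("generation is bit-for-bit deterministic given the seed", {
  spec <- mixed_field_spec(3, noise_sd = 6, field_shape = c(150L, 400L))
  g1 <- generate_field(spec)
  g2 <- generate_field(spec)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$objects, g2$truth$objects)
  # a different seed moves the objects
  g3 <- generate_field(mixed_field_spec(4, noise_sd = 6,
                                        field_shape = c(150L, 400L)))
  expect_false(identical(g1$image$pixels, g3$image$pixels))
})

test_that("rouleau pixel sets match the closed-form disc-union area", {
  # two discs of radius r with centers d = r apart: union = 2A - lens
  r <- 3.9; d <- 3.9
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  union_analytic <- 2 * pi * r^2 - lens
  px <- render_rouleau(2, orientation = 0.4, um_per_px = 0.25)
  realized <- nrow(px) * 0.0625
  expect_lt(abs(realized - union_analytic) / union_analytic, 0.03)
  expect_error(render_rouleau(1, 0), "2 cells")
})

test_that("rouleau area grows affinely with the cell count", {
  # fine rasterization so boundary-pixel jitter stays below the tolerance
  areas <- vapply(2:9, function(n)
    nrow(render_rouleau(n, orientation = 0.9, um_per_px = 0.125)) * 0.125^2,
    numeric(1))
  inc <- diff(areas)
  expect_true(all(abs(inc - mean(inc)) / mean(inc) < 0.02))
})

test_that("cluster blobs are seeded, connected, and near their target area", {
  set.seed(12)
  px <- render_cluster(2000, um_per_px = 0.5)
  area <- nrow(px) * 0.25
  expect_gte(area, 1800); expect_lte(area, 2200)
  # connectivity: one 8-connected component
  m <- matrix(0L, max(px[, "row"]) + 1L, max(px[, "col"]) + 1L)
  m[px + 1L] <- 1L
  expect_identical(attr(label_components(m, 8L), "n_labels"), 1L)
  # same seed, same blob
  set.seed(12)
  expect_identical(render_cluster(2000, um_per_px = 0.5), px)
  # a 3000 um^2 blob is a P5 aggregate network under the default binning
  set.seed(13)
  a3 <- nrow(render_cluster(3000, um_per_px = 0.5)) * 0.25
  expect_identical(assign_population(a3), "P5")
  expect_error(render_cluster(50), ">= 100")
})

test_that("objects stay separated: labeling recovers one region per object", {
  for (seed in 1:3) {
    gf <- generate_field(mixed_field_spec(seed, field_shape = c(200L, 600L)))
    mask <- binarize(gf$image, method = "fixed", fixed_threshold = 130,
                     polarity = "dark_foreground")
    lab <- label_components(mask, 8L)
    expect_identical(attr(lab, "n_labels"), nrow(gf$truth$objects))
  }
})

test_that("infeasible packings fail with an informative error", {
  spec <- synthetic_spec(field_shape = c(40, 40), um_per_px = 0.5,
                         clusters = c(3000), seed = 1)
  expect_error(generate_field(spec), "cannot fit|too crowded")
})

test_that("the pipeline recovers truth counts under moderate noise", {
  # SNR = (190 - 70) / 24 = 5
  hits <- 0L
  for (seed in 1:15) {
    gf <- generate_field(mixed_field_spec(seed, noise_sd = 24,
                                          field_shape = c(200L, 600L)))
    res <- analyze_noise_free(gf$image)
    hits <- hits + identical(na_vector(res$result), gf$truth$totals$n)
  }
  expect_gte(hits / 15, 0.95)
})
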
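test_that("auto thresholds isolate the dark minority class exactly", {
  set.seed(21)
  px <- matrix(200, 40, 40)
  px[sample(1600, 160)] <- 40      # 10% dark aggregate pixels
  img <- calibrated_image(px, 1)
  for (m in c("otsu", "isodata")) {
    mask <- binarize(img, method = m, polarity = "dark_foreground")
    expect_identical(which(unclass(mask) == 1L), which(px == 40))
    thr <- attr(mask, "threshold")
    expect_gt(thr, 40); expect_lt(thr, 200)
  }
  # fixed method requires a threshold
  expect_error(binarize(img, method = "fixed"), "fixed_threshold")
  mask <- binarize(img, method = "fixed", fixed_threshold = 120,
                   polarity = "dark_foreground")
  expect_identical(which(unclass(mask) == 1L), which(px == 40))
})

test_that("constant images give an empty mask with a warning, not an error", {
  img <- calibrated_image(matrix(77, 10, 10), 1)
  expect_warning(mask <- binarize(img), "constant")
  expect_true(all(unclass(mask) == 0L))
})

test_that("auto polarity picks the minority class, invariant to inversion", {
  set.seed(22)
  for (i in 1:25) {
    lv <- sort(sample(0:255, 2))
    frac <- runif(1, 0.05, 0.45)
    px <- matrix(ifelse(runif(900) < frac, lv[1], lv[2]), 30, 30)
    m1 <- binarize(calibrated_image(px, 1), polarity = "auto")
    m2 <- binarize(calibrated_image(255 - px, 1), polarity = "auto")
    expect_identical(unclass(m1) != 0L, unclass(m2) != 0L)
    # the minority class is the foreground
    expect_lte(sum(unclass(m1)), 450)
  }
})

test_that("refine fills holes, removes salt noise, leaves solids unchanged", {
  # solid disc with a 2-pixel interior hole (non-integer radius, so the
  # rasterization has no single-pixel caps for the opening to shave)
  m <- matrix(0L, 21, 21)
  d <- outer(-10:10, -10:10, function(r, c) r^2 + c^2 <= 60)
  m[d] <- 1L
  holed <- m; holed[11, 11] <- 0L; holed[11, 12] <- 0L
  r <- refine(holed)
  expect_identical(matrix(as.integer(unclass(r)), 21, 21), m)

  # isolated single pixel is removed
  salt <- matrix(0L, 9, 9); salt[5, 5] <- 1L
  expect_true(all(unclass(refine(salt)) == 0L))

  # solid rectangle is unchanged
  rect <- matrix(0L, 12, 12); rect[3:9, 4:10] <- 1L
  expect_identical(matrix(as.integer(unclass(refine(rect))), 12, 12), rect)
})

test_that("refine is idempotent on random masks", {
  set.seed(23)
  for (i in 1:40) {
    m <- matrix(as.integer(runif(1024) < runif(1, 0.2, 0.7)), 32, 32)
    r1 <- refine(m)
    r2 <- refine(r1)
    expect_identical(unclass(r1) != 0L, unclass(r2) != 0L)
  }
})

test_that("labeling honors connectivity and raster-scan label order", {
  m <- matrix(0L, 20, 20)
  m[3:6, 3:6] <- 1L
  m[12:15, 10:13] <- 1L
  lab <- label_components(m)
  expect_identical(attr(lab, "n_labels"), 2L)
  # raster order: the region whose first pixel comes first gets label 1
  expect_identical(as.integer(lab[3, 3]), 1L)
  expect_identical(as.integer(lab[12, 10]), 2L)

  # two blocks touching at one diagonal pixel pair
  dg <- matrix(0L, 8, 8)
  dg[2:3, 2:3] <- 1L
  dg[4:5, 4:5] <- 1L
  expect_identical(attr(label_components(dg, 8), "n_labels"), 1L)
  expect_identical(attr(label_components(dg, 4), "n_labels"), 2L)

  empty <- matrix(0L, 5, 5)
  expect_identical(attr(label_components(empty), "n_labels"), 0L)
  expect_error(label_components(m, connectivity = 6), "4 or 8")
})

test_that("labeling matches independent oracles and conserves pixel counts", {
  set.seed(24)
  for (i in 1:60) {
    m <- matrix(as.integer(runif(1024) < runif(1, 0.3, 0.6)), 32, 32)
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)
      expect_true(partitions_equal(lab, prop_label_oracle(m, conn)))
      # foreground pixel count is conserved across the labeled regions
      n <- attr(lab, "n_labels")
      expect_identical(sum(tabulate(lab[lab > 0], nbins = n)), sum(m))
    }
    # EBImage's bwlabel is 4-connected: independent cross-check
    expect_true(partitions_equal(label_components(m, 4L),
                                 EBImage::bwlabel(m)))
  }
})
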
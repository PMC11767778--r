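field_img <- function(h = 300, w = 1600, s = 0.5, group = "control",
                      id = "f") {
  calibrated_image(matrix(0, h, w), s, source_id = id, group_label = group)
}

test_that("field results implement AAI = S_i / S_V and the counts", {
  img <- field_img()
  # empty field: all indices zero
  r0 <- compute_field_result(stub_records(numeric(0)), img)
  expect_identical(r0$SV_px, 480000L)
  expect_true(all(unlist(r0[paste0("AAI_", 1:5)]) == 0))
  expect_true(all(unlist(r0[paste0("NA_", 1:5)]) == 0L))
  expect_identical(r0$p0_area_ratio, 0)

  # one P3 aggregate of 4800 px in the 1600 x 300 field
  rec <- stub_records(4800, population = "P3")
  r1 <- compute_field_result(rec, img)
  expect_equal(r1$AAI_3, 0.01)
  expect_identical(r1$NA_3, 1L)
  expect_equal(r1$AAI_1 + r1$AAI_2 + r1$AAI_4 + r1$AAI_5, 0)

  expect_error(compute_field_result(stub_records(100), img), "classified")
})

test_that("field-result invariants hold on random record sets", {
  set.seed(41)
  img <- field_img(1000, 1000, 1)   # large enough for any drawn record set
  for (i in 1:50) {
    n <- sample(0:30, 1)
    areas <- exp(runif(n, log(50), log(4000)))
    rec <- stub_records(areas, population = assign_population(areas))
    r <- compute_field_result(rec, img)
    aai <- unlist(r[paste0("AAI_", 1:5)])
    na <- unlist(r[paste0("NA_", 1:5)])
    expect_true(all(aai >= 0 & aai <= 1))
    expect_lte(sum(aai) + r$p0_area_ratio, 1)
    expect_identical(unname(na == 0L), unname(aai == 0))   # NA_i = 0 <=> AAI_i = 0
    # counts partition the record set
    expect_identical(sum(na) + r$n_p0, nrow(rec))
  }
})

test_that("AAI is additive over fields and responds to single aggregates", {
  set.seed(42)
  img <- field_img(150, 400, 1)
  a1 <- exp(runif(8, log(60), log(3000)))
  a2 <- exp(runif(5, log(60), log(3000)))
  r1 <- compute_field_result(stub_records(a1, assign_population(a1)), img)
  r2 <- compute_field_result(stub_records(a2, assign_population(a2)), img)
  merged <- stub_records(c(a1, a2), assign_population(c(a1, a2)))
  # the two fields side by side form one field of twice the area
  rm <- compute_field_result(merged, field_img(150, 800, 1))
  for (k in paste0("AAI_", 1:5))
    expect_equal(rm[[k]], (r1[[k]] + r2[[k]]) / 2)
  # adding one aggregate of area a bumps exactly one AAI by a/SV, one NA by 1
  a <- 800
  plus <- stub_records(c(a1, a), assign_population(c(a1, a)))
  rp <- compute_field_result(plus, img)
  sv <- r1$SV_px
  daai <- unlist(rp[paste0("AAI_", 1:5)]) - unlist(r1[paste0("AAI_", 1:5)])
  dna <- unlist(rp[paste0("NA_", 1:5)]) - unlist(r1[paste0("NA_", 1:5)])
  expect_equal(sum(daai != 0), 1L)
  expect_equal(unname(daai[["AAI_3"]]), a / sv)
  expect_identical(unname(dna[["NA_3"]]), 1L)
})

test_that("group summaries use the sample SD and handle degenerate groups", {
  img <- field_img()
  rec <- stub_records(c(4800, 120), population = c("P3", "P1"))
  r <- compute_field_result(rec, img)
  both <- rbind(r, r)
  s <- summarize_group(both, "control")
  expect_true(all(s$sd == 0))                       # identical duplicates
  expect_equal(s$mean[s$index == "AAI_3"], 0.01)
  expect_identical(unique(s$n), 2L)

  # hand computation with the n-1 denominator
  r2 <- r; r2$AAI_3 <- 0.02; r$AAI_3 <- 0.04
  s2 <- summarize_group(rbind(r, r2), "control")
  expect_equal(s2$mean[s2$index == "AAI_3"], 0.03)
  expect_equal(s2$sd[s2$index == "AAI_3"], 0.0141421356, tolerance = 1e-8)

  expect_warning(s1 <- summarize_group(r, "control"), "SD")
  expect_true(all(s1$sd == 0))
  expect_error(summarize_group(r, "nosuch"), "nosuch")
})
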
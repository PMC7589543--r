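# 22-state classification, PAS mapping, barcode symbolization, summaries,
# and the stripe rendering.

test_that("segment classification reproduces the published state table", {
  expect_equal(classify_segment("walking", 400, cadence = 60), 19L)
  expect_equal(classify_segment("walking", 150, cadence = 90), 16L)
  expect_equal(classify_segment("lying_sitting", 500, intensity = 0.01), 1L)
  expect_equal(classify_segment("lying_sitting", 500, intensity = 0.08), 2L)
  expect_equal(classify_segment("standing", 50, intensity = 0.01), 3L)
  expect_equal(classify_segment("standing", 50, intensity = 0.5), 6L)
  expect_equal(classify_segment("walking", 30, cadence = 140), 10L)
  expect_error(classify_segment("walking", 30), "cadence")
  expect_error(classify_segment("standing", 30), "intensity")
  expect_error(classify_segment("flying", 30, intensity = 0.1), "unknown mode")
  expect_error(classify_segment("walking", -5, cadence = 100), "positive")
})

test_that("the mode x duration x intensity sweep hits all 22 states exactly once", {
  p <- barcode_params()
  states <- c(
    classify_segment("lying_sitting", 100, intensity = c(0.01, 0.08), params = p),
    classify_segment("standing", 100, intensity = c(0.01, 0.06, 0.15, 0.3), params = p),
    as.vector(vapply(c(30, 90, 200, 500), function(d)
      classify_segment("walking", d, cadence = c(50, 85, 115, 150), params = p),
      numeric(4))))
  expect_equal(sort(states), 1:22)
  # bin edges leave no gaps: boundary values classify into the upper bin
  expect_equal(classify_segment("walking", 60, cadence = 70), 12L)
  expect_equal(classify_segment("walking", 120, cadence = 100), 17L)
  expect_equal(classify_segment("walking", 360, cadence = 130), 22L)
})

test_that("PAS mapping collapses intensity and partitions the alphabet 2+4x5", {
  expect_equal(map_pas(19L), 6L)
  expect_equal(map_pas(2L), 1L)
  expect_equal(map_pas(16L), 5L)
  sizes <- table(map_pas(1:22))
  expect_equal(unname(c(sizes)), c(2L, 4L, 4L, 4L, 4L, 4L))
  expect_error(map_pas(0), "1..22")
  expect_error(map_pas(23), "1..22")
  # non-walking segments can never reach PAS >= 3
  for (int in c(0.01, 0.08, 0.25, 0.5)) {
    expect_lte(map_pas(classify_segment("lying_sitting", 100, intensity = int)), 1)
    expect_lte(map_pas(classify_segment("standing", 100, intensity = int)), 2)
  }
})

test_that("barcode symbolization writes one state per epoch with majority overlap", {
  tl <- mk_timeline("standing", 100, body = 0.01)
  b <- to_barcode(tl)
  expect_length(b, 100)
  expect_true(all(unclass(b) == 3))

  tl2 <- mk_timeline(c("lying_sitting", "walking", "lying_sitting"),
                     c(1000, 400, 600), cadence = c(NA, 60, NA),
                     body = c(0.01, NA, 0.01))
  b2 <- to_barcode(tl2)
  expect_equal(sort(unique(unclass(b2))), c(1L, 19L))
  expect_equal(sum(unclass(b2) == 19), 400)
  expect_equal(length(b2) * attr(b2, "epoch"), attr(tl2, "day_length"))

  # fractional boundary: the majority owner takes the split epoch
  tl3 <- mk_timeline(c("standing", "lying_sitting"), c(10.4, 9.6),
                     body = c(0.01, 0.01))
  b3 <- to_barcode(tl3)
  expect_equal(sum(unclass(b3) == 3), 10)  # epoch 11 is 40/60 lying
})

test_that("summaries normalize to 100% and flag achievers from exact counts", {
  b <- structure(rep(1L, 50), epoch = 1, subject_id = "A", class = "pab_barcode")
  s <- pa_summary(b)
  expect_equal(s$pas_fractions[1], 100)
  expect_equal(s$achiever, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(s$pct_activity, 0)

  b2 <- structure(c(rep(1L, 30), rep(8L, 30)), epoch = 1, subject_id = "B",
                  class = "pab_barcode")
  s2 <- pa_summary(b2)
  expect_equal(s2$pas_fractions[c(1, 3)], c(50, 50))
  expect_equal(s2$pas_3_6, 50)
  expect_equal(s2$pct_activity, 50)
  expect_equal(sum(s2$state_fractions), 100)
  expect_equal(sum(s2$pas_fractions), 100)
  expect_error(pa_summary(structure(integer(), class = "pab_barcode")), "empty")
})

test_that("summaries are stable under epoch refinement", {
  tl <- mk_timeline(c("lying_sitting", "walking", "standing", "walking"),
                    c(497.3, 95.7, 203.4, 403.6),
                    cadence = c(NA, 95, NA, 68), body = c(0.01, NA, 0.05, NA))
  s1 <- pa_summary(to_barcode(tl, barcode_params(epoch = 1)))
  s2 <- pa_summary(to_barcode(tl, barcode_params(epoch = 0.5)))
  expect_lt(max(abs(s1$pas_fractions - s2$pas_fractions)),
            100 * 1 / sum(tl$end - tl$start) + 1e-9)
})

test_that("time lands in PAS 6 exactly when a very long walking bout exists", {
  set.seed(404)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    modes <- sample(c("lying_sitting", "standing", "walking"), k, replace = TRUE)
    durs <- runif(k, 30, 500)
    cad <- ifelse(modes == "walking", runif(k, 50, 150), NA)
    tl <- mk_timeline(modes, durs, cadence = cad)
    s <- pa_summary(to_barcode(tl))
    has_vl <- any(modes == "walking" & durs > 360)
    expect_equal(s$pas_fractions[6] > 0, has_vl)
  }
})

test_that("barcode stripe rendering writes an image with a 22-color palette", {
  pal <- barcode_palette()
  expect_length(pal, 22)
  expect_equal(anyDuplicated(pal), 0)
  b <- to_barcode(mk_timeline(c("standing", "walking"), c(300, 100),
                              cadence = c(NA, 100)))
  f <- tempfile(fileext = ".png")
  render_barcode_image(b, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("barcodes round-trip through the text format", {
  b <- to_barcode(mk_timeline(c("standing", "walking"), c(120, 80),
                              cadence = c(NA, 110)))
  f <- tempfile(fileext = ".txt")
  write_barcodes(list(b), f)
  back <- read_barcodes(f)[[1]]
  expect_equal(unclass(back), unclass(b), ignore_attr = TRUE)
  expect_equal(attr(back, "epoch"), attr(b, "epoch"))
})
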
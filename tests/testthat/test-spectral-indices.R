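test_that("index formulas give the textbook values", {
  sc <- make_scene(B7 = 0.4, B5 = 0.2, B8 = 0.3, B11 = 0.3, B8A = 0.3)
  expect_equal(compute_index(sc, "CIre")[1, 1], 1.0)
  expect_equal(compute_index(sc, "NDWI")[1, 1], 0.0)
  sc2 <- make_scene(B8A = 0.3, B11 = 0.1)
  expect_equal(compute_index(sc2, "NDII")[1, 1], 0.5)
  sc3 <- make_scene(B3 = 0.3, B4 = 0.1)
  expect_equal(compute_index(sc3, "CCI")[1, 1], 0.5)
})

test_that("indices guard denominators and reject unknown names", {
  b <- matrix(0.2, 3, 3)
  z <- matrix(0, 3, 3)
  zn <- matrix(0.2, 3, 3); zn[1, 1] <- NA
  sc <- rs_scene(list(B2 = b, B3 = b, B4 = b, B5 = z, B6 = b, B7 = b, B8 = zn,
                      B8A = b, B11 = b, B12 = b))
  expect_true(all(is.na(compute_index(sc, "CIre"))))   # zero denominator
  expect_true(is.na(compute_index(sc, "NDWI")[1, 1]))  # nodata propagates
  expect_false(anyNA(compute_index(sc, "NDWI")[-1]))
  expect_error(compute_index(sc, "EVI"), "unknown index")
  expect_error(compute_index(rs_scene(list(B2 = b)), "NDVI"), "missing band")
})

test_that("normalized-difference indices stay within [-1, 1] on random scenes", {
  set.seed(101)
  for (rep in 1:20) {
    bands <- setNames(lapply(1:10, function(k) matrix(runif(64, 0.01, 1), 8)),
                      c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
                        "B11", "B12"))
    sc <- rs_scene(bands)
    for (ix in c("CCI", "NDII", "NDWI", "NDVI")) {
      v <- compute_index(sc, ix)
      expect_true(all(abs(v[is.finite(v)]) <= 1))
    }
  }
})

test_that("rescale01 maps tails to the endpoints and is monotone inside", {
  v <- matrix(seq(0, 1, length.out = 1001), ncol = 1)
  r <- rescale01(v, clip_pct = 0.1)
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)
  expect_lt(abs(r[501] - 0.5), 1e-3)     # midpoint preserved
  set.seed(7)
  x <- rnorm(500)
  rx <- rescale01(x, clip_pct = 0.1)
  inner <- rx > 0 & rx < 1
  expect_equal(cor(rank(x[inner]), rank(rx[inner])), 1)
})

test_that("rescale01 handles degenerate inputs", {
  expect_equal(unique(as.vector(rescale01(matrix(0.3, 5, 5)))), 0.5)
  m <- matrix(NA_real_, 3, 3)
  expect_error(rescale01(m), "no valid values")
  m[1, 1] <- 2
  expect_equal(rescale01(m)[1, 1], 0.5)   # single value = constant raster
  expect_true(is.na(rescale01(m)[2, 2]))
})

test_that("compute_index then rescale01 preserves ranking of interior pixels", {
  set.seed(11)
  bands <- setNames(lapply(1:10, function(k) matrix(runif(400, 0.05, 0.9), 20)),
                    c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
                      "B11", "B12"))
  v <- compute_index(rs_scene(bands), "NDWI")
  r <- rescale01(v, 0.1)
  inner <- which(r > 0 & r < 1)
  expect_equal(cor(rank(v[inner]), rank(r[inner])), 1)
})

test_that("mean resampling averages 2x2 blocks and keeps partial blocks", {
  x <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)   # one block
  expect_equal(resample_mean(x)[1, 1], 0.25)
  u <- matrix(0.7, 6, 4)
  expect_equal(unique(as.vector(resample_mean(u))), 0.7)
  x[2, 2] <- NA
  expect_equal(resample_mean(x)[1, 1], mean(c(0.1, 0.3, 0.2)))
  x[] <- NA
  expect_true(is.na(resample_mean(x)[1, 1]))
  expect_error(resample_mean(matrix(0, 3, 4)), "even")
})
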
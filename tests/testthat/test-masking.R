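test_that("cloud-free rule uses strict 5% blue / 15% NIR thresholds", {
  sc <- make_scene(B2 = 0.04, B8A = 0.20)
  expect_true(cloudfree_mask(sc)[1, 1])
  expect_false(cloudfree_mask(make_scene(B2 = 0.06, B8A = 0.20))[1, 1])
  expect_false(cloudfree_mask(make_scene(B2 = 0.05, B8A = 0.15))[1, 1])  # boundary
  expect_false(cloudfree_mask(make_scene(B2 = 0.04, B8A = 0.10))[1, 1])
  b <- matrix(0.02, 2, 2); b[1, 1] <- NA
  expect_false(cloudfree_mask(make_scene(B2 = b, nr = 2, nc = 2))[1, 1])
})

test_that("median-outlier thresholds follow median +/- c * MAD", {
  expect_equal(median_outlier_threshold(c(1, 2, 3, 4, 100), "lower", c = 3), 0)
  expect_equal(median_outlier_threshold(c(5, 5, 5, 5, 9), "lower", c = 3), 5)  # MAD 0
  x <- c(-3, -1, 0, 1, 3)
  lo <- median_outlier_threshold(x, "lower", c = 2)
  hi <- median_outlier_threshold(x, "upper", c = 2)
  expect_equal(lo + hi, 2 * median(x))
  expect_error(median_outlier_threshold(numeric(0)), "empty")
})

make_vote_scene <- function(cloud_px = NULL, nr = 20, nc = 20) {
  b2 <- matrix(0.02, nr, nc)
  b8a <- matrix(0.5, nr, nc)
  if (!is.null(cloud_px)) b2[cloud_px] <- 0.30
  make_scene(B2 = b2, B8A = b8a, B3 = 0.10, B4 = 0.06, B6 = 0.25, B12 = 0.15,
             nr = nr, nc = nc)
}

test_that("forest mask keeps pixels valid in two of three scenes", {
  polys <- forest_polygons(matrix(TRUE, 20, 20))
  s_all <- make_vote_scene()
  s_c1 <- make_vote_scene(cloud_px = cbind(5, 5))
  # pixel (5,5) cloudy in one scene only -> kept; cloudy in two -> dropped
  m2 <- build_forest_mask(list(s_all, s_all, s_c1), polys)
  expect_true(m2[5, 5])
  m1 <- build_forest_mask(list(s_all, s_c1, s_c1), polys)
  expect_false(m1[5, 5])
  expect_equal(sum(!m1), 1)
  # all scenes clean -> mask equals the rasterized polygons
  half <- matrix(FALSE, 20, 20); half[1:10, ] <- TRUE
  mh <- build_forest_mask(list(s_all, s_all, s_all), forest_polygons(half))
  expect_equal(unclass(mh), half, ignore_attr = TRUE)
  expect_equal(attr(mh, "count_valid"), sum(half))
})

test_that("forest mask drops NDVI and shadow outliers inside the polygons", {
  nr <- 24; nc <- 24
  b8a <- matrix(0.5, nr, nc); b8a[3, 3] <- 0.17   # low NDVI outlier (gap)
  b6 <- matrix(0.25, nr, nc); b6[4, 4] <- 0.01    # dark B6 outlier (shadow)
  b6 <- b6 + seq(0, 0.01, length.out = nr)        # spread so MAD > 0
  b8a <- b8a + matrix(seq(0, 0.01, length.out = nr * nc), nr, nc)
  sc <- make_scene(B2 = 0.02, B8A = b8a, B6 = b6, nr = nr, nc = nc)
  m <- build_forest_mask(list(sc, sc, sc), forest_polygons(matrix(TRUE, nr, nc)))
  expect_false(m[3, 3])
  expect_false(m[4, 4])
  expect_true(m[10, 10])
})

test_that("edge-patch exclusion removes small components and erodes", {
  m <- matrix(FALSE, 60, 60)
  m[10:59, 5:54] <- TRUE          # 50 x 50 block
  m[2, 2] <- TRUE; m[2, 3] <- TRUE  # isolated 2-pixel patch
  out <- exclude_edge_patches(m, min_patch_px = 28, erosion_px = 0)
  expect_false(any(out[1:3, 1:4]))
  expect_equal(sum(out), 2500)
  er <- exclude_edge_patches(m, min_patch_px = 28, erosion_px = 1)
  expect_equal(sum(er), 48 * 48)
  expect_true(all(er[11:58, 6:53]))
  expect_equal(exclude_edge_patches(m, 1, 0), m, ignore_attr = TRUE)
  expect_error(exclude_edge_patches(m, -1, 0), ">= 0")
})

test_that("each masking step only removes pixels", {
  set.seed(21)
  nr <- 32; nc <- 32
  poly_mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
  polys <- forest_polygons(poly_mask)
  scenes <- lapply(1:3, function(k) {
    b2 <- matrix(0.02, nr, nc)
    b2[sample(nr * nc, 30)] <- 0.3
    make_scene(B2 = b2, B8A = matrix(runif(nr * nc, 0.3, 0.6), nr, nc),
               nr = nr, nc = nc)
  })
  m <- build_forest_mask(scenes, polys)
  expect_true(all(poly_mask[m]))  # mask subset of polygon area
  m2 <- exclude_edge_patches(m, min_patch_px = 10, erosion_px = 1)
  expect_true(all(m[m2]))
})

test_that("pixel counts convert to the right areas", {
  expect_equal(mask_area_km2(2500, 20), 1)
  expect_equal(mask_area_km2(1, 20), 4e-4)
})
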
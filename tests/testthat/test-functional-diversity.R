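test_that("circular kernel reproduces the 60 m calculation mask", {
  k <- circular_kernel(3)
  expect_equal(round(sum(k), 1), 28.3)
  expect_equal(round(sum(k) * 20^2 / 1e4, 3), 1.131)  # hectares at 20 m
  expect_equal(k[4, 4], 1.0)                           # fully interior center
  expect_equal(unclass(k), t(unclass(k)), ignore_attr = TRUE)  # symmetry
  expect_equal(unclass(k), unclass(k)[7:1, 7:1], ignore_attr = TRUE)
  expect_error(circular_kernel(0), "positive")
})

test_that("hull-volume richness matches closed forms", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(functional_richness(cube), 1.0)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(functional_richness(tet), 1 / 6)
  set.seed(3)
  coplanar <- cbind(runif(12), runif(12), 0.4)
  expect_equal(functional_richness(coplanar), 0)
  expect_true(is.na(functional_richness(tet[1:3, ])))  # below min_points
})

test_that("functional evenness matches hand-derived values and is scale-free", {
  regular <- cbind(c(0, 0.5, 1), 0, 0)
  expect_equal(functional_evenness(regular), 1.0)
  skewed <- cbind(c(0, 0.1, 1), 0, 0)
  expect_equal(functional_evenness(skewed), 0.2)  # PEW = 0.1, 0.9
  set.seed(5)
  P <- matrix(runif(30), ncol = 3)
  f0 <- functional_evenness(P)
  expect_equal(functional_evenness(P * 7.3), f0)          # uniform scaling
  expect_equal(functional_evenness(sweep(P, 2, c(1, -2, 5), "+")), f0)
  expect_equal(functional_evenness(P[sample(nrow(P)), ]), f0)  # relabeling
  expect_true(is.na(functional_evenness(matrix(0.5, 5, 3))))   # coincident
})

test_that("richness and evenness agree with brute-force oracles", {
  set.seed(42)
  for (t in 1:200) {
    n <- sample(4:25, 1)
    P <- matrix(runif(3 * n), ncol = 3)
    expect_lt(abs(functional_richness(P) - oracle_hull_volume(P)), 1e-9)
    if (n >= 3) {
      w <- runif(n, 0.2, 1)
      expect_lt(abs(functional_evenness(P, w) - oracle_feve(P, w)), 1e-9)
    }
  }
})

test_that("convex richness grows under point addition; alpha shape never exceeds it", {
  set.seed(9)
  for (t in 1:25) {
    P <- matrix(runif(3 * 12), ncol = 3)
    v1 <- functional_richness(P)
    v2 <- functional_richness(rbind(P, matrix(runif(9), ncol = 3)))
    expect_gte(v2, v1 - 1e-12)
    a <- functional_richness(P, alpha = runif(1, 0.2, 0.8))
    expect_lte(a, v1 + 1e-12)
  }
  # huge alpha reduces to the convex hull
  P <- matrix(runif(36), ncol = 3)
  expect_equal(functional_richness(P, alpha = 1e3), functional_richness(P))
})

test_that("the MST is a spanning tree with the minimal total length", {
  set.seed(13)
  for (t in 1:20) {
    n <- sample(4:15, 1)
    P <- matrix(runif(3 * n), ncol = 3)
    mst <- trait_mst(P)
    expect_equal(nrow(mst), n - 1)
    expect_equal(sum(mst$length), sum(oracle_mst_edges(P)[, 3]))
  }
})

test_that("map-level diversity equals direct per-window computation", {
  set.seed(31)
  nr <- 12; nc <- 12
  traits <- lapply(1:3, function(k) matrix(runif(nr * nc), nr, nc))
  traits[[1]][3, 7] <- NA  # a hole
  mask <- matrix(TRUE, nr, nc)
  kernel <- circular_kernel(3)
  fd <- map_functional_diversity(traits, mask, kernel, alpha = "convex",
                                 use_kernel_weights = TRUE)
  hw <- (nrow(kernel) - 1) / 2
  for (i in seq(4, 9, by = 2)) for (j in seq(4, 9, by = 3)) {
    pts <- NULL; w <- NULL
    for (a in -hw:hw) for (b in -hw:hw) {
      kwt <- kernel[a + hw + 1, b + hw + 1]
      if (kwt <= 0) next
      v <- c(traits[[1]][i + a, j + b], traits[[2]][i + a, j + b],
             traits[[3]][i + a, j + b])
      if (anyNA(v)) next
      pts <- rbind(pts, v); w <- c(w, kwt)
    }
    expect_equal(fd$fric[i, j], functional_richness(pts))
    expect_equal(fd$feve[i, j], functional_evenness(pts, w))
    expect_equal(fd$n_points[i, j], nrow(pts))
  }
})

test_that("adaptive alpha mode equals a per-window alpha of twice the mean MST edge", {
  set.seed(33)
  nr <- 9; nc <- 9
  traits <- lapply(1:3, function(k) matrix(runif(nr * nc), nr, nc))
  kernel <- circular_kernel(2)
  fd <- map_functional_diversity(traits, matrix(TRUE, nr, nc), kernel,
                                 alpha = "adaptive", alpha_mult = 2)
  hw <- (nrow(kernel) - 1) / 2
  for (i in c(4, 5)) for (j in c(4, 6)) {
    pts <- NULL
    for (a in -hw:hw) for (b in -hw:hw) {
      if (kernel[a + hw + 1, b + hw + 1] <= 0) next
      pts <- rbind(pts, c(traits[[1]][i + a, j + b], traits[[2]][i + a, j + b],
                          traits[[3]][i + a, j + b]))
    }
    alpha <- 2 * mean(trait_mst(pts)$length)
    expect_equal(fd$fric[i, j], functional_richness(pts, alpha = alpha))
  }
})

test_that("windows with identical traits or too few points are degenerate", {
  nr <- 10; nc <- 10
  traits <- lapply(1:3, function(k) matrix(0.4, nr, nc))
  fd <- map_functional_diversity(traits, matrix(TRUE, nr, nc),
                                 circular_kernel(3), alpha = "convex")
  expect_equal(fd$fric[5, 5], 0)          # zero dispersion
  expect_true(is.na(fd$feve[5, 5]))       # coincident points
  sparse <- lapply(1:3, function(k) {
    m <- matrix(NA_real_, nr, nc); m[5, 5] <- 0.2; m[5, 6] <- 0.3; m
  })
  fd2 <- map_functional_diversity(sparse, matrix(TRUE, nr, nc),
                                  circular_kernel(3), alpha = "convex",
                                  min_cover = 0)
  expect_true(is.na(fd2$fric[5, 5]))      # n_points < min_points
  expect_equal(fd2$n_points[5, 5], 2)
})

test_that("low kernel coverage suppresses the center pixel", {
  nr <- 10; nc <- 10
  traits <- lapply(1:3, function(k) matrix(runif(nr * nc), nr, nc))
  mask <- matrix(TRUE, nr, nc)
  fd <- map_functional_diversity(traits, mask, circular_kernel(3),
                                 alpha = "convex", min_cover = 0.5)
  expect_true(is.na(fd$fric[1, 1]))   # corner window mostly off-grid
  expect_false(is.na(fd$fric[5, 5]))
})

test_that("richness and evenness maps are near-independent on default landscapes", {
  tr <- generate_truth(landscape_config(), seed = 20260401)
  ok <- is.finite(tr$truth_fd$fric) & is.finite(tr$truth_fd$feve)
  expect_lt(cor(tr$truth_fd$fric[ok], tr$truth_fd$feve[ok])^2, 0.1)
})
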
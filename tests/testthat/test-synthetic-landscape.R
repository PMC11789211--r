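small_cfg <- function(n_regions = 6, ...) {
  landscape_config(rows = 48, cols = 48, n_regions = n_regions, ...)
}

test_that("identical config and seed give bit-identical truth and scenes", {
  t1 <- generate_truth(small_cfg(), seed = 5)
  t2 <- generate_truth(small_cfg(), seed = 5)
  expect_identical(t1$patch_map, t2$patch_map)
  expect_identical(t1$traits, t2$traits)
  expect_identical(t1$year_factors, t2$year_factors)
  s1 <- render_scene(t1, 4)
  s2 <- render_scene(t2, 4)
  expect_identical(s1$bands, s2$bands)
  t3 <- generate_truth(small_cfg(), seed = 6)
  expect_false(identical(t1$patch_map, t3$patch_map))
})

test_that("configuration preconditions are enforced", {
  expect_error(landscape_config(rows = 16), "32")
  expect_error(landscape_config(rows = 40, cols = 40, n_regions = 2000),
               "n_regions")
  expect_error(generate_truth(small_cfg(), 1) |> render_scene(99),
               "not a configured acquisition")
})

test_that("patch and region maps reference existing labels and all regions", {
  cfg <- small_cfg()
  tr <- generate_truth(cfg, seed = 8)
  expect_true(all(tr$patch_map %in% seq_len(cfg$n_species)))
  expect_setequal(unique(as.vector(tr$subregion_map)), seq_len(cfg$n_regions))
  expect_true(all(tr$species_traits >= 0 & tr$species_traits <= 1))
})

test_that("noiseless scenes invert exactly back to the trait and NDWI targets", {
  cfg <- noiseless_config(rows = 48, cols = 48, n_regions = 6)
  tr <- generate_truth(cfg, seed = 3)
  sc <- render_scene(tr, 1)
  expect_lt(max(abs(compute_index(sc, "CIre") - tr$traits$chl)), 1e-9)
  expect_lt(max(abs(compute_index(sc, "CCI") - tr$traits$ccr)), 1e-9)
  expect_lt(max(abs(compute_index(sc, "NDII") - tr$traits$ewt)), 1e-9)
  # august scene of the drought year carries the dipped NDWI target
  aug2 <- tr$dates$date_index[tr$dates$role == "august" & tr$dates$year == 2][1]
  sc2 <- render_scene(tr, aug2)
  target <- tr$ndwi_base * tr$year_factors[[2]]
  expect_lt(max(abs(compute_index(sc2, "NDWI") - target)), 1e-9)
  # determinism of the render
  expect_identical(sc2$bands, render_scene(tr, aug2)$bands)
})

test_that("injected clouds violate the cloud-free rule at the expected rate", {
  cfg <- small_cfg(cloud_fraction = 0.05, shadow_fraction = 0.04)
  tr <- generate_truth(cfg, seed = 17)
  npix <- cfg$rows * cfg$cols
  p <- cfg$cloud_fraction + cfg$shadow_fraction
  tol <- 4 * sqrt(p * (1 - p) / npix) + 2 / npix
  for (d in c(1, 5)) {
    viol <- mean(!cloudfree_mask(render_scene(tr, d)))
    expect_lt(abs(viol - p), tol)
  }
  # clean configuration leaves every pixel cloud-free
  tr0 <- generate_truth(noiseless_config(rows = 48, cols = 48, n_regions = 6), 1)
  expect_true(all(cloudfree_mask(render_scene(tr0, 1))))
})

test_that("a single species without trait variation collapses richness to zero", {
  cfg <- small_cfg(n_species = 1, trait_jitter_sd = 0)
  tr <- generate_truth(cfg, seed = 2)
  fric <- tr$truth_fd$fric
  expect_true(all(fric[is.finite(fric)] == 0))
})

test_that("switching the diversity linkage off gives one uniform NDWI drop", {
  cfg <- small_cfg(beta_ric = 0, gamma_eve = c(0, 0), noise_sd_response = 0,
                   region_effect_sd = 0)
  tr <- generate_truth(cfg, seed = 4)
  drop <- tr$year_factors[[2]] - 1
  expect_equal(max(drop) - min(drop), 0)
  expect_equal(unique(as.vector(drop)), cfg$drop_mean)
})

test_that("the generated dataset round-trips through disk", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(n_regions = 4)
  res <- generate_dataset(cfg, seed = 9, out_dir = dir)
  expect_length(res$files$scenes, nrow(res$truth$dates))
  tr2 <- read_truth_json(res$files$truth)
  expect_equal(tr2$patch_map, res$truth$patch_map)
  expect_equal(tr2$traits, res$truth$traits, tolerance = 1e-12)
  expect_equal(tr2$year_factors, res$truth$year_factors, tolerance = 1e-12)
  expect_equal(tr2$ric01, res$truth$ric01, tolerance = 1e-12)
  sc <- read_scene_tif(res$files$scenes[1])
  sc0 <- render_scene(res$truth, 1)
  expect_equal(sc$bands$B8A, sc0$bands$B8A, tolerance = 1e-6)
  polys <- read_forest_geojson(res$files$polygons)
  expect_equal(rasterize_polygons(polys, c(cfg$rows, cfg$cols),
                                  cfg$pixel_size),
               res$truth$forest_mask)
})

test_that("a run without four years of data fails with a clear error", {
  cfg <- small_cfg(years = 1)
  rc <- run_config(generator = cfg, alpha = "convex")
  expect_error(run_synthetic_analysis(rc, seed = 1), "4 years")
})
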
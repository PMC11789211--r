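#' Synthetic landscape configuration
#'
#' Settings for the synthetic-landscape generator. The generator emulates a
#' patchy mixed forest observed by a decametric multispectral sensor: species
#' patches with distinct trait triples (chlorophyll proxy CHL,
#' carotenoid/chlorophyll proxy CCR, water-content proxy EWT), reflectance
#' bands constructed by inverting the index definitions so that CIre, CCI,
#' NDII and NDWI recover known targets, cloud/shadow contamination, four
#' yearly NDWI levels encoding a drought dip with partial rebound, geographic
#' subregions, and a configurable generative linkage between local diversity
#' and the drought response.
#'
#' The NDWI drop of the drought year at each pixel is
#' `drop = drop_mean + beta_ric * ric01 + gamma_eve[1] * eve01 +
#' gamma_eve[2] * eve01^2 + region effect + noise`, where `ric01` and `eve01`
#' are the true local functional richness and evenness (computed from the
#' noise-free trait layers with the same circular kernel the pipeline uses,
#' convex-hull mode, rescaled to 0--1). Year trajectories are
#' `NDWI_1 = base`, `NDWI_2 = base * (1 + drop)`,
#' `NDWI_3 = base * (1 + rebound_frac * drop)` and
#' `NDWI_4 = base * (1 + relapse_frac * drop)`: a dip in year 2, a strong
#' rebound in year 3 and a partial relapse in year 4.
#'
#' @param rows,cols Grid size in 20 m pixels (minimum 32).
#' @param n_species Number of species with distinct trait triples.
#' @param n_regions Number of geographic subregions `K` (default 21).
#' @param pixel_size Pixel edge length in meters.
#' @param trait_range Range from which species trait triples are drawn.
#' @param trait_jitter_sd Within-species trait standard deviation at pixel
#'   scale (within-species variability at 20 m is poorly known; it is a
#'   parameter, not an assertion).
#' @param trait_clip Hard clip applied to jittered traits; kept inside the
#'   invertible range of the band inversions.
#' @param patch_seeds_per_species Flood-fill seed points per species.
#' @param anchors Fixed anchor reflectances for the under-determined band
#'   inversions (B5 for CIre, B4 for CCI, B11 for NDII/NDWI).
#' @param b2_clear,b6_base,b12_base Background reflectances of the bands not
#'   constrained by an index.
#' @param ndwi_base Baseline (pre-drought) NDWI level.
#' @param drop_mean Mean fractional NDWI drop of the drought year.
#' @param beta_ric Slope of the generative richness linkage (response units
#'   per unit of rescaled richness).
#' @param gamma_eve Length-2 vector: linear and quadratic coefficients of the
#'   generative evenness linkage.
#' @param rebound_frac,relapse_frac Fractions of the drop retained in the
#'   rebound year (3) and the final year (4).
#' @param region_effect_sd SD of per-subregion response offsets.
#' @param noise_sd_reflectance Gaussian band noise SD (reflectance units;
#'   instrument-level noise, atmospheric effects are out of scope).
#' @param noise_sd_ndwi Per-date jitter SD of the NDWI target (scene-to-scene
#'   variation within a month).
#' @param noise_sd_response Per-pixel, per-year SD of the response noise.
#' @param cloud_fraction,shadow_fraction Expected contamination rates per
#'   acquisition date.
#' @param n_diversity_dates Early-summer acquisitions for the diversity
#'   composite (default 3).
#' @param years Number of years of late-summer composites (the drought
#'   analysis needs 4).
#' @param dates_per_year Late-summer acquisitions per year (default 3).
#' @param forest_margin_px Non-forest margin width around the grid.
#' @param n_clearings,clearing_px Number and size range of rectangular
#'   non-forest clearings.
#' @param kernel_radius_px Moving-window radius used for the truth linkage.
#' @param clip_pct Tail-clip percentage used when rescaling the truth
#'   diversity layers.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(rows = 96, cols = 96, n_species = 8,
                             n_regions = 21, pixel_size = 20,
                             trait_range = c(0.20, 0.72),
                             trait_jitter_sd = 0.03,
                             trait_clip = c(0.15, 0.78),
                             patch_seeds_per_species = 6,
                             anchors = c(B5 = 0.08, B4 = 0.06, B11 = 0.12),
                             b2_clear = 0.02, b6_base = 0.25, b12_base = 0.15,
                             ndwi_base = 0.62, drop_mean = -0.25,
                             beta_ric = 0.10, gamma_eve = c(0.10, -0.10),
                             rebound_frac = 0.3, relapse_frac = 0.5,
                             region_effect_sd = 0.02,
                             noise_sd_reflectance = 0.002,
                             noise_sd_ndwi = 0.005,
                             noise_sd_response = 0.02,
                             cloud_fraction = 0.03, shadow_fraction = 0.02,
                             n_diversity_dates = 3, years = 4,
                             dates_per_year = 3, forest_margin_px = 2,
                             n_clearings = 3, clearing_px = c(4, 10),
                             kernel_radius_px = 3, clip_pct = 0.1) {
  cfg <- as.list(environment())
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

validate_landscape_config <- function(cfg) {
  if (cfg$rows < 32 || cfg$cols < 32)
    stop_cfg("grid must be at least 32 x 32 pixels")
  if (cfg$n_species < 1) stop_cfg("n_species must be >= 1")
  if (cfg$n_regions < 1 || cfg$n_regions > cfg$rows * cfg$cols)
    stop_cfg("n_regions must be in [1, number of pixels]")
  if (cfg$years < 1) stop_cfg("years must be >= 1")
  invisible(cfg)
}

#' Acquisition date table of a configuration
#'
#' @param config A [landscape_config()].
#' @return Tibble with `date_index`, `role` (`"diversity"` or `"august"`),
#'   `year` (NA for diversity dates) and `date_tag`.
#' @export
scene_dates <- function(config) {
  nd <- config$n_diversity_dates
  div <- tibble::tibble(date_index = seq_len(nd), role = "diversity",
                        year = NA_integer_,
                        date_tag = sprintf("diversity-%d", seq_len(nd)))
  aug <- tidyr::expand_grid(year = seq_len(config$years),
                            rep = seq_len(config$dates_per_year))
  aug <- tibble::tibble(date_index = nd + seq_len(nrow(aug)), role = "august",
                        year = aug$year,
                        date_tag = sprintf("august-y%d-%d", aug$year, aug$rep))
  dplyr::bind_rows(div, aug)
}

#' Generate the ground truth of a synthetic landscape
#'
#' Builds species patches by seeded multi-source flood fill, subregions by
#' nearest-seed tessellation, a forest area with margin and clearings, true
#' per-pixel trait layers (species trait plus within-species jitter), the
#' true local diversity layers, and the four-year NDWI targets carrying the
#' generative diversity--response linkage (see [landscape_config()]).
#'
#' @param config A [landscape_config()].
#' @param seed Integer root seed; all stages draw from named substreams of
#'   it, so the same (config, seed) gives bit-identical truth.
#' @return Object of class `landscape_truth`.
#' @export
generate_truth <- function(config = landscape_config(), seed = 1) {
  validate_landscape_config(config)
  nr <- config$rows; nc <- config$cols; npix <- nr * nc

  species_traits <- with_substream(seed, "species", 0L, {
    matrix(runif(config$n_species * 3, config$trait_range[1],
                 config$trait_range[2]),
           ncol = 3, dimnames = list(NULL, c("chl", "ccr", "ewt")))
  })

  patch_map <- with_substream(seed, "patches", 0L,
                              flood_fill_patches(nr, nc, config$n_species,
                                                 config$patch_seeds_per_species))

  subregion_map <- with_substream(seed, "regions", 0L,
                                  voronoi_regions(nr, nc, config$n_regions))

  forest <- with_substream(seed, "forest", 0L, {
    m <- matrix(TRUE, nr, nc)
    if (config$forest_margin_px > 0) {
      e <- config$forest_margin_px
      m[seq_len(e), ] <- FALSE; m[nr - seq_len(e) + 1, ] <- FALSE
      m[, seq_len(e)] <- FALSE; m[, nc - seq_len(e) + 1] <- FALSE
    }
    for (k in seq_len(config$n_clearings)) {
      h <- sample(config$clearing_px[1]:config$clearing_px[2], 1)
      w <- sample(config$clearing_px[1]:config$clearing_px[2], 1)
      i0 <- sample(seq_len(nr - h), 1); j0 <- sample(seq_len(nc - w), 1)
      m[i0:(i0 + h - 1), j0:(j0 + w - 1)] <- FALSE
    }
    m
  })
  polygons <- forest_polygons(forest, config$pixel_size)

  traits <- with_substream(seed, "jitter", 0L, {
    lapply(1:3, function(tr) {
      base <- matrix(species_traits[patch_map, tr], nr, nc)
      j <- if (config$trait_jitter_sd > 0)
        matrix(rnorm(npix, 0, config$trait_jitter_sd), nr, nc) else 0
      clamp(base + j, config$trait_clip[1], config$trait_clip[2])
    })
  })
  names(traits) <- c("chl", "ccr", "ewt")

  # true local diversity of the noise-free trait layers; convex-hull mode
  # keeps the truth linkage free of the alpha tuning parameter
  kernel <- circular_kernel(config$kernel_radius_px)
  tmask <- lapply(traits, function(m) { m[!forest] <- NA_real_; m })
  fd <- map_functional_diversity(tmask, forest, kernel, alpha = "convex")
  ric01 <- rescale01_or_flat(fd$fric, config$clip_pct)
  eve01 <- rescale01_or_flat(fd$feve, config$clip_pct)

  region_effects <- with_substream(seed, "region_effects", 0L,
                                   rnorm(config$n_regions, 0,
                                         config$region_effect_sd))

  ric_fill <- mean(ric01, na.rm = TRUE)
  eve_fill <- mean(eve01, na.rm = TRUE)
  r01 <- ifelse(is.na(ric01), ric_fill, ric01)
  e01 <- ifelse(is.na(eve01), eve_fill, eve01)
  drop_signal <- config$drop_mean + config$beta_ric * r01 +
    config$gamma_eve[1] * e01 + config$gamma_eve[2] * e01^2 +
    matrix(region_effects[subregion_map], nr, nc)

  eps_y <- with_substream(seed, "response", 0L, {
    lapply(seq_len(max(config$years - 1, 0)), function(y)
      if (config$noise_sd_response > 0)
        matrix(rnorm(npix, 0, config$noise_sd_response), nr, nc)
      else matrix(0, nr, nc))
  })

  ndwi_base <- matrix(config$ndwi_base, nr, nc)
  year_factors <- vector("list", config$years)
  year_factors[[1]] <- matrix(1, nr, nc)
  fracs <- c(1, config$rebound_frac, config$relapse_frac)
  for (y in seq_len(config$years)[-1]) {
    f <- if (y - 1 <= length(fracs)) fracs[y - 1] else config$relapse_frac
    year_factors[[y]] <- 1 + f * drop_signal + eps_y[[y - 1]]
  }

  structure(list(config = config, seed = seed,
                 species_traits = species_traits, patch_map = patch_map,
                 subregion_map = subregion_map, forest_mask = forest,
                 polygons = polygons, traits = traits,
                 truth_fd = fd, ric01 = ric01, eve01 = eve01,
                 region_effects = region_effects, drop_signal = drop_signal,
                 ndwi_base = ndwi_base, year_factors = year_factors,
                 dates = scene_dates(config)),
            class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf(
    "<landscape_truth> %d x %d px, %d species, %d subregions, seed %d\n  forest: %d px; dates: %d diversity + %d august\n",
    x$config$rows, x$config$cols, x$config$n_species, x$config$n_regions,
    x$seed, sum(x$forest_mask), x$config$n_diversity_dates,
    sum(x$dates$role == "august")))
  invisible(x)
}

# a metric that is undefined everywhere (e.g. evenness of a single-species
# landscape) carries no linkage information; use the degenerate midpoint
rescale01_or_flat <- function(x, clip_pct) {
  if (!any(is.finite(x))) {
    x[] <- 0.5
    return(x)
  }
  rescale01(x, clip_pct)
}

# Multi-source BFS flood fill: species claim pixels outward from their seed
# points, producing a patchy mixed-stand tessellation.
flood_fill_patches <- function(nr, nc, n_species, seeds_per_species) {
  npix <- nr * nc
  lab <- integer(npix)
  n_seeds <- n_species * seeds_per_species
  cells <- sample.int(npix, min(n_seeds, npix))
  owner <- rep(seq_len(n_species), length.out = length(cells))
  queue <- integer(npix + length(cells))
  lab[cells] <- owner
  ord <- sample.int(length(cells))
  queue[seq_along(cells)] <- cells[ord]
  head <- 1L; tail <- length(cells)
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    i <- ((p - 1L) %% nr) + 1L
    j <- ((p - 1L) %/% nr) + 1L
    sp <- lab[p]
    for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                if (j > 1L) p - nr, if (j < nc) p + nr)) {
      if (lab[q] == 0L) {
        lab[q] <- sp
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
  }
  matrix(lab, nr, nc)
}

# nearest-seed tessellation with K guaranteed distinct labels
voronoi_regions <- function(nr, nc, K) {
  cells <- sample.int(nr * nc, K)
  si <- ((cells - 1L) %% nr) + 1L
  sj <- ((cells - 1L) %/% nr) + 1L
  ii <- matrix(rep(seq_len(nr), nc), nr, nc)
  jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(Inf, nr, nc)
  lab <- matrix(1L, nr, nc)
  for (k in seq_len(K)) {
    d <- (ii - si[k])^2 + (jj - sj[k])^2
    upd <- d < best
    lab[upd] <- k
    best[upd] <- d[upd]
  }
  lab[cells] <- seq_len(K)  # seeds keep their own label even under ties
  lab
}

# invertible target ranges for the band inversions, given the anchors
invert_band <- function(index_name, target, anchor, pixel_label) {
  if (index_name == "CIre") {
    bad <- target < 0 | anchor * (1 + target) > 1
    if (any(bad)) stop_cfg("CIre target out of invertible range at pixel %s",
                           pixel_label(which(bad)[1]))
    anchor * (1 + target)
  } else {
    hi <- (1 - anchor) / (1 + anchor)
    bad <- target <= -1 | target >= 1 | target > hi
    if (any(bad)) stop_cfg("%s target out of invertible range at pixel %s",
                           index_name, pixel_label(which(bad)[1]))
    anchor * (1 + target) / (1 - target)
  }
}

#' Render the reflectance scene of one acquisition date
#'
#' Constructs the ten bands by inverting the index definitions -- B7 so CIre
#' equals the pixel's CHL target (anchor B5), B3 so CCI equals CCR (anchor
#' B4), B8A so NDII equals EWT (anchor B11), B8 so NDWI equals the date's
#' target (anchor B11) -- then injects cloud and shadow patches that violate
#' the cloud-free rule, adds Gaussian band noise, and clips to `[0, 1]`.
#'
#' @param truth A [generate_truth()] result.
#' @param date_index Row of `truth$dates`.
#' @return An [rs_scene()].
#' @export
render_scene <- function(truth, date_index) {
  cfg <- truth$config
  dates <- truth$dates
  if (!date_index %in% dates$date_index)
    stop_cfg("date_index %s is not a configured acquisition", date_index)
  info <- dates[dates$date_index == date_index, ]
  nr <- cfg$rows; nc <- cfg$cols; npix <- nr * nc
  pixel_label <- function(p) sprintf("(%d, %d)", ((p - 1) %% nr) + 1,
                                     ((p - 1) %/% nr) + 1)

  ndwi_target <- if (info$role == "diversity") truth$ndwi_base else
    truth$ndwi_base * truth$year_factors[[info$year]]
  ndwi_target <- ndwi_target + with_substream(truth$seed, "ndwi_jitter",
                                              date_index, {
    if (cfg$noise_sd_ndwi > 0) matrix(rnorm(npix, 0, cfg$noise_sd_ndwi), nr, nc)
    else 0
  })

  an <- cfg$anchors
  bands <- list(
    B2 = matrix(cfg$b2_clear, nr, nc),
    B3 = invert_band("CCI", truth$traits$ccr, an[["B4"]], pixel_label),
    B4 = matrix(an[["B4"]], nr, nc),
    B5 = matrix(an[["B5"]], nr, nc),
    B6 = matrix(cfg$b6_base, nr, nc),
    B7 = invert_band("CIre", truth$traits$chl, an[["B5"]], pixel_label),
    B8 = invert_band("NDWI", ndwi_target, an[["B11"]], pixel_label),
    B8A = invert_band("NDII", truth$traits$ewt, an[["B11"]], pixel_label),
    B11 = matrix(an[["B11"]], nr, nc),
    B12 = matrix(cfg$b12_base, nr, nc))

  contam <- with_substream(truth$seed, "clouds", date_index, {
    cloud <- sample_patches(nr, nc, cfg$cloud_fraction, exclude = NULL)
    shadow <- sample_patches(nr, nc, cfg$shadow_fraction, exclude = cloud)
    list(cloud = cloud, shadow = shadow)
  })
  if (any(contam$cloud)) {
    bands$B2[contam$cloud] <- 0.30
    for (nm in setdiff(names(bands), "B2"))
      bands[[nm]][contam$cloud] <- clamp(bands[[nm]][contam$cloud] * 0.8 + 0.2,
                                         0, 1)
  }
  if (any(contam$shadow)) {
    for (nm in names(bands))
      bands[[nm]][contam$shadow] <- bands[[nm]][contam$shadow] * 0.12
  }

  bands <- with_substream(truth$seed, "noise", date_index, {
    lapply(bands, function(b) {
      if (cfg$noise_sd_reflectance > 0)
        b <- b + matrix(rnorm(npix, 0, cfg$noise_sd_reflectance), nr, nc)
      clamp(b, 0, 1)
    })
  })
  rs_scene(bands, pixel_size = cfg$pixel_size, date_tag = info$date_tag)
}

# contaminate ~frac of all pixels with circular patches; the pixel count is
# drawn from the binomial law so realized fractions match frac up to
# binomial sampling error, with patchy spatial structure
sample_patches <- function(nr, nc, frac, exclude = NULL) {
  m <- matrix(FALSE, nr, nc)
  if (frac <= 0) return(m)
  npix <- nr * nc
  target <- rbinom(1, npix, frac)
  if (target == 0) return(m)
  avail <- if (is.null(exclude)) matrix(TRUE, nr, nc) else !exclude
  guard <- 0
  while (sum(m) < target && guard < 10000) {
    guard <- guard + 1
    ci <- sample.int(nr, 1); cj <- sample.int(nc, 1)
    r <- runif(1, 1.5, 4.5)
    ii <- max(1, floor(ci - r)):min(nr, ceiling(ci + r))
    jj <- max(1, floor(cj - r)):min(nc, ceiling(cj + r))
    disk <- outer(ii, jj, function(a, b) (a - ci)^2 + (b - cj)^2 <= r^2)
    m[ii, jj][disk & avail[ii, jj]] <- TRUE
  }
  excess <- sum(m) - target
  if (excess > 0) {
    on <- which(m)
    m[sample(on, excess)] <- FALSE
  }
  m
}

#' Generate a full synthetic input set on disk
#'
#' Writes one multi-band raster per acquisition date, the forest polygons as
#' GeoJSON, the subregion label raster, and the ground truth as JSON, all
#' consumable by [run_pipeline()] with no other inputs.
#'
#' @param config A [landscape_config()].
#' @param seed Integer root seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `landscape_truth` and the file paths.
#' @export
generate_dataset <- function(config = landscape_config(), seed = 1, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_cfg("cannot create output directory %s", out_dir)
  truth <- generate_truth(config, seed)
  scene_paths <- character(nrow(truth$dates))
  for (k in seq_len(nrow(truth$dates))) {
    sc <- render_scene(truth, truth$dates$date_index[k])
    scene_paths[k] <- file.path(out_dir,
                                sprintf("scene-%02d-%s.tif", k,
                                        truth$dates$date_tag[k]))
    write_scene_tif(sc, scene_paths[k])
  }
  poly_path <- file.path(out_dir, "forest.geojson")
  write_forest_geojson(truth$polygons, poly_path)
  region_path <- file.path(out_dir, "subregions.tif")
  write_raster_tif(truth$subregion_map + 0, region_path,
                   layer_names = "subregion")
  truth_path <- file.path(out_dir, "truth.json")
  write_truth_json(truth, truth_path)
  invisible(list(truth = truth,
                 files = list(scenes = scene_paths, polygons = poly_path,
                              subregions = region_path, truth = truth_path)))
}
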
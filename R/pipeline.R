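#' Run configuration for the full pipeline
#'
#' Bundles the generator settings with the analysis settings of every stage.
#' All values are validated up front and a frozen copy is written into the
#' output directory by [run_pipeline()].
#'
#' @param generator A [landscape_config()] (synthetic mode).
#' @param alpha Richness hull mode passed to [map_functional_diversity()]:
#'   `"adaptive"` (default), `"convex"`, or a fixed positive alpha.
#' @param alpha_mult Adaptive-alpha multiplier.
#' @param use_kernel_weights Kernel area fractions as FEve abundances.
#' @param c_ndvi,c_shadow,votes Forest-mask constants (see
#'   [build_forest_mask()]).
#' @param min_patch_px,erosion_px Edge-exclusion parameters (see
#'   [exclude_edge_patches()]).
#' @param eps Denominator guard for change ratios.
#' @param clip_pct Tail-clip percent for all 0--1 rescaling.
#' @param n_bins_univariate,n_bins_combined Bin counts of the separate
#'   (default 1000) and combined (default 20) analyses.
#' @param min_bin_frac Small-bin exclusion threshold of the separate analysis.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = landscape_config(), alpha = "adaptive",
                       alpha_mult = 2, use_kernel_weights = TRUE,
                       c_ndvi = 3, c_shadow = 3, votes = 2,
                       min_patch_px = 28, erosion_px = 0, eps = 1e-3,
                       clip_pct = 0.1, n_bins_univariate = 1000,
                       n_bins_combined = 20, min_bin_frac = 0.01) {
  validate_landscape_config(generator)
  if (eps <= 0) stop_cfg("eps must be > 0")
  if (n_bins_combined < 2 || n_bins_univariate < 2)
    stop_cfg("bin counts must be >= 2")
  structure(as.list(environment()), class = "run_config")
}

.pipeline_stages <- c("simulate", "indices", "mask", "diversity", "response",
                      "analyze")

# ---- in-memory stage helpers ------------------------------------------------

#' Composite trait maps from the early-summer scenes
#'
#' Computes CIre, CCI and NDII per scene, keeps only cloud-free pixels, and
#' takes the per-pixel median across scenes.
#'
#' @param scenes List of diversity-date [rs_scene()] objects.
#' @return Named list of matrices `chl`, `ccr`, `ewt`.
#' @export
composite_trait_maps <- function(scenes) {
  idx <- c(chl = "CIre", ccr = "CCI", ewt = "NDII")
  out <- lapply(idx, function(ix) {
    per_scene <- lapply(scenes, function(sc) {
      v <- compute_index(sc, ix)
      v[!cloudfree_mask(sc)] <- NA_real_
      v
    })
    median_composite(per_scene, tag = ix)
  })
  names(out) <- names(idx)
  out
}

#' Yearly NDWI composites from the late-summer scenes
#'
#' @param scenes List of august [rs_scene()] objects.
#' @param years Integer year id of each scene.
#' @return List of per-year median NDWI matrices, in year order.
#' @export
yearly_ndwi_composites <- function(scenes, years) {
  stopifnot(length(scenes) == length(years))
  lapply(sort(unique(years)), function(y) {
    per <- lapply(scenes[years == y], function(sc) {
      v <- compute_index(sc, "NDWI")
      v[!cloudfree_mask(sc)] <- NA_real_
      v
    })
    median_composite(per, tag = sprintf("year%d", y))
  })
}

#' Binning, univariate fits and variance partitioning of one landscape
#'
#' Rescales the diversity maps to 0--1 (with tail clipping), runs the
#' 1000-bin separate analyses (each diversity metric against each response,
#' weighted AIC form selection), builds the 20 x 20 x K stratified table and
#' fits the weighted sequential-SS models with conservative F-ratios and
#' subregion correction.
#'
#' @param fd An [map_functional_diversity()] result.
#' @param responses A [drought_responses()] result.
#' @param subregion_map Integer subregion raster.
#' @param mask Logical analysis mask.
#' @param config A [run_config()].
#' @return List with `ric01`, `eve01`, `univariate` (tibble of fits),
#'   `strata`, `anova` (list by response, each with conservative F), and
#'   `corrected` (list by response).
#' @export
analyze_diversity_response <- function(fd, responses, subregion_map, mask,
                                       config = run_config()) {
  fric <- fd$fric; fric[!mask] <- NA_real_
  feve <- fd$feve; feve[!mask] <- NA_real_
  ric01 <- rescale01(fric, config$clip_pct)
  eve01 <- rescale01(feve, config$clip_pct)
  resp <- list(rst = responses$resistance, rcv = responses$recovery,
               rsl = responses$resilience)
  resp <- lapply(resp, function(m) { m[!mask] <- NA_real_; m })

  uni <- tidyr::expand_grid(metric = c("ric", "eve"),
                            response = names(resp))
  uni_fits <- purrr::pmap(uni, function(metric, response) {
    series <- binned_series(if (metric == "ric") ric01 else eve01,
                            resp[[response]], config$n_bins_univariate)
    series <- filter_small_bins(series, config$min_bin_frac)
    fit_univariate(series)
  })
  uni$fit <- uni_fits
  uni$chosen <- purrr::map_chr(uni_fits, "chosen")
  uni$r2 <- purrr::map_dbl(uni_fits, ~ unname(.x$r2[.x$chosen]))
  uni$n_bins_used <- purrr::map_int(uni_fits, ~ as.integer(.x$n_bins_used))

  strata <- stratified_table(ric01, eve01, subregion_map, resp,
                             config$n_bins_combined)
  anovas <- lapply(setNames(nm = names(resp)), function(r)
    conservative_f(fit_combined(strata, r)))
  corrected <- lapply(setNames(nm = names(resp)), function(r)
    region_correct(strata, r))
  list(ric01 = ric01, eve01 = eve01, univariate = uni, strata = strata,
       anova = anovas, corrected = corrected)
}

#' Run the full synthetic pipeline in memory
#'
#' Convenience wrapper chaining generation, rendering, index computation,
#' masking, diversity and response mapping, and the statistical analysis,
#' without writing artifacts. [run_pipeline()] is the on-disk, resumable
#' equivalent.
#'
#' @param config A [run_config()].
#' @param seed Integer root seed.
#' @return List with `truth`, `scenes` (not retained; NULL), `traits`,
#'   `mask`, `fd`, `responses`, and the [analyze_diversity_response()]
#'   result under `analysis`.
#' @export
run_synthetic_analysis <- function(config = run_config(), seed = 1) {
  gen <- config$generator
  truth <- generate_truth(gen, seed)
  dates <- truth$dates
  div_scenes <- lapply(dates$date_index[dates$role == "diversity"],
                       function(k) render_scene(truth, k))
  traits <- composite_trait_maps(div_scenes)

  mask <- build_forest_mask(div_scenes, truth$polygons, config$c_ndvi,
                            config$c_shadow, config$votes)
  mask <- exclude_edge_patches(mask, config$min_patch_px, config$erosion_px)

  tmask <- lapply(traits, function(m) { m[!mask] <- NA_real_; rescale01(m, config$clip_pct) })
  kernel <- circular_kernel(gen$kernel_radius_px)
  fd <- map_functional_diversity(tmask, mask, kernel, alpha = config$alpha,
                                 alpha_mult = config$alpha_mult,
                                 use_kernel_weights = config$use_kernel_weights)

  if (gen$years < 4)
    stop_cfg("drought-response analysis needs 4 years of composites (got %d)",
             gen$years)
  aug <- dates[dates$role == "august", ]
  aug_scenes <- lapply(aug$date_index, function(k) render_scene(truth, k))
  yearly <- yearly_ndwi_composites(aug_scenes, aug$year)
  responses <- drought_responses(yearly[1:4], eps = config$eps)

  analysis <- analyze_diversity_response(fd, responses, truth$subregion_map,
                                         mask, config)
  list(truth = truth, traits = traits, mask = mask, fd = fd,
       responses = responses, yearly = yearly, analysis = analysis)
}

# ---- on-disk pipeline -------------------------------------------------------

stage_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

outputs_current <- function(manifest, stage, out_dir) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  paths <- file.path(out_dir, names(st$md5))
  if (!all(file.exists(paths))) return(FALSE)
  identical(unname(unlist(stage_hashes(paths))), unname(unlist(st$md5)))
}

#' Run the pipeline with on-disk artifacts, hashing and resume
#'
#' Executes the six stages `simulate`, `indices`, `mask`, `diversity`,
#' `response`, `analyze` in order, writing every intermediate artifact into
#' `out_dir` together with a manifest (stage, outputs, content hash, wall
#' time). With `resume = TRUE`, stages whose outputs still match the
#' manifest hashes are skipped, and everything downstream of the first stale
#' stage is recomputed.
#'
#' @param config A [run_config()].
#' @param seed Integer root seed.
#' @param out_dir Output directory.
#' @param resume Skip up-to-date stages (default FALSE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), seed = 1, out_dir,
                         resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(seed = seed, config = unclass_deep(config)),
                       file.path(out_dir, "run-config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$seed <- seed
  timing <- list()
  dirty <- FALSE

  for (stage in .pipeline_stages) {
    if (resume && !dirty && outputs_current(manifest, stage, out_dir)) next
    dirty <- TRUE
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(
      run_stage(stage, config, seed, out_dir),
      error = function(e) stop_cfg("stage '%s' failed: %s", stage,
                                   conditionMessage(e)))
    manifest$stages[[stage]] <- list(outputs = as.list(basename(outputs)),
                                     md5 = stage_hashes(outputs))
    timing[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  manifest$stages <- manifest$stages[.pipeline_stages]
  manifest$timing <- timing
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

run_stage <- function(stage, config, seed, out_dir) {
  gen <- config$generator
  p <- function(...) file.path(out_dir, sprintf(...))
  dates <- scene_dates(gen)
  scene_path <- function(k) p("scene-%02d-%s.tif", k, dates$date_tag[k])
  switch(stage,
    simulate = {
      res <- generate_dataset(gen, seed, out_dir)
      c(unlist(res$files), paste0(unlist(res$files)[grepl("tif$", unlist(res$files))], ".json"))
    },
    indices = {
      div <- lapply(dates$date_index[dates$role == "diversity"], function(k)
        read_scene_tif(scene_path(k)))
      traits <- composite_trait_maps(div)
      write_raster_tif(traits, p("traits.tif"), gen$pixel_size,
                       layer_names = names(traits))
      aug <- dates[dates$role == "august", ]
      yearly <- yearly_ndwi_composites(
        lapply(aug$date_index, function(k) read_scene_tif(scene_path(k))),
        aug$year)
      write_raster_tif(yearly, p("ndwi-yearly.tif"), gen$pixel_size,
                       layer_names = sprintf("year%d", seq_along(yearly)))
      c(p("traits.tif"), p("traits.tif.json"),
        p("ndwi-yearly.tif"), p("ndwi-yearly.tif.json"))
    },
    mask = {
      div <- lapply(dates$date_index[dates$role == "diversity"], function(k)
        read_scene_tif(scene_path(k)))
      polys <- read_forest_geojson(p("forest.geojson"))
      m <- build_forest_mask(div, polys, config$c_ndvi, config$c_shadow,
                             config$votes)
      m <- exclude_edge_patches(m, config$min_patch_px, config$erosion_px)
      write_raster_tif(m + 0, p("mask.tif"), gen$pixel_size,
                       layer_names = "forest_mask")
      jsonlite::write_json(
        list(provenance = attr(m, "provenance"),
             thresholds = attr(m, "thresholds"),
             count_valid = sum(m), area_km2 = mask_area_km2(sum(m), gen$pixel_size)),
        p("mask-provenance.json"), auto_unbox = TRUE, digits = NA)
      c(p("mask.tif"), p("mask.tif.json"), p("mask-provenance.json"))
    },
    diversity = {
      traits <- read_raster_tif(p("traits.tif"))
      m <- read_raster_tif(p("mask.tif"))[, , 1] > 0
      tl <- lapply(1:3, function(k) {
        v <- traits[, , k]
        v[!m] <- NA_real_
        rescale01(v, config$clip_pct)
      })
      kernel <- circular_kernel(gen$kernel_radius_px)
      fd <- map_functional_diversity(tl, m, kernel, alpha = config$alpha,
                                     alpha_mult = config$alpha_mult,
                                     use_kernel_weights = config$use_kernel_weights)
      write_raster_tif(list(fd$fric, fd$feve, fd$n_points), p("diversity.tif"),
                       gen$pixel_size,
                       layer_names = c("fric", "feve", "n_points"))
      jsonlite::write_json(list(radius_px = fd$radius_px,
                                alpha = format(fd$alpha)),
                           p("diversity-params.json"), auto_unbox = TRUE)
      c(p("diversity.tif"), p("diversity.tif.json"),
        p("diversity-params.json"))
    },
    response = {
      if (gen$years < 4)
        stop_cfg("drought-response stage needs 4 years of composites (got %d)",
                 gen$years)
      yearly_arr <- read_raster_tif(p("ndwi-yearly.tif"))
      m <- read_raster_tif(p("mask.tif"))[, , 1] > 0
      yearly <- lapply(1:4, function(y) {
        v <- yearly_arr[, , y]
        v[!m] <- NA_real_
        v
      })
      resp <- drought_responses(yearly, eps = config$eps)
      write_raster_tif(list(resp$resistance, resp$recovery, resp$resilience),
                       p("response.tif"), gen$pixel_size,
                       layer_names = c("resistance", "recovery", "resilience"))
      c(p("response.tif"), p("response.tif.json"))
    },
    analyze = {
      dv <- read_raster_tif(p("diversity.tif"))
      rp <- read_raster_tif(p("response.tif"))
      m <- read_raster_tif(p("mask.tif"))[, , 1] > 0
      regions <- read_raster_tif(p("subregions.tif"))[, , 1]
      fd <- structure(list(fric = dv[, , 1], feve = dv[, , 2],
                           n_points = dv[, , 3]), class = "fd_map")
      resp <- structure(list(resistance = rp[, , 1], recovery = rp[, , 2],
                             resilience = rp[, , 3]),
                        class = "drought_response")
      an <- analyze_diversity_response(fd, resp, regions, m, config)
      write.csv(an$strata, p("strata.csv"), row.names = FALSE)
      uni <- an$univariate[, c("metric", "response", "chosen", "r2",
                               "n_bins_used")]
      write.csv(uni, p("univariate.csv"), row.names = FALSE)
      model_report <- lapply(an$anova, function(a)
        list(response = a$response, terms = a$terms,
             r_squared = a$r_squared,
             table = as.data.frame(a$table)))
      jsonlite::write_json(model_report, p("models.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
      for (r in names(an$corrected))
        write.csv(an$corrected[[r]], p("corrected-%s.csv", r),
                  row.names = FALSE)
      c(p("strata.csv"), p("univariate.csv"), p("models.json"),
        p("corrected-rst.csv"), p("corrected-rcv.csv"), p("corrected-rsl.csv"))
    },
    stop_cfg("unknown stage '%s'", stage))
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a completed [run_pipeline()] output directory and
#' writes `report.json`: diversity- and response-map statistics, the
#' univariate fit table, the sequential-SS tables with SS percentages and
#' conservative F-ratios, and the subregion-corrected scatter data. The
#' report is a pure function of the artifacts, so regenerating it from the
#' same run directory is byte-identical.
#'
#' @param out_dir A completed run directory.
#' @return The report list, invisibly.
#' @export
report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop_cfg("no manifest in %s", out_dir)
  manifest <- jsonlite::read_json(manifest_path)
  missing <- setdiff(.pipeline_stages, names(manifest$stages))
  if (length(missing))
    stop_cfg("incomplete run: missing stages %s", paste(missing, collapse = ", "))
  dv <- read_raster_tif(file.path(out_dir, "diversity.tif"))
  rp <- read_raster_tif(file.path(out_dir, "response.tif"))
  models <- jsonlite::read_json(file.path(out_dir, "models.json"),
                                simplifyVector = TRUE)
  uni <- utils::read.csv(file.path(out_dir, "univariate.csv"))
  layer_stats <- function(m) list(
    n_valid = n_valid(m), mean = mean(m, na.rm = TRUE),
    sd = sd(m, na.rm = TRUE),
    q = as.list(setNames(quantile(m, c(.05, .5, .95), na.rm = TRUE, names = FALSE),
                         c("q05", "q50", "q95"))))
  rep <- list(
    seed = manifest$seed,
    diversity = list(fric = layer_stats(dv[, , 1]), feve = layer_stats(dv[, , 2])),
    response = list(resistance_pct = layer_stats(100 * rp[, , 1]),
                    recovery_pct = layer_stats(100 * rp[, , 2]),
                    resilience_pct = layer_stats(100 * rp[, , 3])),
    univariate = uni,
    models = lapply(models, function(m) {
      m$table$ss_pct <- 100 * m$table$r2_increment
      m
    }))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "columns")
  invisible(rep)
}
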
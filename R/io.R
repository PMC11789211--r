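# Raster and truth serialization. Rasters are written as 32-bit float TIFF
# with values affinely packed into [0, 1]; the affine transform, grid
# metadata and nodata convention live in a JSON sidecar next to the file
# (<path>.json). Nodata is encoded as the packed sentinel 0 with data mapped
# into [0.05, 1].

.pack_lo <- 0.05

#' Write a raster (matrix or multi-layer list) to TIFF with a JSON sidecar
#'
#' @param x Numeric matrix, 3-D array, or list of matrices.
#' @param path Output `.tif` path; the sidecar is written to `<path>.json`.
#' @param pixel_size Pixel edge length in meters.
#' @param layer_names Optional layer (band) names.
#' @param nodata Nodata value recorded in the sidecar (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster_tif <- function(x, path, pixel_size = 20, layer_names = NULL,
                             nodata = -9999) {
  if (is.list(x)) x <- simplify2array(x)
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  if (rng[2] - rng[1] < 1e-300) rng[2] <- rng[1] + 1
  scaled <- .pack_lo + (x - rng[1]) / (rng[2] - rng[1]) * (1 - .pack_lo)
  scaled[is.na(x)] <- 0
  pages <- lapply(seq_len(dim(x)[3]), function(k) scaled[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(rows = dim(x)[1], cols = dim(x)[2], layers = dim(x)[3],
               pixel_size = pixel_size, nodata = nodata,
               value_min = rng[1], value_max = rng[2], pack_lo = .pack_lo,
               layer_names = as.list(layer_names %||%
                                       sprintf("layer%d", seq_len(dim(x)[3]))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster_tif()]
#'
#' @param path `.tif` path with its `<path>.json` sidecar.
#' @return A 3-D array (rows x cols x layers) with `NA` for nodata; layer
#'   names and `pixel_size` attached as attributes.
#' @export
read_raster_tif <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  img <- simplify2array(tiff::readTIFF(path, all = TRUE))
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  lo <- meta$pack_lo
  out <- (img - lo) / (1 - lo) * (meta$value_max - meta$value_min) +
    meta$value_min
  out[img < lo / 2] <- NA_real_
  attr(out, "layer_names") <- unlist(meta$layer_names)
  attr(out, "pixel_size") <- meta$pixel_size
  out
}

#' Write a scene's band stack to TIFF
#'
#' @param scene An [rs_scene()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_tif <- function(scene, path) {
  write_raster_tif(scene$bands, path, pixel_size = scene$pixel_size,
                   layer_names = names(scene$bands))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$date_tag <- scene$date_tag
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scene written by [write_scene_tif()]
#'
#' @param path `.tif` path.
#' @return An [rs_scene()].
#' @export
read_scene_tif <- function(path) {
  arr <- read_raster_tif(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  nms <- attr(arr, "layer_names")
  bands <- setNames(lapply(seq_len(dim(arr)[3]), function(k) arr[, , k]), nms)
  rs_scene(bands, pixel_size = attr(arr, "pixel_size"),
           date_tag = meta$date_tag %||% "")
}

mat_to_json <- function(m) list(dim = dim(m), data = as.vector(m))
# x comes from jsonlite::read_json(..., simplifyVector = TRUE): nulls are NA
json_to_mat <- function(x) {
  matrix(as.numeric(x$data), x$dim[1], x$dim[2])
}

#' Serialize a landscape truth to JSON
#'
#' @param truth A [generate_truth()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  cfg <- unclass(truth$config)
  obj <- list(
    seed = truth$seed, config = cfg,
    species_traits = list(dim = dim(truth$species_traits),
                          data = as.vector(truth$species_traits)),
    patch_map = mat_to_json(truth$patch_map),
    subregion_map = mat_to_json(truth$subregion_map),
    forest_mask = mat_to_json(truth$forest_mask + 0L),
    traits = lapply(truth$traits, mat_to_json),
    ric01 = mat_to_json(truth$ric01), eve01 = mat_to_json(truth$eve01),
    region_effects = truth$region_effects,
    drop_signal = mat_to_json(truth$drop_signal),
    ndwi_base = mat_to_json(truth$ndwi_base),
    year_factors = lapply(truth$year_factors, mat_to_json))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a landscape truth from JSON
#'
#' @param path Path written by [write_truth_json()].
#' @return A `landscape_truth` object (polygons and date table are rebuilt
#'   from the stored forest mask and configuration).
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- obj$config
  cfg$anchors <- setNames(as.numeric(cfg$anchors), c("B5", "B4", "B11"))
  class(cfg) <- "landscape_config"
  st <- matrix(as.numeric(obj$species_traits$data),
               ncol = 3, dimnames = list(NULL, c("chl", "ccr", "ewt")))
  forest <- json_to_mat(obj$forest_mask) > 0
  traits <- lapply(obj$traits, json_to_mat)
  structure(list(config = cfg, seed = obj$seed, species_traits = st,
                 patch_map = json_to_mat(obj$patch_map),
                 subregion_map = json_to_mat(obj$subregion_map),
                 forest_mask = forest,
                 polygons = forest_polygons(forest, cfg$pixel_size),
                 traits = traits, truth_fd = NULL,
                 ric01 = json_to_mat(obj$ric01),
                 eve01 = json_to_mat(obj$eve01),
                 region_effects = unlist(obj$region_effects),
                 drop_signal = json_to_mat(obj$drop_signal),
                 ndwi_base = json_to_mat(obj$ndwi_base),
                 year_factors = lapply(obj$year_factors, json_to_mat),
                 dates = scene_dates(cfg)),
            class = "landscape_truth")
}
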
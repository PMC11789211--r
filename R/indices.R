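#' Construct a reflectance scene
#'
#' A scene is one acquisition date's stack of surface-reflectance bands on a
#' common grid. Bands are stored as numeric matrices of reflectance fractions
#' in `[0, 1]`, with `NA` marking nodata. The ten bands used throughout the
#' package are B2, B3, B4, B5, B6, B7, B8, B8A, B11 and B12 (the bands
#' available at 10 or 20 m native resolution on typical decametric
#' multispectral sensors).
#'
#' @param bands Named list of numeric matrices with identical dimensions.
#' @param pixel_size Pixel edge length in meters (default 20).
#' @param date_tag Free-form acquisition label.
#' @return An object of class `rs_scene`.
#' @export
rs_scene <- function(bands, pixel_size = 20, date_tag = "") {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == ""))
    stop_cfg("`bands` must be a named list of matrices")
  d <- dim(bands[[1]])
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || !is.numeric(b)) stop_cfg("band %s is not a numeric matrix", nm)
    if (!identical(dim(b), d)) stop_cfg("band %s has mismatched dimensions", nm)
    rng <- range(b, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      stop_cfg("band %s has reflectance outside [0, 1]", nm)
  }
  structure(list(bands = bands, pixel_size = pixel_size, date_tag = date_tag),
            class = "rs_scene")
}

#' @export
print.rs_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<rs_scene> %s: %d x %d px @ %g m, bands: %s\n",
              if (nzchar(x$date_tag)) x$date_tag else "(untagged)",
              d[1], d[2], x$pixel_size, paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

scene_band <- function(scene, name) {
  if (!name %in% names(scene$bands)) stop_cfg("missing band %s", name)
  scene$bands[[name]]
}

# band pairs per index; first entry is the numerator-side band
.index_bands <- list(
  CIre = c("B7", "B5"),
  CCI  = c("B3", "B4"),
  NDII = c("B8A", "B11"),
  NDWI = c("B8", "B11"),
  NDVI = c("B8A", "B4")
)

#' Compute a spectral vegetation index
#'
#' Implements the five indices used by the pipeline:
#' * `CIre = rho783 / rho704 - 1` (bands B7, B5) — red-edge chlorophyll
#'   index, proxy for canopy chlorophyll content (CHL);
#' * `CCI = (rho560 - rho664) / (rho560 + rho664)` (B3, B4) — proxy for the
#'   carotenoid/chlorophyll ratio (CCR);
#' * `NDII = (rho865 - rho1614) / (rho865 + rho1614)` (B8A, B11) — proxy for
#'   equivalent water thickness (EWT);
#' * `NDWI = (rho833 - rho1614) / (rho833 + rho1614)` (B8, B11) — canopy
#'   water index used for the drought response;
#' * `NDVI` (B8A, B4) — used only for forest masking.
#'
#' Pixels where any input band is nodata, or where the denominator magnitude
#' falls below `1e-9`, are returned as `NA`.
#'
#' @param scene An [rs_scene()].
#' @param index_name One of `"CIre"`, `"CCI"`, `"NDII"`, `"NDWI"`, `"NDVI"`.
#' @return A numeric matrix with attribute `index` set to `index_name`.
#' @export
compute_index <- function(scene, index_name) {
  if (!index_name %in% names(.index_bands))
    stop_cfg("unknown index '%s'", index_name)
  bb <- .index_bands[[index_name]]
  a <- scene_band(scene, bb[1])
  b <- scene_band(scene, bb[2])
  if (index_name == "CIre") {
    den <- b
    out <- a / den - 1
  } else {
    den <- a + b
    out <- (a - b) / den
  }
  out[!is.finite(out) | abs(den) < 1e-9] <- NA_real_
  attr(out, "index") <- index_name
  out
}

#' Rescale a raster to the 0--1 range with percentile tail clipping
#'
#' Linearly maps values between the lower and upper `clip_pct` percentiles to
#' `[0, 1]`; the lowest `clip_pct` percent of values are set to 0 and the
#' highest `clip_pct` percent to 1. Percentiles use the standard
#' linear-interpolation empirical definition (`stats::quantile` type 7). A
#' constant raster maps to 0.5 everywhere: a degenerate range carries no
#' ordering information and 0.5 keeps downstream moving-window statistics
#' well-defined (zero trait dispersion then simply yields zero richness).
#'
#' @param x Numeric matrix or vector; `NA` is passed through.
#' @param clip_pct Percent of each tail to clip (default 0.1).
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
rescale01 <- function(x, clip_pct = 0.1) {
  v <- x[is.finite(x)]
  if (length(v) < 1) stop_cfg("rescale01: no valid values")
  qs <- quantile(v, c(clip_pct / 100, 1 - clip_pct / 100), names = FALSE,
                 type = 7)
  out <- x
  if (qs[2] - qs[1] < 1e-12) {
    out[is.finite(x)] <- 0.5
  } else {
    out <- clamp((x - qs[1]) / (qs[2] - qs[1]), 0, 1)
  }
  attributes(out) <- attributes(x)
  out
}

#' Aggregate a 10 m raster to 20 m by 2x2 block means
#'
#' Each output pixel is the mean of the valid members of its 2x2 input block;
#' the output is nodata only when all four members are nodata (maximal data
#' retention, mirroring multi-date compositing).
#'
#' @param x Numeric matrix with even dimensions.
#' @return Matrix of half the dimensions.
#' @export
resample_mean <- function(x) {
  d <- dim(x)
  if (any(d %% 2 != 0)) stop_cfg("resample_mean: dimensions must be even")
  i <- seq(1, d[1], by = 2)
  j <- seq(1, d[2], by = 2)
  q <- list(x[i, j, drop = FALSE], x[i + 1, j, drop = FALSE],
            x[i, j + 1, drop = FALSE], x[i + 1, j + 1, drop = FALSE])
  s <- matrix(0, length(i), length(j))
  n <- matrix(0L, length(i), length(j))
  for (blk in q) {
    ok <- is.finite(blk)
    s[ok] <- s[ok] + blk[ok]
    n <- n + ok
  }
  out <- s / n
  out[n == 0L] <- NA_real_
  out
}
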
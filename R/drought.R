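#' Median composite of index rasters
#'
#' Per-pixel median across a list of index rasters (e.g. the NDWI of the
#' late-summer acquisitions of one year); a pixel is nodata only when it has
#' no valid observation.
#'
#' @param index_rasters List of numeric matrices on one grid.
#' @param tag Optional label (e.g. the year) stored as an attribute.
#' @return Numeric matrix with attributes `tag` and `n_scenes`.
#' @export
median_composite <- function(index_rasters, tag = NULL) {
  if (length(index_rasters) < 1) stop_cfg("need at least one raster")
  d <- dim(index_rasters[[1]])
  for (r in index_rasters) if (!identical(dim(r), d)) stop_cfg("grid mismatch")
  stack <- simplify2array(index_rasters)
  if (length(index_rasters) == 1) {
    out <- index_rasters[[1]]
  } else if (length(index_rasters) == 3) {
    # vectorized median of three with per-pixel missingness
    a <- index_rasters[[1]]; b <- index_rasters[[2]]; c3 <- index_rasters[[3]]
    cnt <- is.finite(a) + is.finite(b) + is.finite(c3)
    tot <- matrix(0, d[1], d[2])
    for (m in list(a, b, c3)) tot[is.finite(m)] <- tot[is.finite(m)] + m[is.finite(m)]
    out <- tot / cnt                                   # 1 or 2 valid: mean
    med3 <- pmax(pmin(a, b), pmin(pmax(a, b), c3))     # 3 valid: median
    out[cnt == 3] <- med3[cnt == 3]
    out[cnt == 0] <- NA_real_
  } else {
    out <- apply(stack, c(1, 2), function(v) {
      v <- v[is.finite(v)]
      if (length(v)) median(v) else NA_real_
    })
  }
  attr(out, "tag") <- tag
  attr(out, "n_scenes") <- length(index_rasters)
  out
}

#' Fractional change ratio between two rasters
#'
#' `(target - base) / base`, invalid where `|base| < eps` (percent changes of
#' a near-zero index are unstable) or where either input is nodata.
#'
#' @param base,target Numeric matrices on one grid.
#' @param eps Denominator guard (default 1e-3).
#' @return Numeric matrix of dimensionless fractional change (-0.2 = -20%).
#' @export
change_ratio <- function(base, target, eps = 1e-3) {
  if (!same_dim(base, target)) stop_cfg("grid mismatch")
  out <- (target - base) / base
  out[!is.finite(out) | abs(base) < eps] <- NA_real_
  out
}

#' Drought resistance, recovery and resilience maps
#'
#' Given the four yearly late-summer NDWI composites (pre-drought year 1,
#' drought year 2, and post-drought years 3 and 4):
#' * resistance = (NDWI_2 - NDWI_1) / NDWI_1 — immediate change during the
#'   drought;
#' * recovery = (NDWI_3 - NDWI_2) / NDWI_2 — rebound after the drought;
#' * resilience = (NDWI_4 - NDWI_1) / NDWI_1 — net change to the second
#'   post-drought year (avoids a linear combination with recovery).
#'
#' Responses are stored as fractions; render them as percentages only at
#' reporting time.
#'
#' @param yearly List of four yearly NDWI composite matrices, in year order.
#' @param eps Denominator guard passed to [change_ratio()].
#' @return Object of class `drought_response`: list with matrices
#'   `resistance`, `recovery`, `resilience`.
#' @export
drought_responses <- function(yearly, eps = 1e-3) {
  if (length(yearly) != 4) stop_cfg("need exactly 4 yearly composites")
  d <- dim(yearly[[1]])
  for (r in yearly) if (!identical(dim(r), d)) stop_cfg("grid mismatch")
  structure(list(resistance = change_ratio(yearly[[1]], yearly[[2]], eps),
                 recovery = change_ratio(yearly[[2]], yearly[[3]], eps),
                 resilience = change_ratio(yearly[[1]], yearly[[4]], eps),
                 eps = eps),
            class = "drought_response")
}

#' @export
print.drought_response <- function(x, ...) {
  fmt <- function(m) sprintf("%d valid, mean %+.1f%%", n_valid(m),
                             100 * mean(m, na.rm = TRUE))
  cat(sprintf("<drought_response> %d x %d px\n  resistance: %s\n  recovery:   %s\n  resilience: %s\n",
              nrow(x$resistance), ncol(x$resistance), fmt(x$resistance),
              fmt(x$recovery), fmt(x$resilience)))
  invisible(x)
}

#' @rdname tidy.fd_map
#' @export
tidy.drought_response <- function(x, ...) {
  d <- dim(x$resistance)
  tibble::tibble(row = rep(seq_len(d[1]), d[2]),
                 col = rep(seq_len(d[2]), each = d[1]),
                 resistance = as.vector(x$resistance),
                 recovery = as.vector(x$recovery),
                 resilience = as.vector(x$resilience))
}
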
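#' Cloud- and cloud-shadow-free pixel mask
#'
#' A pixel counts as cloud- and shadow-free when its blue reflectance (B2) is
#' strictly below 5% and its NIR reflectance (B8A) strictly above 15%. Clouds
#' are bright in the blue; clouds, their shadows and open water are dark in
#' the NIR. Pixels with nodata in either band are not cloud-free.
#'
#' @param scene An [rs_scene()].
#' @return Logical matrix with attribute `provenance`.
#' @export
cloudfree_mask <- function(scene) {
  b2 <- scene_band(scene, "B2")
  b8a <- scene_band(scene, "B8A")
  m <- !is.na(b2) & !is.na(b8a) & b2 < 0.05 & b8a > 0.15
  attr(m, "provenance") <- "cloudfree: B2 < 0.05 & B8A > 0.15"
  m
}

#' Robust median-outlier threshold
#'
#' Returns `median - c * MAD` (side `"lower"`) or `median + c * MAD` (side
#' `"upper"`), where MAD is the raw median absolute deviation from the median
#' (no consistency constant). Used to flag the dark tail of the NDVI, B6 and
#' B12 distributions when refining the forest mask.
#'
#' @param values Numeric vector; non-finite entries are dropped.
#' @param side `"lower"` or `"upper"`.
#' @param c MAD multiplier (default 3).
#' @return Scalar threshold.
#' @export
median_outlier_threshold <- function(values, side = c("lower", "upper"), c = 3) {
  side <- match.arg(side)
  v <- values[is.finite(values)]
  if (length(v) < 1) stop_cfg("median_outlier_threshold: empty sample")
  med <- median(v)
  mad_raw <- median(abs(v - med))
  if (side == "lower") med - c * mad_raw else med + c * mad_raw
}

#' Build the multi-date forest mask
#'
#' Per scene, a pixel is valid when it is (i) cloud-free ([cloudfree_mask()]),
#' (ii) inside the forest polygons, (iii) above the lower median-outlier NDVI
#' threshold computed within the polygon area (removes gaps, dead canopies),
#' and (iv) not in shadow, i.e. B6 and B12 are each above their lower
#' median-outlier thresholds within the polygon area. The final mask keeps
#' pixels valid in at least `votes` of the scenes (default 2 of 3, applied as
#' mean of the boolean validity layers >= votes/n).
#'
#' @param scenes List of [rs_scene()] objects on one grid (typically 3 early
#'   summer acquisitions).
#' @param polygons Forest polygons as returned by [forest_polygons()] /
#'   [read_forest_geojson()].
#' @param c_ndvi,c_shadow MAD multipliers for the NDVI and shadow thresholds.
#' @param votes Minimum number of scenes in which a pixel must be valid.
#' @return Logical matrix with attributes `provenance` (rules applied),
#'   `thresholds` (per-scene NDVI/B6/B12 thresholds) and `count_valid`.
#' @export
build_forest_mask <- function(scenes, polygons, c_ndvi = 3, c_shadow = 3,
                              votes = 2) {
  if (length(scenes) < 1) stop_cfg("need at least one scene")
  d <- dim(scenes[[1]]$bands[[1]])
  for (s in scenes)
    if (!identical(dim(s$bands[[1]]), d)) stop_cfg("scene grid mismatch")
  inpoly <- rasterize_polygons(polygons, d, scenes[[1]]$pixel_size)
  if (!any(inpoly)) stop_cfg("empty polygon set")
  thresholds <- list()
  votes_sum <- matrix(0L, d[1], d[2])
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    cf <- cloudfree_mask(sc)
    ndvi <- compute_index(sc, "NDVI")
    b6 <- scene_band(sc, "B6")
    b12 <- scene_band(sc, "B12")
    sel <- inpoly & cf
    thr_ndvi <- median_outlier_threshold(ndvi[sel], "lower", c_ndvi)
    thr_b6 <- median_outlier_threshold(b6[sel], "lower", c_shadow)
    thr_b12 <- median_outlier_threshold(b12[sel], "lower", c_shadow)
    # a pixel is excluded when it is strictly below the outlier threshold,
    # so a zero-MAD (constant) distribution excludes nothing
    valid <- cf & inpoly &
      !is.na(ndvi) & ndvi >= thr_ndvi &
      !is.na(b6) & b6 >= thr_b6 &
      !is.na(b12) & b12 >= thr_b12
    votes_sum <- votes_sum + valid
    thresholds[[k]] <- c(ndvi = thr_ndvi, b6 = thr_b6, b12 = thr_b12)
  }
  m <- (votes_sum / length(scenes)) >= (votes / length(scenes)) - 1e-12
  attr(m, "provenance") <- c("cloudfree", "polygon clip", "ndvi median-outlier",
                             "shadow median-outlier (B6, B12)",
                             sprintf("%d-of-%d voting", votes, length(scenes)))
  attr(m, "thresholds") <- thresholds
  attr(m, "count_valid") <- sum(m)
  m
}

#' Remove small forest patches and optionally erode patch edges
#'
#' Diversity metrics computed near forest edges are biased by incomplete
#' moving windows; small isolated patches consist entirely of such pixels.
#' Removes 8-connected components smaller than `min_patch_px` pixels and then
#' erodes the remaining area by `erosion_px` pixels (8-neighborhood). Never
#' adds pixels.
#'
#' @param mask Logical matrix.
#' @param min_patch_px Minimum component area in pixels (default 28, about
#'   one moving-window area).
#' @param erosion_px Number of erosion iterations (default 0).
#' @return Logical matrix with updated `count_valid`.
#' @export
exclude_edge_patches <- function(mask, min_patch_px = 28, erosion_px = 0) {
  if (min_patch_px < 0 || erosion_px < 0) stop_cfg("parameters must be >= 0")
  m <- mask & !is.na(mask)
  if (min_patch_px > 1 && any(m)) {
    lab <- label_components(m)
    keep <- which(tabulate(lab[m]) >= min_patch_px)
    m <- m & matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (erosion_px > 0) for (k in seq_len(erosion_px)) m <- erode_once(m)
  attr(m, "provenance") <- c(attr(mask, "provenance"),
                             sprintf("min_patch_px=%d, erosion_px=%d",
                                     min_patch_px, erosion_px))
  attr(m, "count_valid") <- sum(m)
  m
}

# 8-connected component labelling via igraph.
label_components <- function(m) {
  d <- dim(m)
  idx <- matrix(seq_len(prod(d)), d[1], d[2])
  edges <- list()
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in shifts) {
    i1 <- seq_len(d[1] - abs(s[1]))
    j1 <- if (s[2] >= 0) seq_len(d[2] - s[2]) else seq(1 - s[2], d[2])
    a <- idx[i1, j1, drop = FALSE]
    b <- idx[i1 + s[1], j1 + s[2], drop = FALSE]
    ok <- m[a] & m[b]
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(a[ok], b[ok])
  }
  lab <- matrix(0L, d[1], d[2])
  on_px <- which(m)
  if (length(on_px) == 0) return(lab)
  ed <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(ed), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(on_px),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  lab[as.integer(igraph::V(g)$name)] <- comp$membership
  lab
}

# one 8-neighborhood binary erosion step
erode_once <- function(m) {
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- m
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    out <- out & pad[(2 + di):(d[1] + 1 + di), (2 + dj):(d[2] + 1 + dj)]
  }
  out
}

#' Forest area implied by a pixel count
#'
#' @param count_valid Number of valid pixels.
#' @param pixel_size Pixel edge length in meters.
#' @return Area in square kilometers.
#' @export
mask_area_km2 <- function(count_valid, pixel_size = 20) {
  count_valid * pixel_size^2 / 1e6
}
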
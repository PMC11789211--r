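#' Circular moving-window kernel with area-fraction weights
#'
#' Builds the `(2r+1) x (2r+1)` weight grid of a circular calculation mask:
#' each cell's weight is the fraction of its unit square covered by the circle
#' of radius `radius_px` centered on the center cell's midpoint, estimated by
#' subpixel sampling (`subdiv^2` subcells per pixel). With the default
#' three-pixel radius (60 m at 20 m pixels) the weights sum to about 28.27
#' pixels, i.e. a calculation area of 1.131 ha.
#'
#' @param radius_px Radius in pixels (default 3).
#' @param subdiv Subpixel sampling density per axis (default 100).
#' @return Numeric weight matrix of class `fd_kernel` with attribute
#'   `radius_px`.
#' @export
circular_kernel <- function(radius_px = 3, subdiv = 100) {
  if (radius_px <= 0) stop_cfg("radius_px must be positive")
  r <- ceiling(radius_px)
  offs <- -r:r
  sub <- (seq_len(subdiv) - 0.5) / subdiv - 0.5
  g <- expand.grid(dx = sub, dy = sub)
  w <- outer(offs, offs, Vectorize(function(di, dj) {
    mean((di + g$dx)^2 + (dj + g$dy)^2 <= radius_px^2)
  }))
  structure(w, radius_px = radius_px, class = c("fd_kernel", "matrix", "array"))
}

#' @export
print.fd_kernel <- function(x, ...) {
  cat(sprintf("<fd_kernel> radius %g px, weight sum %.2f px\n",
              attr(x, "radius_px"), sum(x)))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Functional richness of a trait point cloud
#'
#' Volume occupied by a set of points in 3-D trait space. With
#' `alpha = Inf` this is the convex hull volume; a finite `alpha` gives the
#' volume of the alpha complex (union of Delaunay tetrahedra with
#' circumradius at most `alpha`), a concave hull less sensitive to outlying
#' points. Coplanar or otherwise degenerate point sets have zero 3-D measure.
#'
#' @param pts `N x 3` numeric matrix of trait coordinates.
#' @param alpha Alpha parameter; `Inf` (default) for the convex hull.
#' @param min_points Minimum number of points (default 4); below it the
#'   result is `NA` rather than an error.
#' @return Non-negative volume in trait units cubed, or `NA`.
#' @export
functional_richness <- function(pts, alpha = Inf, min_points = 4) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop_cfg("pts must have 3 columns")
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < min_points) return(NA_real_)
  .cpp_alpha_volume(pts, alpha)
}

#' Functional evenness of a trait point cloud
#'
#' Villeger-style FEve: the regularity of point placement (and abundance)
#' along the Euclidean minimum spanning tree of the cloud. For branch `l`
#' joining points `i` and `j`, the weighted evenness is
#' `EW_l = d(i, j) / (w_i + w_j)`; partial weighted evenness is
#' `PEW_l = EW_l / sum(EW)`, and
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Equal abundances cancel, making FEve purely geometric; uniform scaling of
#' all coordinates leaves FEve unchanged. 1 means a perfectly regular tree.
#'
#' @param pts `N x 3` numeric matrix (`N >= 3`).
#' @param weights Positive abundances (default equal).
#' @return Scalar in `[0, 1]`, or `NA` for fewer than 3 points or an
#'   all-coincident cloud.
#' @export
functional_evenness <- function(pts, weights = NULL) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop_cfg("pts must have 3 columns")
  ok <- complete.cases(pts)
  pts <- pts[ok, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(pts)) else weights <- weights[ok]
  if (any(weights <= 0)) stop_cfg("weights must be positive")
  if (nrow(pts) < 3) return(NA_real_)
  .cpp_feve(pts, as.numeric(weights))
}

#' Euclidean minimum spanning tree of a point cloud
#'
#' @param pts `N x 3` numeric matrix.
#' @return Tibble with columns `from`, `to` (1-based indices) and `length`.
#' @export
trait_mst <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop_cfg("pts must have 3 columns")
  tibble::as_tibble(as.data.frame(.cpp_mst(pts)))
}

#' Map functional richness and evenness with a circular moving window
#'
#' For every valid center pixel, gathers the trait triples of the valid
#' pixels under the kernel, then computes functional richness (hull volume)
#' and evenness (MST regularity) of that local cloud. A center is reported
#' only when at least `min_cover` of the total kernel weight falls on valid
#' pixels; richness additionally needs `min_points_ric` points (a 3-D simplex
#' requires four) and evenness `min_points_eve`.
#'
#' @param traits List of three numeric matrices (CHL, CCR, EWT trait layers,
#'   typically rescaled to `[0, 1]`), or a 3-layer array.
#' @param mask Logical matrix of center pixels to evaluate.
#' @param kernel An [circular_kernel()] weight matrix.
#' @param alpha `"convex"` for convex hulls, `"adaptive"` (default) for a
#'   per-window alpha equal to `alpha_mult` times the mean MST branch length,
#'   or a positive number for a fixed alpha.
#' @param alpha_mult Multiplier for the adaptive mode (default 2).
#' @param min_points_ric,min_points_eve Minimum point counts (defaults 4, 3).
#' @param min_cover Minimum fraction of kernel weight on valid pixels
#'   (default 0.5).
#' @param use_kernel_weights Use the kernel area fractions as FEve abundances
#'   (default `TRUE`); `FALSE` gives equal abundances.
#' @return Object of class `fd_map`: list with matrices `fric`, `feve`,
#'   `n_points` plus the parameters used.
#' @export
map_functional_diversity <- function(traits, mask, kernel = circular_kernel(3),
                                     alpha = "adaptive", alpha_mult = 2,
                                     min_points_ric = 4, min_points_eve = 3,
                                     min_cover = 0.5,
                                     use_kernel_weights = TRUE) {
  if (is.array(traits) && length(dim(traits)) == 3)
    traits <- lapply(seq_len(dim(traits)[3]), function(k) traits[, , k])
  if (length(traits) != 3) stop_cfg("need exactly 3 trait layers")
  if (!same_dim(traits[[1]], mask)) stop_cfg("traits and mask grids differ")
  if (is.character(alpha)) {
    alpha <- match.arg(alpha, c("adaptive", "convex"))
    mode <- if (alpha == "convex") 0L else 1L
    apar <- alpha_mult
  } else {
    if (!is.finite(alpha) || alpha <= 0) stop_cfg("fixed alpha must be > 0")
    mode <- 2L
    apar <- alpha
  }
  res <- .cpp_fd_map(traits[[1]], traits[[2]], traits[[3]],
                     mask & !is.na(mask), unclass(kernel), mode, apar,
                     as.integer(min_points_ric), as.integer(min_points_eve),
                     min_cover, isTRUE(use_kernel_weights))
  structure(list(fric = res$fric, feve = res$feve, n_points = res$n_points,
                 radius_px = attr(kernel, "radius_px"),
                 alpha = if (mode == 0L) "convex" else if (mode == 1L)
                   sprintf("adaptive (x%g mean MST edge)", alpha_mult) else apar),
            class = "fd_map")
}

#' @export
print.fd_map <- function(x, ...) {
  cat(sprintf(
    "<fd_map> %d x %d px, radius %g px, alpha: %s\n  fric: %d valid (range %s)\n  feve: %d valid (range %s)\n",
    nrow(x$fric), ncol(x$fric), x$radius_px, format(x$alpha),
    n_valid(x$fric), paste(signif(range(x$fric, na.rm = TRUE), 3), collapse = " .. "),
    n_valid(x$feve), paste(signif(range(x$feve, na.rm = TRUE), 3), collapse = " .. ")))
  invisible(x)
}

#' Turn a map object into a tidy pixel tibble
#'
#' @param x An `fd_map` or `drought_response` object.
#' @param ... Unused.
#' @return Tibble with `row`, `col` and one column per layer.
#' @export
tidy.fd_map <- function(x, ...) {
  d <- dim(x$fric)
  tibble::tibble(row = rep(seq_len(d[1]), d[2]),
                 col = rep(seq_len(d[2]), each = d[1]),
                 fric = as.vector(x$fric), feve = as.vector(x$feve),
                 n_points = as.vector(x$n_points))
}
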
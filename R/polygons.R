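# Forest polygons in grid coordinates (meters). The pixel at (row i, col j)
# has its center at x = (j - 0.5) * pixel_size, y = (i - 0.5) * pixel_size.

#' Build forest polygons from a boolean forest raster
#'
#' Decomposes the forest area into axis-aligned rectangles (row runs merged
#' vertically) whose union covers the forest pixels exactly, so that
#' rasterizing the polygons recovers the input mask.
#'
#' @param mask Logical matrix (TRUE = forest).
#' @param pixel_size Pixel edge length in meters.
#' @return Object of class `forest_polygons`: list of rings, each a matrix of
#'   (x, y) vertices in meters.
#' @export
forest_polygons <- function(mask, pixel_size = 20) {
  d <- dim(mask)
  runs <- list()
  for (i in seq_len(d[1])) {
    r <- rle(as.vector(mask[i, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      runs[[length(runs) + 1]] <- c(i, starts[k], ends[k])
    }
  }
  # merge identical runs on consecutive rows
  rects <- list()
  open <- list()  # key "j1_j2" -> c(i_start, j1, j2, i_last)
  for (run in runs) {
    key <- paste(run[2], run[3], sep = "_")
    o <- open[[key]]
    if (!is.null(o) && o[4] == run[1] - 1) {
      o[4] <- run[1]
      open[[key]] <- o
    } else {
      if (!is.null(o)) rects[[length(rects) + 1]] <- o
      open[[key]] <- c(run[1], run[2], run[3], run[1])
    }
  }
  for (o in open) rects[[length(rects) + 1]] <- o
  rings <- lapply(rects, function(r) {
    x0 <- (r[2] - 1) * pixel_size; x1 <- r[3] * pixel_size
    y0 <- (r[1] - 1) * pixel_size; y1 <- r[4] * pixel_size
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  })
  structure(rings, pixel_size = pixel_size, class = "forest_polygons")
}

#' Rasterize polygons onto a pixel grid
#'
#' Marks a pixel TRUE when its center falls inside any polygon ring
#' (even-odd rule; points on the boundary of the half-open upper edge are
#' excluded, so adjacent rectangles never double-claim a pixel).
#'
#' @param polygons A `forest_polygons` object (list of rings).
#' @param dims Raster dimensions `c(rows, cols)`.
#' @param pixel_size Pixel edge length in meters.
#' @return Logical matrix.
#' @export
rasterize_polygons <- function(polygons, dims, pixel_size = 20) {
  out <- matrix(FALSE, dims[1], dims[2])
  cx <- (seq_len(dims[2]) - 0.5) * pixel_size
  cy <- (seq_len(dims[1]) - 0.5) * pixel_size
  for (ring in polygons) {
    xr <- range(ring[, 1]); yr <- range(ring[, 2])
    jj <- which(cx > xr[1] & cx < xr[2])
    ii <- which(cy > yr[1] & cy < yr[2])
    if (!length(ii) || !length(jj)) next
    for (i in ii) {
      inside <- point_in_ring(cx[jj], cy[i], ring)
      out[i, jj[inside]] <- TRUE
    }
  }
  out
}

# even-odd ray casting for a vector of x at fixed y
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring) - 1  # closed ring
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    crosses <- (y1 > y) != (y2 > y)
    if (any(crosses)) {
      xin <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      inside <- xor(inside, crosses & (x < xin))
    }
  }
  inside
}

#' Write forest polygons to GeoJSON
#'
#' @param polygons A `forest_polygons` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forest_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(ring) {
    list(type = "Feature", properties = list(class = "forest"),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(pixel_size = attr(polygons, "pixel_size")),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read forest polygons from GeoJSON
#'
#' @param path GeoJSON file written by [write_forest_geojson()] (or any
#'   FeatureCollection of simple polygons in grid meters).
#' @return A `forest_polygons` object.
#' @export
read_forest_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  rings <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  })
  structure(rings, pixel_size = obj$properties$pixel_size %||% 20,
            class = "forest_polygons")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
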
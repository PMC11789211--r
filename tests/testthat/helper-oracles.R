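# Independent brute-force oracles, deliberately different algorithms from the
# package internals (facet enumeration vs incremental hull; Kruskal vs Prim).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Convex hull volume by facet enumeration: a triple is a hull facet when all
# remaining points lie on one side of its plane; the hull is star-shaped from
# the centroid, so summing centroid-apex tetrahedra gives the volume.
# Assumes general position (no 4 coplanar hull points).
oracle_hull_volume <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nn <- cross3(P[j, ] - P[i, ], P[k, ] - P[i, ])
    if (sum(nn^2) < 1e-20) next
    d <- as.vector(sweep(P, 2, P[i, ]) %*% nn)
    s <- d[-c(i, j, k)]
    if (all(s <= 1e-12) || all(s >= -1e-12)) {
      vol <- vol + abs(det(rbind(P[i, ] - ctr, P[j, ] - ctr, P[k, ] - ctr))) / 6
    }
  }
  vol
}

# MST by Kruskal over the full edge list with union-find.
oracle_mst_edges <- function(P) {
  n <- nrow(P)
  ed <- t(combn(n, 2))
  len <- sqrt(rowSums((P[ed[, 1], , drop = FALSE] -
                         P[ed[, 2], , drop = FALSE])^2))
  o <- order(len)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- integer(0)
  for (e in o) {
    a <- find(ed[e, 1]); b <- find(ed[e, 2])
    if (a != b) { parent[a] <- b; keep <- c(keep, e) }
    if (length(keep) == n - 1) break
  }
  cbind(ed[keep, , drop = FALSE], len[keep])
}

oracle_feve <- function(P, w = rep(1, nrow(P))) {
  S <- nrow(P)
  ed <- oracle_mst_edges(P)
  ew <- ed[, 3] / (w[ed[, 1]] + w[ed[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# a flat-band scene for index arithmetic tests
make_scene <- function(..., nr = 4, nc = 4) {
  vals <- list(...)
  defaults <- list(B2 = 0.02, B3 = 0.1, B4 = 0.06, B5 = 0.08, B6 = 0.25,
                   B7 = 0.1, B8 = 0.4, B8A = 0.4, B11 = 0.12, B12 = 0.15)
  bands <- lapply(modifyList(defaults, vals), function(v)
    if (is.matrix(v)) v else matrix(v, nr, nc))
  rs_scene(bands)
}

# study conditions with every stochastic element switched off
noiseless_config <- function(...) {
  landscape_config(noise_sd_reflectance = 0, noise_sd_ndwi = 0,
                   noise_sd_response = 0, cloud_fraction = 0,
                   shadow_fraction = 0, ...)
}
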
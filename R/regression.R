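#' Equal-range bin index of values on the unit interval
#'
#' Bin `i` (1-based) covers the half-open interval `[(i-1)/n, i/n)`; the last
#' bin is closed at 1. Values are expected rescaled to `[0, 1]` (see
#' [rescale01()]); tiny numerical excursions are clamped.
#'
#' @param values Numeric vector (NA allowed).
#' @param n_bins Number of bins (>= 2).
#' @return Integer vector of bin ids in `1..n_bins` (NA where input is NA).
#' @export
equal_range_bins <- function(values, n_bins) {
  if (n_bins < 2) stop_cfg("n_bins must be >= 2")
  if (!any(is.finite(values))) stop_cfg("no finite values to bin")
  v <- clamp(values, 0, 1)
  id <- pmin(floor(v * n_bins), n_bins - 1L) + 1L
  as.integer(id)
}

bin_mid <- function(bin, n_bins) (bin - 0.5) / n_bins

#' Binned diversity--response series
#'
#' Discretizes a rescaled diversity metric into `n_bins` equal-range bins and
#' averages the drought response within each bin; the per-bin pixel count `N`
#' becomes the regression weight downstream. Averaging over the whole map
#' mixes distant pixels with similar diversity into one bin, which damps
#' spatial autocorrelation.
#'
#' @param diversity Numeric vector or matrix of the rescaled metric.
#' @param response Numeric vector or matrix of the drought response.
#' @param n_bins Number of bins (default 1000).
#' @return Tibble of class `bef_bins` with `bin`, `mid`, `n`, `mean_response`.
#' @export
binned_series <- function(diversity, response, n_bins = 1000) {
  x <- as.vector(diversity)
  y <- as.vector(response)
  if (length(x) != length(y)) stop_cfg("diversity/response length mismatch")
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop_cfg("no jointly valid pixels")
  bins <- equal_range_bins(x[ok], n_bins)
  out <- tibble::tibble(bin = bins, y = y[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), mean_response = mean(.data$y),
                     .groups = "drop") |>
    dplyr::mutate(mid = bin_mid(.data$bin, n_bins), .after = "bin")
  attr(out, "n_bins") <- n_bins
  class(out) <- c("bef_bins", class(out))
  out
}

#' Drop sparsely populated bins
#'
#' Removes bins holding fewer than `min_frac` of the maximum per-bin pixel
#' count; a bin exactly at the threshold is kept. Such bins carry unstable
#' means from the thin tails of the diversity distribution.
#'
#' @param series A [binned_series()] tibble.
#' @param min_frac Fraction of the maximum bin count (default 0.01).
#' @return Filtered series; attributes `n_kept` and `value_range` report the
#'   surviving bin count and their diversity range.
#' @export
filter_small_bins <- function(series, min_frac = 0.01) {
  thr <- min_frac * max(series$n)
  out <- dplyr::filter(series, .data$n >= thr)
  attr(out, "n_bins") <- attr(series, "n_bins")
  attr(out, "n_kept") <- nrow(out)
  attr(out, "value_range") <- range(out$mid)
  class(out) <- unique(c("bef_bins", class(out)))
  out
}

# AIC treating the regression weights as frequency (pixel-count) weights.
# The RSS is floored just above numerical zero so that an essentially
# perfect fit does not reward extra parameters through rounding noise; the
# parameter penalty then decides among exact fits.
aic_frequency <- function(fit) {
  w <- fit$weights %||% rep(1, length(resid(fit)))
  W <- sum(w)
  y <- fit$model[[1]]
  rss <- max(sum(w * resid(fit)^2), 1e-25 * sum(w * y^2), 1e-300)
  k <- sum(!is.na(coef(fit))) + 1
  W * (log(2 * pi * rss / W) + 1) + 2 * k
}

#' Weighted univariate fit with AIC model-form selection
#'
#' Fits the binned mean response on the bin-center diversity value by
#' weighted least squares (weights = per-bin pixel counts, treated as
#' frequency weights) for each candidate form — linear `y ~ x`, quadratic
#' `y ~ x + x^2`, logarithmic `y ~ log(x + offset)` — and selects the form
#' with the lowest frequency-weighted AIC. The logarithmic form is skipped
#' with a warning when `x + offset` is not strictly positive.
#'
#' @param series A [binned_series()] (after [filter_small_bins()]).
#' @param forms Candidate forms (default all three).
#' @param log_offset Offset added inside the logarithm (default 0; bin
#'   centers of a 0--1 metric are strictly positive).
#' @return Object of class `bef_unifit`: list with the chosen form, per-form
#'   fits, AIC and r-squared.
#' @export
fit_univariate <- function(series,
                           forms = c("linear", "quadratic", "logarithmic"),
                           log_offset = 0) {
  if (nrow(series) < 3) stop_cfg("need at least 3 surviving bins")
  d <- data.frame(x = series$mid, y = series$mean_response, N = series$n)
  fits <- list()
  for (f in forms) {
    if (f == "logarithmic" && any(d$x + log_offset <= 0)) {
      warning("logarithmic form skipped: non-positive predictor values")
      next
    }
    fml <- switch(f,
                  linear = y ~ x,
                  quadratic = y ~ x + I(x^2),
                  logarithmic = y ~ log(x + log_offset))
    fits[[f]] <- lm(fml, data = d, weights = N)
  }
  if (!length(fits)) stop_cfg("no candidate form could be fitted")
  aic <- vapply(fits, aic_frequency, numeric(1))
  r2 <- vapply(fits, function(m) {
    w <- m$weights
    y <- m$model[[1]]
    1 - sum(w * resid(m)^2) / sum(w * (y - weighted.mean(y, w))^2)
  }, numeric(1))
  chosen <- names(which.min(aic))
  structure(list(chosen = chosen, fits = fits, aic = aic, r2 = r2,
                 n_bins_used = nrow(series), log_offset = log_offset),
            class = "bef_unifit")
}

#' @export
print.bef_unifit <- function(x, ...) {
  cat(sprintf("<bef_unifit> chosen form: %s (over %d bins)\n", x$chosen,
              x$n_bins_used))
  for (f in names(x$fits))
    cat(sprintf("  %-12s AIC %10.2f  r2 %.4f\n", f, x$aic[f], x$r2[f]))
  invisible(x)
}

#' @export
tidy.bef_unifit <- function(x, ...) {
  fit <- x$fits[[x$chosen]]
  s <- summary(fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.bef_unifit <- function(x, ...) {
  tibble::tibble(chosen = x$chosen, r.squared = unname(x$r2[x$chosen]),
                 AIC = unname(x$aic[x$chosen]), n_bins = x$n_bins_used)
}

#' Stratify response maps by diversity bins and subregion
#'
#' Crosses `n_bins` equal-range richness bins, `n_bins` evenness bins and the
#' `K` subregions into `n_bins * n_bins * K` strata; for each stratum,
#' averages each drought response and counts the contributing pixels `N`.
#' Empty strata are retained as rows with `N = 0` for accounting and are
#' excluded from fitting.
#'
#' @param ric,eve Rescaled (0--1) richness and evenness rasters (or vectors).
#' @param region Integer subregion raster/vector (labels `1..K`).
#' @param responses Named list of response rasters (e.g. `rst`, `rcv`, `rsl`).
#' @param n_bins Bins per diversity metric (default 20).
#' @return Tibble of class `bef_strata`: `ric_bin`, `eve_bin`, `region`,
#'   `ric_mid`, `eve_mid`, one `mean_<name>` per response, and `N`.
#' @export
stratified_table <- function(ric, eve, region, responses, n_bins = 20) {
  x <- as.vector(ric); e <- as.vector(eve); g <- as.vector(region)
  if (length(x) != length(e) || length(x) != length(g))
    stop_cfg("input grids differ")
  if (!length(stats::na.omit(unique(g[g != 0]))))
    stop_cfg("region map has no labels")
  resp <- lapply(responses, as.vector)
  ok <- is.finite(x) & is.finite(e) & is.finite(g) & g > 0
  for (r in resp) ok <- ok & is.finite(r)
  K <- max(g[ok])
  d <- tibble::tibble(ric_bin = equal_range_bins(x[ok], n_bins),
                      eve_bin = equal_range_bins(e[ok], n_bins),
                      region = as.integer(g[ok]))
  for (nm in names(resp)) d[[paste0("mean_", nm)]] <- resp[[nm]][ok]
  out <- d |>
    dplyr::group_by(.data$ric_bin, .data$eve_bin, .data$region) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("mean_"), mean),
                     N = dplyr::n(), .groups = "drop") |>
    tidyr::complete(ric_bin = seq_len(n_bins), eve_bin = seq_len(n_bins),
                    region = seq_len(K), fill = list(N = 0L)) |>
    dplyr::mutate(ric_mid = bin_mid(.data$ric_bin, n_bins),
                  eve_mid = bin_mid(.data$eve_bin, n_bins),
                  .after = "region")
  attr(out, "n_bins") <- n_bins
  attr(out, "K") <- K
  class(out) <- c("bef_strata", class(out))
  out
}

# model frame shared by fit_combined / region_correct
strata_model_frame <- function(table, response, log_offset = NULL) {
  col <- paste0("mean_", response)
  if (!col %in% names(table)) stop_cfg("response %s not in table", response)
  n_bins <- attr(table, "n_bins") %||% max(table$ric_bin)
  if (is.null(log_offset)) log_offset <- 0.5 / n_bins  # half a bin width
  d <- table[table$N > 0, ]
  data.frame(y = d[[col]],
             ric = d$ric_mid, eve = d$eve_mid,
             logric = log(d$ric_mid + log_offset), eve2 = d$eve_mid^2,
             REG = factor(d$region), N = d$N)
}

default_terms <- function(response) {
  switch(response,
         rst = ,
         rcv = c("logric", "eve", "eve2", "REG",
                 "logric:REG", "eve:REG", "eve2:REG"),
         rsl = c("ric", "eve", "REG", "ric:REG", "eve:REG"),
         stop_cfg("no default term order for response '%s'", response))
}

#' Weighted sequential-SS model of a stratified table
#'
#' Fits the stratum-mean drought response on continuous bin-center diversity
#' values, the subregion factor and their interactions, by weighted least
#' squares with the pixel counts `N` as weights, entering terms in a fixed
#' order (sequential / Type-I sums of squares). Default term orders:
#' * resistance (`rst`) and recovery (`rcv`):
#'   `logric + eve + eve2 + REG + logric:REG + eve:REG + eve2:REG`
#' * resilience (`rsl`): `ric + eve + REG + ric:REG + eve:REG`
#'
#' The richness bin center of the first bin can be arbitrarily close to 0, so
#' the logarithm is taken of `ric + log_offset` with a default offset of half
#' a bin width. Each term's share of the total sum of squares is its
#' increment of multiple r-squared.
#'
#' @param table A [stratified_table()].
#' @param response `"rst"`, `"rcv"` or `"rsl"` (a `mean_<response>` column).
#' @param terms Character vector overriding the default term order.
#' @param log_offset Offset inside `log(ric + offset)`.
#' @return Object of class `bef_anova`: the fitted `lm`, the sequential
#'   ANOVA tibble (`term`, `df`, `ss`, `ms`, `f`, `p`, `r2_increment`) and
#'   bookkeeping fields.
#' @export
fit_combined <- function(table, response, terms = NULL, log_offset = NULL) {
  d <- strata_model_frame(table, response, log_offset)
  if (nrow(d) < 2) stop_cfg("need at least 2 nonempty strata")
  if (is.null(terms)) terms <- default_terms(response)
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- lm(stats::terms(fml, keep.order = TRUE), data = d, weights = N)
  an <- anova(fit)
  tot_ss <- sum(an$`Sum Sq`)
  tb <- tibble::tibble(term = rownames(an), df = an$Df, ss = an$`Sum Sq`,
                       ms = an$`Mean Sq`, f = an$`F value`,
                       p = an$`Pr(>F)`, r2_increment = an$`Sum Sq` / tot_ss)
  rank_deficient <- anyNA(coef(fit))
  if (rank_deficient)
    tb$note <- ifelse(tb$term %in% all_aliased_terms(fit),
                      "SS on estimable subspace", NA_character_)
  structure(list(fit = fit, table = tb, response = response,
                 terms = terms, total_ss = tot_ss,
                 r_squared = sum(tb$r2_increment[tb$term != "Residuals"]),
                 rank_deficient = rank_deficient),
            class = "bef_anova")
}

all_aliased_terms <- function(fit) {
  nas <- names(coef(fit))[is.na(coef(fit))]
  asg <- attr(fit$qr$qr, "assign") %||% fit$assign
  labs <- attr(terms(fit), "term.labels")
  unique(labs[asg[match(nas, colnames(model.matrix(fit)))]])
}

#' @export
print.bef_anova <- function(x, ...) {
  cat(sprintf("<bef_anova> response: %s, r2 = %.4f%s\n", x$response,
              x$r_squared, if (x$rank_deficient) " (rank deficient)" else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.bef_anova <- function(x, ...) x$table

#' @export
glance.bef_anova <- function(x, ...) {
  res <- x$table[x$table$term == "Residuals", ]
  tibble::tibble(response = x$response, r.squared = x$r_squared,
                 total_ss = x$total_ss, df.residual = res$df,
                 n_strata = length(resid(x$fit)))
}

#' Conservative F-ratios against diversity-by-region interactions
#'
#' For each diversity main-effect term whose interaction with the subregion
#' factor is in the model, computes `F2 = MS(term) / MS(term:REG)` with the
#' interaction degrees of freedom in the denominator. Testing a diversity
#' effect against how much it varies between subregions (rather than against
#' the residual) corresponds to treating the interaction as a random term
#' and is the more conservative test of a generalizable effect.
#'
#' @param anova A [fit_combined()] result.
#' @return The same object with `f2`, `df2` and `p2` columns added for terms
#'   that have a matching interaction.
#' @export
conservative_f <- function(anova) {
  tb <- anova$table
  tb$f2 <- NA_real_; tb$df2 <- NA_real_; tb$p2 <- NA_real_
  main <- tb$term[!grepl(":", tb$term) & tb$term != "Residuals" &
                    tb$term != "REG"]
  found <- FALSE
  for (tm in main) {
    inter <- paste0(tm, ":REG")
    k <- match(inter, tb$term)
    if (is.na(k)) next
    found <- TRUE
    i <- match(tm, tb$term)
    tb$f2[i] <- tb$ms[i] / tb$ms[k]
    tb$df2[i] <- tb$df[k]
    tb$p2[i] <- pf(tb$f2[i], tb$df[i], tb$df[k], lower.tail = FALSE)
  }
  if (!found) stop_cfg("no diversity-by-region interaction term in the model")
  anova$table <- tb
  anova
}

#' Subregion-corrected response values
#'
#' Removes between-subregion differences for plotting: fits the response on
#' the subregion factor alone (weighted by `N`) and returns the residuals
#' plus the weighted grand mean. The corrected values have equal weighted
#' means across subregions, and their overall weighted mean equals the grand
#' mean.
#'
#' @param table A [stratified_table()].
#' @param response Response name as in [fit_combined()].
#' @return The nonempty rows of `table` with a `corrected` column added.
#' @export
region_correct <- function(table, response) {
  col <- paste0("mean_", response)
  d <- table[table$N > 0, ]
  gm <- weighted.mean(d[[col]], d$N)
  if (length(unique(d$region)) > 1) {
    fit <- lm(d[[col]] ~ factor(d$region), weights = d$N)
    d$corrected <- resid(fit) + gm
  } else {
    d$corrected <- d[[col]]
  }
  d
}

#' Published cantonal reference areas of the study region
#'
#' Total and forested areas of the two administrative regions of the original
#' study area (northern Switzerland), as published by the cantonal
#' authorities; the forest share in percent is recomputed from the two areas.
#'
#' @return Tibble with `canton`, `total_km2`, `forest_km2`, `forest_share_pct`.
#' @export
study_area_reference <- function() {
  tibble::tibble(canton = c("Aargau", "Zurich"),
                 total_km2 = c(1403.80, 1728.87),
                 forest_km2 = c(490.70, 503.73)) |>
    dplyr::mutate(forest_share_pct = 100 * .data$forest_km2 / .data$total_km2)
}
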
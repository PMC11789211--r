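test_that("equal-range bins use half-open intervals with a closed last bin", {
  expect_equal(equal_range_bins(c(0.25, 0.75, 1.0, 0), n_bins = 2),
               c(1L, 2L, 2L, 1L))
  expect_equal(equal_range_bins(0.5, 2), 2L)  # 0.5 belongs to [0.5, 1]
  set.seed(14)
  v <- runif(60000)
  b <- equal_range_bins(v, 1000)
  counts <- tabulate(b, 1000)
  expect_lt(max(abs(counts - 60)), 6 * sqrt(60))  # uniform law
  expect_error(equal_range_bins(numeric(0), 10), "finite")
})

test_that("binned series average the response and count pixels per bin", {
  d <- binned_series(c(0.1, 0.12, 0.9, NA), c(1, 3, 5, 7), n_bins = 10)
  expect_equal(nrow(d), 2)
  expect_equal(d$n, c(2L, 1L))
  expect_equal(d$mean_response, c(2, 5))
  expect_equal(d$mid, c(0.15, 0.95))
  one <- binned_series(rep(0.35, 5), 1:5, n_bins = 10)
  expect_equal(nrow(one), 1)   # all values in a single bin
})

test_that("small-bin exclusion keeps bins at exactly 1% of the maximum", {
  s <- tibble::tibble(bin = 1:3, mid = c(0.1, 0.5, 0.9), n = c(1000L, 10L, 9L),
                      mean_response = c(1, 2, 3))
  attr(s, "n_bins") <- 10
  f <- filter_small_bins(s, 0.01)
  expect_equal(f$bin, c(1L, 2L))   # n = 10 kept (boundary), n = 9 dropped
  expect_equal(attr(f, "n_kept"), 2L)
  expect_equal(nrow(filter_small_bins(s, 0)), 3)  # no-op threshold
})

test_that("univariate selection finds exact and noisy functional forms", {
  s <- tibble::tibble(bin = 1:50, mid = (1:50 - 0.5) / 50, n = rep(20L, 50))
  s$mean_response <- 2 * s$mid + 1
  fit <- fit_univariate(s)
  expect_equal(fit$chosen, "linear")
  expect_equal(unname(fit$r2["linear"]), 1)
  expect_equal(unname(coef(fit$fits$linear)), c(1, 2), tolerance = 1e-10)
  # equal weights reproduce the unweighted fit
  uw <- lm(mean_response ~ mid, data = s)
  expect_equal(unname(coef(fit$fits$linear)), unname(coef(uw)))
  # logarithmic data is identified in the clear majority of replicates
  set.seed(99)
  wins <- 0
  for (r in 1:100) {
    sl <- tibble::tibble(bin = 1:800, mid = (1:800 - 0.5) / 800,
                         n = rep(10L, 800))
    sl$mean_response <- 0.5 + 1.0 * log(sl$mid) + rnorm(800, 0, 0.4)
    if (fit_univariate(sl)$chosen == "logarithmic") wins <- wins + 1
  }
  expect_gt(wins, 50)
})

test_that("the log form is skipped, with a warning, for non-positive predictors", {
  s <- tibble::tibble(bin = 1:5, mid = c(-0.1, 0.2, 0.4, 0.6, 0.8),
                      n = rep(5L, 5), mean_response = 1:5)
  expect_warning(fit <- fit_univariate(s), "non-positive")
  expect_false("logarithmic" %in% names(fit$fits))
})

sim_strata <- function(seed, K = 4, n_bins = 8, beta_ric = 0, beta_eve = 0,
                       sd = 0.05, region_sd = 0, slope_by_region = 0) {
  set.seed(seed)
  g <- tidyr::expand_grid(ric_bin = seq_len(n_bins), eve_bin = seq_len(n_bins),
                          region = seq_len(K))
  g$ric_mid <- (g$ric_bin - 0.5) / n_bins
  g$eve_mid <- (g$eve_bin - 0.5) / n_bins
  g$N <- rpois(nrow(g), 30) + 1L
  reg_eff <- rnorm(K, 0, region_sd)
  reg_slope <- rnorm(K, 0, slope_by_region)
  mu <- beta_ric * g$ric_mid + beta_eve * g$eve_mid + reg_eff[g$region] +
    reg_slope[g$region] * g$ric_mid
  g$mean_rst <- mu + rnorm(nrow(g), 0, sd / sqrt(g$N))
  g$mean_rsl <- g$mean_rst
  attr(g, "n_bins") <- n_bins
  attr(g, "K") <- K
  class(g) <- c("bef_strata", class(g))
  g
}

test_that("stratification produces the full bins-by-bins-by-region grid", {
  set.seed(4)
  n <- 5000
  ric <- runif(n); eve <- runif(n); reg <- sample(1:21, n, replace = TRUE)
  resp <- list(rst = rnorm(n))
  tb <- stratified_table(ric, eve, reg, resp, n_bins = 20)
  expect_equal(nrow(tb), 8400)                  # 20 x 20 x 21
  expect_equal(sum(tb$N), n)
  tb2 <- stratified_table(runif(50), runif(50), rep(1, 50),
                          list(rst = rnorm(50)), n_bins = 2)
  expect_equal(nrow(tb2), 4)
  # a single-pixel stratum carries that pixel's value
  tb3 <- stratified_table(0.05, 0.05, 1, list(rst = 0.37), n_bins = 2)
  expect_equal(tb3$mean_rst[tb3$N == 1], 0.37)
})

test_that("sequential SS decomposition is additive and order changes only the split", {
  tb <- sim_strata(1, beta_ric = 0.2, beta_eve = -0.1, region_sd = 0.05)
  a1 <- fit_combined(tb, "rst", terms = c("ric", "eve", "REG"))
  a2 <- fit_combined(tb, "rst", terms = c("REG", "eve", "ric"))
  expect_equal(sum(a1$table$ss), sum(a2$table$ss), tolerance = 1e-10)
  expect_equal(a1$r_squared, sum(a1$table$r2_increment[a1$table$term != "Residuals"]))
  # total SS equals the weighted corrected total
  d <- tb[tb$N > 0, ]
  tot <- sum(d$N * (d$mean_rst - weighted.mean(d$mean_rst, d$N))^2)
  expect_equal(a1$total_ss, tot, tolerance = 1e-8)
})

test_that("orthogonal balanced designs give order-invariant term SS", {
  g <- tidyr::expand_grid(ric_bin = 1:6, eve_bin = 1:6, region = 1:3)
  g$ric_mid <- (g$ric_bin - 0.5) / 6; g$eve_mid <- (g$eve_bin - 0.5) / 6
  g$N <- 10L
  set.seed(2)
  g$mean_rst <- 0.3 * g$ric_mid - 0.2 * g$eve_mid + rnorm(nrow(g), 0, 0.1)
  attr(g, "n_bins") <- 6; class(g) <- c("bef_strata", class(g))
  a1 <- fit_combined(g, "rst", terms = c("ric", "eve", "REG"))
  a2 <- fit_combined(g, "rst", terms = c("eve", "REG", "ric"))
  for (tm in c("ric", "eve", "REG"))
    expect_equal(a1$table$ss[a1$table$term == tm],
                 a2$table$ss[a2$table$term == tm], tolerance = 1e-10)
})

test_that("a known richness slope is recovered within two standard errors", {
  hits <- 0
  for (s in 1:20) {
    tb <- sim_strata(s, beta_ric = 0.2, sd = 0.2)
    fit <- fit_combined(tb, "rsl", terms = c("ric", "eve", "REG"))
    cf <- summary(fit$fit)$coefficients
    if (abs(cf["ric", 1] - 0.2) <= 2 * cf["ric", 2]) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% nominal coverage
})

test_that("pure-noise responses yield near-zero r2 and nominal type-I error", {
  rej <- 0; r2 <- numeric(200)
  for (s in 1:200) {
    tb <- sim_strata(s, beta_ric = 0, sd = 0.2)
    fit <- fit_combined(tb, "rst", terms = c("ric", "eve", "REG"))
    p <- fit$table$p[fit$table$term == "ric"]
    if (p < 0.05) rej <- rej + 1
    r2[s] <- fit$r_squared
  }
  expect_lt(rej / 200, 0.10)       # ~5% nominal
  expect_gt(rej, 0)
  expect_lt(median(r2), 0.1)
})

test_that("conservative F tests terms against their region interaction", {
  tb <- sim_strata(3, beta_ric = 0.2, region_sd = 0.05, slope_by_region = 0.1)
  fit <- conservative_f(fit_combined(tb, "rsl"))
  t_ric <- fit$table[fit$table$term == "ric", ]
  t_int <- fit$table[fit$table$term == "ric:REG", ]
  expect_equal(t_ric$f2, t_ric$ms / t_int$ms)
  expect_equal(t_ric$df2, t_int$df)
  expect_equal(t_ric$p2, pf(t_ric$f2, t_ric$df, t_int$df, lower.tail = FALSE))
  expect_error(conservative_f(fit_combined(tb, "rst",
                                           terms = c("logric", "eve", "REG"))),
               "interaction")
  # truly region-varying slopes deflate F2 below F on average
  rel <- numeric(100)
  for (s in 1:100) {
    tbv <- sim_strata(s + 500, beta_ric = 0.3, slope_by_region = 0.15,
                      sd = 0.15)
    f <- conservative_f(fit_combined(tbv, "rsl"))
    r <- f$table[f$table$term == "ric", ]
    rel[s] <- r$f2 / r$f
  }
  expect_lt(mean(rel), 1)
})

test_that("subregion correction recenters regions on the weighted grand mean", {
  tb <- sim_strata(6, beta_ric = 0.1, region_sd = 0.2)
  cor1 <- region_correct(tb, "rst")
  gm <- weighted.mean(tb$mean_rst[tb$N > 0], tb$N[tb$N > 0])
  expect_equal(weighted.mean(cor1$corrected, cor1$N), gm, tolerance = 1e-10)
  by_reg <- tapply(seq_len(nrow(cor1)), cor1$region, function(i)
    weighted.mean(cor1$corrected[i], cor1$N[i]))
  expect_lt(max(abs(by_reg - gm)), 1e-8)     # equal weighted region means
  # K = 1 leaves values untouched
  tb1 <- sim_strata(7, K = 1)
  cor2 <- region_correct(tb1, "rst")
  expect_equal(cor2$corrected, cor2$mean_rst)
})

test_that("fitting stratum means with N weights equals fitting all pixels", {
  set.seed(30)
  n <- 2000
  ric <- runif(n); eve <- runif(n); reg <- sample(1:3, n, replace = TRUE)
  n_bins <- 5
  rb <- equal_range_bins(ric, n_bins); eb <- equal_range_bins(eve, n_bins)
  ric_mid <- (rb - 0.5) / n_bins; eve_mid <- (eb - 0.5) / n_bins
  y <- 0.4 * ric_mid - 0.2 * eve_mid + 0.1 * (reg == 2) + rnorm(n, 0, 0.1)
  tb <- stratified_table(ric, eve, reg, list(rst = y), n_bins = n_bins)
  fit_binned <- fit_combined(tb, "rst", terms = c("ric", "eve", "REG"))
  fit_pixel <- lm(y ~ ric_mid + eve_mid + factor(reg))
  expect_equal(unname(coef(fit_binned$fit)), unname(coef(fit_pixel)),
               tolerance = 1e-10)
})

test_that("published cantonal areas reproduce the printed forest shares", {
  ref <- study_area_reference()
  expect_equal(round(ref$forest_share_pct[ref$canton == "Aargau"]), 35)
  expect_equal(round(ref$forest_share_pct[ref$canton == "Zurich"], 1), 29.1)
})
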
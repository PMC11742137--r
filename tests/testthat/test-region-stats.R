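test_that("region summaries compute the stated arithmetic", {
  data <- array(c(0, 0, 2, 6), c(2, 2, 1))
  map <- elemental_map(data, channel_names = "Zn66", pixel_size_um = 5)
  lmap <- region_label_map(matrix(1L, 2, 2), c(`1` = "Tumor"), 5, "elemental")
  rec <- summarize_regions(map, lmap)
  expect_identical(rec$n_pixels, 4L)
  expect_identical(rec$n_nonzero, 2L)
  expect_identical(rec$detect_frac, 0.5)
  expect_identical(rec$mean, 2)
  expect_identical(rec$mean_positive, 4)
})

test_that("fully-missing regions emit no record; missing pixels never count", {
  data <- array(c(NA, NA, 3, 5), c(2, 2, 1))
  map <- elemental_map(data, channel_names = "A", pixel_size_um = 5)
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  lmap <- region_label_map(labels, c(`1` = "gone", `2` = "there"), 5, "elemental")
  rec <- summarize_regions(map, lmap)
  expect_identical(rec$region_label, "there")
  expect_identical(rec$n_pixels, 2L)
})

test_that("mismatched shapes or frames are rejected", {
  map <- elemental_map(array(1, c(2, 2, 1)), channel_names = "A", pixel_size_um = 5)
  lmap <- region_label_map(matrix(1L, 3, 3), c(`1` = "x"), 5, "elemental")
  expect_error(summarize_regions(map, lmap), class = "elemap_shape_mismatch")
  lmap2 <- region_label_map(matrix(1L, 2, 2), c(`1` = "x"), 5, "other")
  expect_error(summarize_regions(map, lmap2), class = "elemap_frame_mismatch")
})

test_that("summaries equal the per-pixel loop oracle on random fixtures", {
  for (seed in 1:12) {
    rl <- random_map_and_labels(seed)
    got <- summarize_regions(rl$map, rl$labels)
    got <- got[order(got$element, got$region_label), ]
    want <- oracle_summarize(rl$map, rl$labels)
    expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
  }
})

test_that("intercept-only fits match the closed forms", {
  set.seed(60)
  # exactly 50% zeros -> logit intercept log(0.5/0.5) = 0
  v <- c(rep(0, 25), stats::rgamma(25, 2, 0.5))
  fit <- fit_hurdle_gamma(v)
  expect_equal(unname(fit$logit_coef), 0, tolerance = 1e-9)
  # general zero fraction: logit = log(p/(1-p))
  v2 <- c(rep(0, 30), stats::rgamma(70, 2, 0.5))
  fit2 <- fit_hurdle_gamma(v2)
  expect_equal(unname(fit2$logit_coef), log(0.7 / 0.3), tolerance = 1e-9)
  # log-link intercept-only gamma mean = sample mean of positives
  pos <- v2[v2 > 0]
  expect_equal(unname(fit2$gamma_coef), log(mean(pos)), tolerance = 1e-9)
  # positives all equal to c -> intercept log c
  v3 <- c(rep(0, 10), rep(7.5, 20))
  fit3 <- fit_hurdle_gamma(v3)
  expect_equal(unname(fit3$gamma_coef), log(7.5), tolerance = 1e-9)
})

test_that("degenerate inputs set flags instead of failing", {
  expect_error(fit_hurdle_gamma(c(-1, rep(1, 10))), class = "elemap_domain_error")
  expect_error(fit_hurdle_gamma(rep(1, 5)), class = "elemap_domain_error")
  all_pos <- fit_hurdle_gamma(stats::rgamma(20, 2, 1) + 0.1)
  expect_true("logit" %in% all_pos$degenerate)
  expect_false(all_pos$converged)
  all_zero <- fit_hurdle_gamma(rep(0, 20))
  expect_true(all(c("logit", "gamma") %in% all_zero$degenerate))
})

test_that("simulation at n = 5000 recovers all three parameters within 3 SE", {
  set.seed(11)
  n <- 5000
  z <- stats::rbinom(n, 1, 0.7)                   # P(zero) = 0.3
  y <- ifelse(z == 1, stats::rgamma(n, shape = 2, scale = 5 / 2), 0)
  fit <- fit_hurdle_gamma(y)
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$logit_coef) - log(0.7 / 0.3)), 3 * unname(fit$logit_se))
  expect_lt(abs(unname(fit$gamma_coef) - log(5)), 3 * unname(fit$gamma_se))
  expect_lt(abs(fit$shape - 2), 3 * fit$shape_se)

  # loglik equals a direct evaluation of the hurdle density at the fit
  p_hat <- stats::plogis(unname(fit$logit_coef))
  mu_hat <- exp(unname(fit$gamma_coef))
  ll <- oracle_hurdle_loglik(y, rep(p_hat, n), rep(mu_hat, n), fit$shape)
  expect_equal(fit$loglik, ll, tolerance = 1e-6)

  # independent shape estimate (MASS) agrees closely
  gl <- stats::glm(y[y > 0] ~ 1, family = stats::Gamma(link = "log"))
  expect_equal(fit$shape, unname(MASS::gamma.shape(gl)$alpha), tolerance = 1e-4)
})

test_that("parameter recovery sharpens with sample size", {
  set.seed(61)
  err <- function(n, p0, shape) {
    reps <- vapply(1:6, function(i) {
      y <- draw <- ifelse(stats::rbinom(n, 1, 1 - p0) == 1,
                          stats::rgamma(n, shape = shape, scale = 5 / shape), 0)
      fit <- fit_hurdle_gamma(y)
      abs(fit$shape - shape)
    }, 0)
    stats::median(reps)
  }
  for (p0 in c(0.1, 0.5)) for (shape in c(0.5, 2, 5)) {
    expect_lt(err(5000, p0, shape), err(500, p0, shape) + 0.05)
  }
})

test_that("group comparisons report ratios, Wald p and BH q consistently", {
  set.seed(62)
  nr <- 40; nc <- 50
  labels <- matrix(rep(c(1L, 2L), each = nr * nc / 2), nr, nc)
  lmap <- region_label_map(labels, c(`1` = "Tumor", `2` = "Stroma"), 5, "elemental")
  n_half <- nr * nc / 2
  mk_channel <- function(mean2) {
    g1 <- ifelse(stats::rbinom(n_half, 1, 0.8) == 1,
                 stats::rgamma(n_half, 2, scale = 5 / 2), 0)
    g2 <- ifelse(stats::rbinom(n_half, 1, 0.6) == 1,
                 stats::rgamma(n_half, 2, scale = mean2 / 2), 0)
    matrix(c(g1, g2), nr, nc)
  }
  data <- array(c(mk_channel(10), mk_channel(5), mk_channel(20)), c(nr, nc, 3))
  map <- elemental_map(data, channel_names = c("Cu65", "Fe57", "Zn66"),
                       pixel_size_um = 5)
  cmp <- compare_groups(map, lmap, c(Tumor = "tumor", Stroma = "normal"))
  expect_identical(nrow(cmp), 3L)
  expect_identical(unique(cmp$contrast), "tumor vs normal")
  # tumor (mean 5) vs normal: Zn66 normal mean 20 -> negative log ratio
  expect_lt(cmp$log_mean_ratio[cmp$element == "Zn66"], 0)
  expect_lt(abs(cmp$log_mean_ratio[cmp$element == "Fe57"]), 0.2)  # both means 5
  # q-values are BH over the batch, monotone, and never below p
  expect_equal(cmp$q_value, stats::p.adjust(cmp$p_value, "BH"))
  expect_true(all(cmp$q_value >= cmp$p_value - 1e-15))
  o <- order(cmp$p_value)
  expect_true(all(diff(cmp$q_value[o]) >= -1e-15))
  # detection odds ratio reflects the 0.8 vs 0.6 detection difference
  expect_true(all(cmp$detect_odds_ratio > 1))
})

test_that("a known twofold abundance ratio is recovered within 3 SE", {
  set.seed(63)
  nr <- 40; nc <- 50
  labels <- matrix(rep(c(1L, 2L), each = nr * nc / 2), nr, nc)
  lmap <- region_label_map(labels, c(`1` = "A", `2` = "B"), 5, "elemental")
  n_half <- nr * nc / 2
  v <- c(stats::rgamma(n_half, 2, scale = 4 / 2), stats::rgamma(n_half, 2, scale = 8 / 2))
  map <- elemental_map(array(v, c(nr, nc, 1)), channel_names = "Zn66", pixel_size_um = 5)
  cmp <- compare_groups(map, lmap, c(A = "a_ref", B = "b_high"))
  expect_identical(cmp$contrast, "b_high vs a_ref")
  expect_lt(abs(cmp$log_mean_ratio - log(2)), 3 * cmp$log_mean_ratio_se)
  expect_identical(cmp$degenerate, "logit")     # no zeros anywhere
})

test_that("an all-zero group degrades gracefully", {
  nr <- 10; nc <- 10
  labels <- matrix(rep(c(1L, 2L), each = 50), nr, nc)
  lmap <- region_label_map(labels, c(`1` = "A", `2` = "B"), 5, "elemental")
  set.seed(64)
  v <- c(rep(0, 50), stats::rgamma(50, 2, 1))
  map <- elemental_map(array(v, c(nr, nc, 1)), channel_names = "E", pixel_size_um = 5)
  cmp <- compare_groups(map, lmap, c(A = "a", B = "b"))
  expect_match(cmp$degenerate, "separation")
  expect_true(is.na(cmp$detect_odds_ratio))
  # gamma contrast is skipped: positives exist only in one group
  expect_match(cmp$degenerate, "gamma")
  expect_true(is.na(cmp$log_mean_ratio))
})

test_that("grouping must name exactly two groups with enough pixels", {
  rl <- random_map_and_labels(3)
  expect_error(compare_groups(rl$map, rl$labels, c(R1 = "a", R2 = "b", R3 = "c")),
               class = "elemap_domain_error")
  tiny <- random_map_and_labels(4, nr = 3, nc = 3)
  expect_error(compare_groups(tiny$map, tiny$labels, c(R1 = "a", R2 = "b")),
               class = "elemap_domain_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(65)
  v <- c(rep(0, 30), stats::rgamma(70, 2, 0.5))
  fit <- fit_hurdle_gamma(v)
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("detection", "abundance", "shape"))
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n, 100L)
  expect_true(gl$converged)
})

test_that("tables export losslessly to CSV and JSON", {
  rl <- random_map_and_labels(5)
  tbl <- summarize_regions(rl$map, rl$labels)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  export_table(tbl, fcsv)
  back <- utils::read.csv(fcsv)
  expect_equal(as.data.frame(tbl), back, tolerance = 1e-12)
  fjson <- withr::local_tempfile(fileext = ".json")
  export_table(tbl, fjson)
  back2 <- jsonlite::fromJSON(fjson)
  expect_equal(back2$mean, tbl$mean, tolerance = 1e-12)

  # empty table -> header-only CSV
  empty <- tbl[0, ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_table(empty, f2)
  expect_identical(nrow(utils::read.csv(f2)), 0L)
  expect_match(readLines(f2)[1], "region_label")

  # labels with separators and quotes survive
  weird <- tibble::tibble(region_label = c('a,b', 'c"d'), value = c(1.5, 2.5))
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_table(weird, f3)
  expect_equal(utils::read.csv(f3)$region_label, weird$region_label)
})
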
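test_that("normality screen flags non-normal groups and degenerate input", {
  set.seed(314)
  d <- tibble::tibble(
    g = rep(c("a", "b"), each = 500),
    v = c(runif(500), rnorm(500))
  )
  scr <- normality_screen(d, "v", "g")
  expect_lt(scr$per_group$p[scr$per_group$group == "a"], 0.05)
  expect_equal(scr$recommendation, "nonparametric")

  const <- tibble::tibble(g = rep(c("a", "b"), each = 5),
                          v = c(rep(1, 5), rnorm(5)))
  scr2 <- normality_screen(const, "v", "g")
  expect_true(scr2$per_group$degenerate[scr2$per_group$group == "a"])

  tiny <- tibble::tibble(g = c("a", "a", "b", "b", "b"), v = rnorm(5))
  expect_error(normality_screen(tiny, "v", "g"),
               class = "oxymetr_stats_error")
})

test_that("Kruskal-Wallis H matches a hand rank computation", {
  # groups {1,2,3} and {4,5,6}: ranks 1..6, H = 12/(6*7)*(12^2/3+15^2/3)-3*7
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = 1:6)
  kw <- kruskal_wallis_pairwise(d, "v", "g")
  h_hand <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(kw$omnibus$statistic_h, h_hand, tolerance = 1e-12)
  expect_equal(kw$omnibus$statistic_h, 3.857, tolerance = 1e-3)
})

test_that("identical groups yield H = 0 and p-values of 1", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4), v = rep(1:4, 3))
  kw <- kruskal_wallis_pairwise(d, "v", "g")
  expect_equal(kw$omnibus$statistic_h, 0, tolerance = 1e-12)
  expect_true(all(kw$pairwise$bonferroni_p == 1))
})

test_that("well-separated groups are significant after Bonferroni", {
  set.seed(99)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 12),
                      v = c(rnorm(12, 0), rnorm(12, 5), rnorm(12, 10)))
  kw <- kruskal_wallis_pairwise(d, "v", "g")
  expect_true(all(kw$pairwise$bonferroni_p < 0.05))
  expect_equal(nrow(kw$pairwise), 3)
  # Bonferroni p never below raw p, capped at one
  expect_true(all(kw$pairwise$bonferroni_p >= kw$pairwise$raw_p))
  expect_true(all(kw$pairwise$bonferroni_p <= 1))
  # broom-style accessors
  expect_equal(nrow(tidy(kw)), 3)
  expect_equal(glance(kw)$n_total, 36)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(7)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), times = c(15, 14, 13)),
                      v = rnorm(42, 100, 20))
  h1 <- kruskal_wallis_pairwise(d, "v", "g")$omnibus$statistic_h
  d$v <- exp(d$v / 50)
  h2 <- kruskal_wallis_pairwise(d, "v", "g")$omnibus$statistic_h
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Dunn pairwise option agrees with rank-sum on clear separations", {
  set.seed(12)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 15),
                      v = c(rnorm(15, 0), rnorm(15, 4)))
  kw_d <- kruskal_wallis_pairwise(d, "v", "g", pairwise_method = "dunn")
  expect_lt(kw_d$pairwise$bonferroni_p[1], 0.05)
})

test_that("Pearson correlation matches a brute-force oracle", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  pc <- pearson_corr(d, "x", "y")
  # hand covariance / SD computation
  r_hand <- sum((d$x - 2.5) * (d$y - 2.5)) /
    sqrt(sum((d$x - 2.5)^2) * sum((d$y - 2.5)^2))
  expect_equal(pc$r, r_hand)
  expect_equal(pc$r, 0.6)
  expect_equal(pearson_corr(tibble::tibble(x = 1:5, y = 2 * (1:5)),
                            "x", "y")$r, 1)
  expect_equal(pearson_corr(tibble::tibble(x = 1:5, y = -(1:5)),
                            "x", "y")$r, -1)

  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    r_bf <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(pearson_corr(tibble::tibble(x = x, y = y), "x", "y")$r,
                 r_bf, tolerance = 1e-12)
  }
  expect_error(pearson_corr(tibble::tibble(x = rep(1, 5), y = rnorm(5)),
                            "x", "y"), class = "oxymetr_stats_error")
})

test_that("coefficient of variation: constants, scale invariance, arithmetic", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  set.seed(2)
  v <- rnorm(30, 50, 5)
  expect_equal(coefficient_of_variation(v), coefficient_of_variation(3 * v))
  # analytic check from the EAE oxygenation statistics: 100 * 14.8 / 63.8
  expect_equal(100 * 14.8 / 63.8, 23.2, tolerance = 1e-2)
  x <- c(63.8 - 14.8, 63.8 + 14.8)
  expect_equal(coefficient_of_variation(x), 100 * sd(x) / mean(x))
  expect_error(coefficient_of_variation(c(-1, 1)),
               class = "oxymetr_stats_error")
})

test_that("sample-size formula reproduces the derived cases", {
  # 2 * (1.96 + 0.8416)^2 = 15.7 -> 16
  expect_equal(sample_size_power(1, 1, alpha = 0.05, power = 0.80), 16L)
  # 2 * (1.96 + 1.645)^2 * 7.5^2 / 20^2 = 3.66 -> 4
  expect_equal(sample_size_power(20, 7.5, alpha = 0.05, power = 0.95), 4L)
  # larger detectable differences need fewer animals
  expect_lte(sample_size_power(40, 7.5, power = 0.95),
             sample_size_power(20, 7.5, power = 0.95))
  expect_error(sample_size_power(0, 5), class = "oxymetr_stats_error")
})

test_that("trajectory divergence finds the first significant day", {
  days <- 1:17
  mk <- function(id, g, scores) tibble::tibble(id = id, group = g,
                                               day = days, score = scores)
  # identical flat trajectories: no divergence
  flat <- dplyr::bind_rows(c(
    lapply(1:13, function(i) mk(i, "eae", rep(0, 17))),
    lapply(14:27, function(i) mk(i, "ctl", rep(0, 17)))
  ))
  expect_true(is.na(trajectory_divergence(flat, "day", "score",
                                          "group")$first_significant_day))

  # step at day 12 with small jitter: first significant day 12
  set.seed(8)
  step <- dplyr::bind_rows(c(
    lapply(1:13, function(i)
      mk(i, "eae", pmax(0, ifelse(days >= 12, 8, 0) + rnorm(17, 0, 0.5)))),
    lapply(14:27, function(i) mk(i, "ctl", pmax(0, rnorm(17, 0, 0.1))))
  ))
  td <- trajectory_divergence(step, "day", "score", "group")
  expect_equal(td$first_significant_day, 12)
  expect_equal(nrow(tidy(td)), 17)

  one_day <- dplyr::bind_rows(mk(1, "eae", rep(1, 17))[1, ],
                              mk(2, "ctl", rep(0, 17))[1, ])
  expect_error(trajectory_divergence(one_day, "day", "score", "group"),
               class = "oxymetr_stats_error")
})

test_that("parametric per-day option behaves like the rank-based one on steps", {
  days <- 1:17
  set.seed(18)
  d <- dplyr::bind_rows(c(
    lapply(1:13, function(i) tibble::tibble(
      id = i, group = "eae", day = days,
      score = ifelse(days >= 10, 6, 0) + rnorm(17, 0, 0.4))),
    lapply(14:27, function(i) tibble::tibble(
      id = i, group = "ctl", day = days, score = rnorm(17, 0, 0.4)))
  ))
  expect_equal(trajectory_divergence(d, "day", "score", "group",
                                     method = "t")$first_significant_day, 10)
})
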
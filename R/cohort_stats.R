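#' Shapiro-Wilk normality screen by group
#'
#' Runs the Shapiro-Wilk test within each group and recommends the
#' nonparametric analysis track when any group departs from normality at
#' alpha = 0.05. Constant groups are reported as degenerate (`p = NA`)
#' rather than erroring.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the metric and grouping
#'   variable.
#' @param alpha Significance level for the recommendation (default 0.05).
#' @return List with `per_group` tibble (`group`, `n`, `w`, `p`,
#'   `degenerate`) and `recommendation` (`"nonparametric"` or
#'   `"parametric"`).
#' @export
normality_screen <- function(data, value, group, alpha = 0.05) {
  vals <- split(data[[value]], data[[group]])
  vals <- lapply(vals, function(x) x[!is.na(x)])
  if (any(lengths(vals) < 3)) {
    abort("each group needs at least 3 observations",
          class = "oxymetr_stats_error")
  }
  rows <- purrr::imap(vals, function(x, g) {
    if (length(unique(x)) == 1) {
      tibble::tibble(group = g, n = length(x), w = NA_real_, p = NA_real_,
                     degenerate = TRUE)
    } else {
      sw <- stats::shapiro.test(x)
      tibble::tibble(group = g, n = length(x), w = unname(sw$statistic),
                     p = sw$p.value, degenerate = FALSE)
    }
  })
  per_group <- dplyr::bind_rows(rows)
  rec <- if (any(per_group$p < alpha, na.rm = TRUE)) "nonparametric"
         else "parametric"
  list(per_group = per_group, recommendation = rec)
}

rank_sum_p <- function(x, y) {
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
}

dunn_pairwise_p <- function(vals) {
  all_v <- unlist(vals)
  r <- rank(all_v)
  g <- rep(names(vals), lengths(vals))
  n <- length(all_v)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(vals), 2, simplify = FALSE)
  purrr::map_dbl(setNames(pairs, vapply(pairs, paste, "", collapse = " vs ")),
                 function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    2 * pnorm(-abs(z))
  })
}

#' Kruskal-Wallis omnibus test with Bonferroni pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square omnibus p-value,
#' followed by all pairwise two-group comparisons with Bonferroni
#' correction (raw p multiplied by the number of pairs, capped at 1).
#' Pairwise comparisons default to rank-sum tests; Dunn's rank-based
#' z-tests are available behind `pairwise_method = "dunn"`.
#'
#' @param data Data frame.
#' @param value,group Column names (strings).
#' @param pairwise_method `"wilcoxon"` (default) or `"dunn"`.
#' @return Object of class `oxy_kw`: list with `omnibus` (tibble:
#'   `statistic_h`, `df`, `p`), `pairwise` (tibble: `pair`, `raw_p`,
#'   `bonferroni_p`), `summaries` (tibble: `group`, `n`, `mean`, `sd`,
#'   `cv_pct`) and metadata.
#' @export
kruskal_wallis_pairwise <- function(data, value, group,
                                    pairwise_method = c("wilcoxon", "dunn")) {
  pairwise_method <- match.arg(pairwise_method)
  vals <- split(data[[value]], data[[group]])
  vals <- lapply(vals, function(x) x[!is.na(x)])
  if (length(vals) < 2 || any(lengths(vals) < 2)) {
    abort("need >= 2 groups with >= 2 observations each",
          class = "oxymetr_stats_error")
  }
  kw <- stats::kruskal.test(unname(vals))
  n_pairs <- choose(length(vals), 2)
  if (pairwise_method == "wilcoxon") {
    pairs <- utils::combn(names(vals), 2, simplify = FALSE)
    raw <- purrr::map_dbl(pairs, function(pr)
      rank_sum_p(vals[[pr[1]]], vals[[pr[2]]]))
    pair_lab <- vapply(pairs, paste, "", collapse = " vs ")
  } else {
    raw <- dunn_pairwise_p(vals)
    pair_lab <- names(raw)
  }
  pairwise <- tibble::tibble(pair = pair_lab, raw_p = unname(raw),
                             bonferroni_p = pmin(1, unname(raw) * n_pairs))
  summaries <- dplyr::bind_rows(purrr::imap(vals, function(x, g)
    tibble::tibble(group = g, n = length(x), mean = mean(x), sd = sd(x),
                   cv_pct = 100 * sd(x) / mean(x))))
  structure(list(
    omnibus = tibble::tibble(statistic_h = unname(kw$statistic),
                             df = unname(kw$parameter), p = kw$p.value),
    pairwise = pairwise, summaries = summaries,
    value = value, group = group, pairwise_method = pairwise_method,
    data = tibble::tibble(group = rep(names(vals), lengths(vals)),
                          value = unlist(vals, use.names = FALSE))
  ), class = "oxy_kw")
}

#' @export
print.oxy_kw <- function(x, ...) {
  cat("Kruskal-Wallis comparison of `", x$value, "` across `", x$group,
      "`\n", sep = "")
  cat(sprintf("  H = %.3f, df = %d, omnibus p = %.4g\n",
              x$omnibus$statistic_h, x$omnibus$df, x$omnibus$p))
  cat("Pairwise (", x$pairwise_method, ", Bonferroni x",
      nrow(x$pairwise), "):\n", sep = "")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  cat("Group summaries:\n")
  print(as.data.frame(x$summaries), row.names = FALSE)
  invisible(x)
}

#' Tidy a Kruskal-Wallis comparison
#'
#' @param x An `oxy_kw` object.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @method tidy oxy_kw
#' @export
tidy.oxy_kw <- function(x, ...) x$pairwise

#' Glance at a Kruskal-Wallis comparison
#'
#' @param x An `oxy_kw` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic_h`, `df`, `p_value`, `n_groups`,
#'   `n_total`.
#' @method glance oxy_kw
#' @export
glance.oxy_kw <- function(x, ...) {
  tibble::tibble(statistic_h = x$omnibus$statistic_h, df = x$omnibus$df,
                 p_value = x$omnibus$p, n_groups = nrow(x$summaries),
                 n_total = sum(x$summaries$n))
}

#' Pearson correlation with t-based p-value
#'
#' Pairwise-complete Pearson correlation; the two-sided p-value comes
#' from the t transform with n - 2 degrees of freedom.
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
pearson_corr <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    abort("need at least 3 complete pairs", class = "oxymetr_stats_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("zero variance in x or y", class = "oxymetr_stats_error")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Coefficient of variation
#'
#' `100 * sample SD / mean`, in percent.
#'
#' @param values Numeric vector.
#' @param na.rm Drop missing values first (default `TRUE`).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values, na.rm = TRUE) {
  if (na.rm) values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) abort("mean is zero; CV undefined",
                    class = "oxymetr_stats_error")
  100 * sd(values) / m
}

#' Two-sample normal-approximation sample size
#'
#' Per-group n to detect a mean difference `delta` between two groups
#' with common SD `sd` at two-sided level `alpha` and the requested
#' power: `n = ceil(2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2)`.
#'
#' @param delta Detectable difference (> 0).
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided type-I level (default 0.05).
#' @param power Target power in (0, 1) (default 0.95).
#' @return Integer n per group.
#' @export
sample_size_power <- function(delta, sd, alpha = 0.05, power = 0.95) {
  if (delta <= 0) abort("delta must be positive",
                        class = "oxymetr_stats_error")
  if (sd <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("sd, alpha and power must be positive (alpha, power < 1)",
          class = "oxymetr_stats_error")
  }
  as.integer(ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 *
                       sd^2 / delta^2))
}

#' First day of disease-trajectory divergence between two groups
#'
#' Compares the two groups' daily disease scores day by day (rank-sum by
#' default, Welch t as the parametric option), Bonferroni-corrects
#' across days, and reports the earliest day whose corrected p-value
#' falls below `alpha`. Attrition is allowed; per-day group sizes are
#' recorded.
#'
#' @param data Long data frame of daily scores.
#' @param day,score,group Column names (strings); `group` must have
#'   exactly two levels.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @param alpha Significance level after correction (default 0.05).
#' @return Object of class `oxy_trajectory`: list with `per_day` tibble
#'   (`day`, `n_1`, `n_2`, `raw_p`, `bonferroni_p`) and
#'   `first_significant_day` (`NA` when none).
#' @export
trajectory_divergence <- function(data, day, score, group,
                                  method = c("wilcoxon", "t"),
                                  alpha = 0.05) {
  method <- match.arg(method)
  glev <- unique(data[[group]])
  if (length(glev) != 2) {
    abort("trajectory comparison needs exactly two groups",
          class = "oxymetr_stats_error")
  }
  keep <- !is.na(data[[score]])
  data <- data[keep, ]
  days1 <- unique(data[[day]][data[[group]] == glev[1]])
  days2 <- unique(data[[day]][data[[group]] == glev[2]])
  shared <- sort(intersect(days1, days2))
  if (length(shared) < 2) {
    abort("fewer than 2 shared days between groups",
          class = "oxymetr_stats_error")
  }
  per_day <- purrr::map_dfr(shared, function(d) {
    x <- data[[score]][data[[day]] == d & data[[group]] == glev[1]]
    y <- data[[score]][data[[day]] == d & data[[group]] == glev[2]]
    p <- if (length(unique(c(x, y))) == 1) {
      1
    } else if (method == "wilcoxon") {
      rank_sum_p(x, y)
    } else {
      stats::t.test(x, y)$p.value
    }
    tibble::tibble(day = d, n_1 = length(x), n_2 = length(y), raw_p = p)
  })
  per_day$bonferroni_p <- pmin(1, per_day$raw_p * nrow(per_day))
  sig <- per_day$day[per_day$bonferroni_p < alpha]
  structure(list(per_day = per_day,
                 first_significant_day = if (length(sig)) min(sig)
                                         else NA_real_,
                 groups = glev, method = method, alpha = alpha),
            class = "oxy_trajectory")
}

#' @export
print.oxy_trajectory <- function(x, ...) {
  cat("Disease-trajectory divergence (", x$groups[1], " vs ", x$groups[2],
      ", ", x$method, ", Bonferroni x", nrow(x$per_day), ")\n", sep = "")
  cat("First significant day:", x$first_significant_day, "\n")
  invisible(x)
}

#' Tidy a trajectory-divergence result
#'
#' @param x An `oxy_trajectory` object.
#' @param ... Unused.
#' @return The per-day tibble.
#' @method tidy oxy_trajectory
#' @export
tidy.oxy_trajectory <- function(x, ...) x$per_day

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
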
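# Growth series, doubling-time estimation and comparison statistics.

#' Construct a growth series
#'
#' @param times_hr strictly increasing observation times in hours.
#' @param counts positive cell counts, one per time point.
#' @param cell_type optional label (`"HUVEC"`, `"ECFC"`, ...).
#' @return an object of class `growth_series`.
#' @export
growth_series <- function(times_hr, counts, cell_type = NA_character_) {
  stopifnot(is.numeric(times_hr), is.numeric(counts),
            length(times_hr) == length(counts), length(times_hr) >= 1L)
  if (any(diff(times_hr) <= 0)) stop("times must be strictly increasing")
  if (any(counts <= 0)) stop("counts must be positive")
  structure(list(times_hr = as.numeric(times_hr),
                 counts = as.numeric(counts), cell_type = cell_type),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> %s: %d time points (%.4g - %.4g hr)\n",
              x$cell_type %||% "?", length(x$times_hr), min(x$times_hr),
              max(x$times_hr)))
  invisible(x)
}

#' Simulate an exponentially growing culture's cell counts
#'
#' Expected count at time t is `seed_density * 2^((t - t0) / doubling_time)`
#' with `t0` the first time point; `noise = "none"` returns the expectations
#' exactly, `noise = "poisson"` draws each time point independently from a
#' Poisson with that mean (draws of zero are floored at one so the series
#' remains a valid growth series).
#'
#' @param seed_density count at the first time point (e.g. cells/cm^2, or
#'   cells/field when already scaled to the imaged area).
#' @param doubling_time_hr population doubling time (> 0).
#' @param times_hr sorted ascending observation times.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed (mandatory when `noise = "poisson"`).
#' @param cell_type optional label carried into the series.
#' @return a [growth_series()].
#' @examples
#' simulate_growth_counts(100, 24, c(0, 24, 48))$counts  # 100 200 400
#' @export
simulate_growth_counts <- function(seed_density, doubling_time_hr, times_hr,
                                   noise = c("none", "poisson"), seed = NULL,
                                   cell_type = NA_character_) {
  noise <- match.arg(noise)
  assert_scalar(seed_density, "seed_density", 0, TRUE)
  assert_scalar(doubling_time_hr, "doubling_time_hr", 0, TRUE)
  if (length(times_hr) == 0L) stop("times_hr must be non-empty")
  if (is.unsorted(times_hr, strictly = TRUE))
    stop("times_hr must be sorted strictly ascending")
  mu <- seed_density * 2^((times_hr - times_hr[1]) / doubling_time_hr)
  counts <- if (noise == "none") mu else {
    if (is.null(seed)) stop("'seed' is mandatory for poisson noise")
    withr::with_seed(seed, pmax(rpois(length(mu), mu), 1))
  }
  growth_series(times_hr, counts, cell_type)
}

#' Doubling time over one interval
#'
#' `(t1 - t0) * log(2) / (log(n1) - log(n0))`: positive for growth, negative
#' for shrinkage. Equal counts make the interval degenerate (division by
#' zero) and raise an error.
#'
#' @param t0,t1 interval endpoints in hours (`t1 > t0`).
#' @param n0,n1 positive counts at `t0` and `t1`.
#' @return doubling time in hours.
#' @examples
#' interval_doubling_time(0, 24, 100, 200)  # 24
#' @export
interval_doubling_time <- function(t0, t1, n0, n1) {
  assert_scalar(t0, "t0"); assert_scalar(t1, "t1")
  assert_scalar(n0, "n0", 0, TRUE); assert_scalar(n1, "n1", 0, TRUE)
  if (t1 <= t0) stop("t1 must be > t0")
  if (n1 == n0)
    stop("degenerate interval: equal counts give an undefined doubling time")
  (t1 - t0) * log(2) / (log(n1) - log(n0))
}

#' Mean doubling time of a growth series
#'
#' The arithmetic mean of [interval_doubling_time()] over consecutive time
#' intervals. Degenerate intervals (equal consecutive counts) are excluded
#' with a warning; if every interval is degenerate an error is raised.
#'
#' @param series a [growth_series()] with at least two time points.
#' @return mean doubling time in hours.
#' @export
mean_doubling_time <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  t <- series$times_hr; n <- series$counts
  if (length(t) < 2L) stop("need at least two time points")
  keep <- diff(n) != 0
  if (!any(keep)) stop("all intervals are degenerate (constant counts)")
  if (!all(keep))
    warning(sprintf("%d degenerate interval(s) excluded", sum(!keep)))
  i <- which(keep)
  dts <- diff(t)[i] * log(2) / (log(n[i + 1L]) - log(n[i]))
  mean(dts)
}

#' Linear regression of counts on time
#'
#' Ordinary least squares of `count / count_scale` on time, as used for
#' growth-rate slopes of cell-count time courses. The default fits raw
#' counts; set `count_scale = 1000` to express slopes in thousands of cells
#' per hour, or `response = "log2_count"` for a log-linear fit (exponential
#' growth's natural scale, in doublings per hour).
#'
#' @param series a [growth_series()] with at least 3 points.
#' @param response `"count"` or `"log2_count"`.
#' @param count_scale divisor applied to counts before fitting.
#' @return an object of class `regression_result`: slope (per hour),
#'   intercept, r_squared, p_value (slope t-test), n, residual_var, and the
#'   fitted data.
#' @export
fit_growth_regression <- function(series, response = c("count", "log2_count"),
                                  count_scale = 1) {
  stopifnot(inherits(series, "growth_series"))
  response <- match.arg(response)
  t <- series$times_hr
  if (length(t) < 3L) stop("need at least 3 points for regression")
  y <- series$counts / count_scale
  if (response == "log2_count") y <- log2(y)
  fit <- lm(y ~ t)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0
  if (var(y) == 0) r2 <- 0
  pv <- tryCatch(sm$coefficients["t", "Pr(>|t|)"], error = function(e) NA_real_)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 p_value = unname(pv),
                 n = length(t),
                 residual_var = sm$sigma^2,
                 response = response, count_scale = count_scale,
                 data = data.frame(t = t, y = y)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> slope %.4g /hr, r^2 %.3f, p %.3g (n = %d)\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

as_regression_data <- function(x, response = "count", count_scale = 1) {
  if (inherits(x, "regression_result")) return(x$data)
  if (inherits(x, "growth_series")) {
    y <- x$counts / count_scale
    if (response == "log2_count") y <- log2(y)
    return(data.frame(t = x$times_hr, y = y))
  }
  stopifnot(is.data.frame(x), all(c("t", "y") %in% names(x)))
  x
}

#' Test equality of two regression slopes
#'
#' The standard ANCOVA slope-homogeneity F-test: a common-slope model
#' `y ~ t + group` is compared against separate slopes `y ~ t * group`. This
#' is the test statistical packages report when asking whether two fitted
#' growth lines share a slope.
#'
#' @param a,b `growth_series`, `regression_result`, or data frames with
#'   columns `t` and `y`.
#' @param response,count_scale passed to the series-to-data conversion.
#' @return a list with `f_statistic`, `df1`, `df2` and `p_value`.
#' @export
slopes_equal_test <- function(a, b, response = "count", count_scale = 1) {
  da <- as_regression_data(a, response, count_scale)
  db <- as_regression_data(b, response, count_scale)
  dat <- rbind(cbind(da, g = "a"), cbind(db, g = "b"))
  dat$g <- factor(dat$g)
  if (var(dat$t) == 0) stop("degenerate design: all times identical")
  reduced <- lm(y ~ t + g, data = dat)
  full <- lm(y ~ t * g, data = dat)
  rss_r <- sum(reduced$residuals^2)
  rss_f <- sum(full$residuals^2)
  df2 <- full$df.residual
  if (df2 <= 0) stop("not enough points to compare slopes")
  if (rss_f <= .Machine$double.eps * max(1, rss_r)) {
    # saturated full model: identical-slope data gives F ~ 0, separated
    # noiseless slopes give F -> Inf
    if (rss_r <= .Machine$double.eps) {
      return(list(f_statistic = 0, df1 = 1L, df2 = df2, p_value = 1))
    }
    return(list(f_statistic = Inf, df1 = 1L, df2 = df2, p_value = 0))
  }
  f <- max((rss_r - rss_f) / 1 / (rss_f / df2), 0)
  list(f_statistic = f, df1 = 1L, df2 = df2,
       p_value = pf(f, 1, df2, lower.tail = FALSE))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F decomposition across k groups, computed via
#' [stats::lm()]/[stats::anova()]. If every group has zero internal variance
#' while means differ, `f_statistic = Inf` and `p_value = 0` are reported
#' explicitly; if all values are identical the test is a no-op (`F = 0`,
#' `p = 1`).
#'
#' @param groups a list (optionally named) of numeric vectors, each of
#'   length >= 2; at least two groups.
#' @return an object of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `group_means`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  k <- length(groups)
  nn <- nrow(dat)
  means <- vapply(groups, mean, numeric(1))
  df_b <- k - 1L
  df_w <- nn - k
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ssb <- sum(vapply(groups, length, integer(1)) * (means - mean(dat$value))^2)
  res <- if (ssw <= .Machine$double.eps * max(1, ssb)) {
    if (ssb <= .Machine$double.eps) {
      list(f = 0, p = 1)
    } else {
      list(f = Inf, p = 0)   # zero within-group variance, distinct means
    }
  } else {
    an <- anova(lm(value ~ group, data = dat))
    list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1])
  }
  structure(list(f_statistic = res$f, df_between = df_b, df_within = df_w,
                 p_value = res$p, group_means = means),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n", x$df_between,
              x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Paired t-test
#'
#' One-sample t-test on the element-wise differences `x - y`. Symmetric:
#' swapping `x` and `y` negates `t` and leaves `p` unchanged. Identical
#' vectors return `t = 0`, `p = 1`; a constant non-zero difference has no
#' sampling variance and is reported as `t = +/-Inf`, `p = 0`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a list with `t`, `df` and `p_value`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L)
  d <- x - y
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1L, p_value = 1))
  if (sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p_value = 0))
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
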
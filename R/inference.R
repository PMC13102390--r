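#' Fit the target-area line to per-ant saturation areas
#'
#' Ordinary least squares of per-ant saturation area (cm2) against cohort
#' age (days). On the study's fixed-demographics cohorts this line is
#' \eqn{y = -0.032 x + 11.22} (R2 = 0.96).
#'
#' @param cohort_ages ages in days (at least 3 distinct values).
#' @param per_ant_saturation saturation area per ant, cm2.
#' @return an object of class `target_line_fit`: the fitted [target_line()],
#'   `r_squared`, the underlying `lm` fit, and `n`.
#' @export
fit_target_line <- function(cohort_ages, per_ant_saturation) {
  stopifnot(length(cohort_ages) == length(per_ant_saturation))
  if (length(unique(cohort_ages)) < 3L) {
    stop("need at least 3 distinct cohort ages to fit a line")
  }
  fit <- lm(y ~ x, data = data.frame(x = cohort_ages, y = per_ant_saturation))
  cf <- coef(fit)
  ss_tot <- sum((per_ant_saturation - mean(per_ant_saturation))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(line = target_line(slope = unname(cf[2]),
                                    intercept = unname(cf[1])),
                 r_squared = r2,
                 fit = fit, n = length(cohort_ages)),
            class = "target_line_fit")
}

#' @export
coef.target_line_fit <- function(object, ...) {
  c(intercept = object$line$intercept, slope = object$line$slope)
}

#' @export
print.target_line_fit <- function(x, ...) {
  cat(sprintf("<target_line_fit> a_age = %.4g + (%.4g) age  (R2 = %.3f, n = %d)\n",
              x$line$intercept, x$line$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
summary.target_line_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.target_line_fit <- function(object, age, ...) {
  target_area(age, object$line)
}

#' @export
residuals.target_line_fit <- function(object, ...) residuals(object$fit, ...)

#' Estimate the basal digging rate constant from a single-cohort trajectory
#'
#' Nonlinear least-squares fit of the closed-form saturation curve
#' \eqn{A(t) = N [a_\infty + (a_0 - a_\infty) e^{-r t / a_\infty}]} to an
#' excavation time series from a cohort of `N` same-age ants, estimating the
#' rate constant `r` and the per-ant saturation area jointly.
#'
#' @param day,area trajectory (days since introduction, cm2).
#' @param N number of ants in the cohort.
#' @param a0 initial area per ant (cm2).
#' @return an object of class `rate_fit` with elements `r`, `a_inf`
#'   (per-ant saturation area), `fit` (the `nls` object, or `NULL` for the
#'   degenerate flat-trajectory case) and `converged`.
#' @export
estimate_r <- function(day, area, N, a0 = 0) {
  stopifnot(length(day) == length(area), N >= 1)
  if (var(area) < 1e-12 || max(area) <= N * a0 + 1e-9) {
    # flat trajectory: no digging signal
    return(structure(list(r = 0, a_inf = mean(area) / N, fit = NULL,
                          converged = TRUE), class = "rate_fit"))
  }
  df <- data.frame(t = day, A = area)
  start <- list(r = 1, a_inf = max(area) / N)
  fit <- try(minpack.lm::nlsLM(
    A ~ N * (a_inf + (a0 - a_inf) * exp(-r * t / a_inf)),
    data = df, start = start,
    lower = c(r = 1e-6, a_inf = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("rate-constant fit did not converge; residual diagnostics unavailable")
  }
  cf <- coef(fit)
  structure(list(r = unname(cf["r"]), a_inf = unname(cf["a_inf"]),
                 fit = fit, converged = TRUE), class = "rate_fit")
}

#' @export
coef.rate_fit <- function(object, ...) c(r = object$r, a_inf = object$a_inf)

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> r = %.3g cm2/(ant day), per-ant saturation = %.3g cm2\n",
              x$r, x$a_inf))
  invisible(x)
}

#' Daily rate series from an irregularly sampled measurement
#'
#' Linearly interpolates the samples to a daily grid, differentiates with
#' central differences, and optionally smooths with a centred moving
#' average. The default 3-day window matches the maximum photography gap.
#'
#' @param day strictly increasing sample days (at least 3).
#' @param value measured series (area, population, ...).
#' @param smooth_window moving-average width in days (odd; 0 or 1 disables).
#' @return data frame `day`, `rate` on the daily grid.
#' @export
rate_series <- function(day, value, smooth_window = 3) {
  stopifnot(length(day) == length(value))
  if (length(day) < 3L) stop("need at least 3 samples")
  if (any(diff(day) <= 0)) stop("sample days must be strictly increasing")
  grid <- seq(ceiling(min(day)), floor(max(day)))
  v <- approx(day, value, xout = grid)$y
  n <- length(grid)
  rate <- numeric(n)
  rate[1] <- v[2] - v[1]
  rate[n] <- v[n] - v[n - 1]
  if (n > 2) rate[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  if (smooth_window > 1) {
    w <- smooth_window
    if (w %% 2 == 0) w <- w + 1
    sm <- as.numeric(stats::filter(rate, rep(1 / w, w), sides = 2))
    rate <- ifelse(is.na(sm), rate, sm)
  }
  data.frame(day = grid, rate = rate)
}

#' Lagged normalized cross-correlation of two daily series
#'
#' Per-lag Pearson correlation of the overlapping segments (each segment is
#' re-standardised at every lag, so edge effects do not bias the peak). A
#' negative lag means `y` precedes `x`: with `x` the digging rate and `y`
#' the population growth rate, a peak at a negative lag says nest expansion
#' follows population growth.
#'
#' @param x,y numeric series on a common daily grid.
#' @param max_lag maximum absolute lag in days; the overlap must be at
#'   least `2 * max_lag` long.
#' @return data frame `lag`, `coefficient`; coefficients are `NA` where a
#'   segment has zero variance.
#' @export
xcorr_lagged <- function(x, y, max_lag = 30) {
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  if (n < 2 * max_lag) stop("series overlap shorter than 2 * max_lag")
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(L) {
    if (L >= 0) { xs <- x[seq_len(n - L)]; ys <- y[seq_len(n - L) + L] }
    else        { xs <- x[seq_len(n + L) - L]; ys <- y[seq_len(n + L)] }
    if (length(xs) < 3 || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  data.frame(lag = lags, coefficient = cc)
}

#' Lag of the cross-correlation maximum
#'
#' @param xc data frame `lag`, `coefficient` (as from [xcorr_lagged()],
#'   possibly averaged over colonies). `NA` coefficients are ignored.
#' @return the lag (days) with the largest coefficient; exact ties are
#'   broken toward the smallest `|lag|`.
#' @export
peak_lag <- function(xc) {
  ok <- !is.na(xc$coefficient)
  if (!any(ok)) stop("all coefficients are undefined")
  xc <- xc[ok, ]
  xc <- xc[order(abs(xc$lag), xc$lag), ]
  xc$lag[which.max(xc$coefficient)]
}

#' Zero-intercept fit of excavated area against population size
#'
#' Least squares through the origin: `slope = sum(x y) / sum(x^2)`. The
#' study's colony-maturation data give \eqn{y = 10.71 x} (R2 = 0.97),
#' i.e. about 11 cm2 regulated per ant.
#'
#' @param mean_area excavated areas (cm2).
#' @param mean_N population sizes (ants).
#' @return an object of class `scaling_fit` with `slope` (cm2/ant),
#'   `r_squared` (relative to the origin line) and `n`.
#' @export
fit_area_vs_population <- function(mean_area, mean_N) {
  stopifnot(length(mean_area) == length(mean_N))
  ok <- is.finite(mean_area) & is.finite(mean_N)
  x <- mean_N[ok]; y <- mean_area[ok]
  if (sum(x^2) == 0) stop("all population values are zero")
  slope <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  structure(list(slope = slope, r_squared = r2, n = length(x)),
            class = "scaling_fit")
}

#' @export
coef.scaling_fit <- function(object, ...) c(slope = object$slope)

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> area = %.4g x population  (R2 = %.3f, n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Asymptotic area per ant of a trajectory
#'
#' Mean of `area / N` over the final `k` sampling points, with day 1 set
#' either at the experiment start or at first worker emergence. The study
#' reports 11.1 (+/- 1) and 11.6 (+/- 1.15) cm2/ant for the two choices.
#'
#' @param day,area,n_ants sampled trajectory.
#' @param day1_mode `"experiment_start"` or `"first_worker"`.
#' @param first_worker_day required for `"first_worker"` mode.
#' @param k number of final sampling points averaged (default 5).
#' @return area per ant in cm2.
#' @export
area_per_ant_stabilization <- function(day, area, n_ants,
                                       day1_mode = c("experiment_start",
                                                     "first_worker"),
                                       first_worker_day = NULL, k = 5) {
  day1_mode <- match.arg(day1_mode)
  stopifnot(length(day) == length(area), length(day) == length(n_ants))
  origin <- if (day1_mode == "first_worker") {
    if (is.null(first_worker_day)) stop("first_worker_day required")
    first_worker_day
  } else 0
  keep <- day >= origin & n_ants > 0
  d <- day[keep]; a <- area[keep]; n <- n_ants[keep]
  if (length(d) < k) stop("fewer than k sampling points after the origin")
  idx <- order(d)
  tail_idx <- tail(idx, k)
  apa <- a[tail_idx] / n[tail_idx]
  if (length(apa) >= 2 && mean(apa) > 0 &&
      (max(apa) - min(apa)) / mean(apa) > 0.5) {
    warning("area per ant still changing over the final window; plateau doubtful")
  }
  mean(apa)
}

#' Fraction of collapse-lost area recovered at digging cessation
#'
#' Digging is deemed to have ceased once the daily rate stays below `eps`
#' for `k` consecutive days after the collapse; `A_cease` is the area on the
#' day cessation is confirmed (the end of that quiet window) and the
#' recovery fraction is `(A_cease - A_post) / (A_pre - A_post)`. The study's colonies stopped at
#' 93 +/- 3% of the lost area; the density-regulation model itself recovers
#' the full plateau (fraction 1).
#'
#' @param day,area trajectory at (near-)daily resolution spanning the
#'   collapse and subsequent cessation.
#' @param event_day day of the collapse.
#' @param eps,k cessation rule (rate below `eps` cm2/day for `k` days).
#' @return recovery fraction (dimensionless).
#' @export
recovery_fraction <- function(day, area, event_day, eps = 0.1, k = 5) {
  stopifnot(length(day) == length(area))
  o <- order(day)
  day <- day[o]; area <- area[o]
  pre <- which(day < event_day)
  post <- which(day >= event_day)
  if (!length(pre) || length(post) < k + 1) {
    stop("trajectory must span the collapse and extend past cessation")
  }
  A_pre <- area[max(pre)]
  A_post <- area[post[1L]]
  if (A_pre <= A_post) stop("no area was lost at the stated event day")
  d <- day[post]; a <- area[post]
  rate <- diff(a) / diff(d)
  quiet <- rate < eps
  run <- rle(quiet)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & (d[ends + 1L] - d[starts]) >= k)
  if (!length(ok)) stop("no cessation detected after the collapse")
  i0 <- starts[ok[1L]]
  i1 <- which(d >= d[i0] + k)[1L]
  (a[i1] - A_post) / (A_pre - A_post)
}

#' Mean delay from population increase to digging onset
#'
#' For every day on which the (daily, interpolated) population count rises,
#' finds the first subsequent day whose digging rate exceeds
#' `rate_threshold` and averages those delays.
#'
#' @param pop data frame `day`, `n` (daily population).
#' @param dig data frame `day`, `rate` (daily digging rate, e.g. from
#'   [rate_series()]).
#' @param rate_threshold digging-rate threshold in cm2/day.
#' @return mean delay in days.
#' @export
onset_delay <- function(pop, dig, rate_threshold = 0.5) {
  stopifnot(all(c("day", "n") %in% names(pop)),
            all(c("day", "rate") %in% names(dig)))
  events <- pop$day[which(diff(pop$n) > 0) + 1L]
  if (!length(events)) stop("no population-increase events")
  hot <- dig$day[dig$rate > rate_threshold]
  delays <- vapply(events, function(e) {
    nxt <- hot[hot >= e]
    if (length(nxt)) nxt[1L] - e else NA_real_
  }, numeric(1))
  delays <- delays[!is.na(delays)]
  if (!length(delays)) stop("digging never exceeded the threshold after any event")
  mean(delays)
}

#' Fit the logistic population model to worker counts
#'
#' Least-squares fit of \eqn{N(t) = K / (1 + e^{-\rho (t - t_{mid})})},
#' reported as [population_params()] with `N0 = 1` (so
#' \eqn{t_{first} = t_{mid} - \log(K - 1)/\rho}).
#'
#' @param day,N observed worker counts (at least 4 points).
#' @return an object of class `logistic_fit` with `params`
#'   (a [population_params()]), `fit` and `converged`. A constant series is
#'   returned degenerately as `K = constant` with `rho = NA`.
#' @export
fit_logistic_population <- function(day, N) {
  stopifnot(length(day) == length(N))
  # leading zero counts predate the first emergence and lie outside the
  # logistic family; fit from the first nonzero count onward
  if (any(N > 0)) {
    first <- which(N > 0)[1L]
    day <- day[first:length(day)]; N <- N[first:length(N)]
  }
  if (length(day) < 4L) stop("need at least 4 points")
  if (var(N) < 1e-12) {
    p <- structure(list(K = N[1], rho = NA_real_, t_first = min(day), N0 = N[1]),
                   class = "population_params")
    return(structure(list(params = p, fit = NULL, converged = TRUE),
                     class = "logistic_fit"))
  }
  df <- data.frame(t = day, n = N)
  t_mid0 <- df$t[which.min(abs(df$n - max(df$n) / 2))]
  fit <- try(minpack.lm::nlsLM(
    n ~ K / (1 + exp(-rho * (t - t_mid))),
    data = df,
    start = list(K = max(df$n) * 1.05, rho = 0.1, t_mid = t_mid0),
    lower = c(K = 1, rho = 1e-4, t_mid = min(df$t) - 100),
    upper = c(K = max(df$n) * 3 + 1, rho = 5, t_mid = max(df$t) + 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("logistic population fit did not converge")
  }
  cf <- coef(fit)
  K <- unname(cf["K"]); rho <- unname(cf["rho"]); t_mid <- unname(cf["t_mid"])
  t_first <- if (K > 1) t_mid - log(K - 1) / rho else t_mid
  p <- population_params(K = K, rho = rho, t_first = t_first, N0 = 1)
  structure(list(params = p, fit = fit, converged = TRUE),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) {
  p <- object$params
  c(K = p$K, rho = p$rho, t_first = p$t_first)
}

#' @export
print.logistic_fit <- function(x, ...) {
  print(x$params)
  invisible(x)
}
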
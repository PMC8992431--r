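#' Interpolate sensor readings over the experimental unit
#'
#' Extends point sensor measurements (temperature, radiation) to every plot
#' position. Default method is inverse-distance weighting (power 2), which
#' is exact at the sensor locations; ordinary kriging with an exponential
#' variogram fitted to the empirical semivariances is available behind
#' `method = "kriging"`. The leave-one-sensor-out cross-validation RMSE is
#' attached so the interpolation quality can be checked.
#'
#' @param sensors Data frame with columns `x`, `y`, `value`.
#' @param queries Data frame with columns `x`, `y`.
#' @param method `"idw"` or `"kriging"`.
#' @param power IDW power, default 2.
#' @return `queries` as a tibble with a `value` column; attribute
#'   `loo_rmse`.
#' @export
interpolate_sensors <- function(sensors, queries,
                                method = c("idw", "kriging"), power = 2) {
  method <- match.arg(method)
  sensors <- as_tibble(sensors)
  queries <- as_tibble(queries)
  if (nrow(sensors) < 1) abort("need at least one sensor")
  key <- paste(sensors$x, sensors$y)
  if (anyDuplicated(key)) {
    agg <- tapply(sensors$value, key, function(v) diff(range(v)))
    if (any(agg > 1e-12)) {
      abort("duplicate sensor coordinates with conflicting values")
    }
    sensors <- sensors[!duplicated(key), ]
  }
  predict_at <- function(train, qx, qy) {
    switch(method,
      idw = idw_predict(train, qx, qy, power),
      kriging = ok_predict(train, qx, qy)
    )
  }
  out <- queries
  out$value <- predict_at(sensors, queries$x, queries$y)
  if (nrow(sensors) >= 3) {
    # cross-validation error on an evenly spaced subsample of sensors, so
    # dense networks stay cheap (the estimate is deterministic)
    idx <- unique(round(seq(1, nrow(sensors), length.out = min(100, nrow(sensors)))))
    loo <- vapply(idx, function(i) {
      predict_at(sensors[-i, ], sensors$x[i], sensors$y[i])
    }, numeric(1))
    attr(out, "loo_rmse") <- sqrt(mean((loo - sensors$value[idx])^2))
  }
  out
}

idw_predict <- function(train, qx, qy, power) {
  dx <- outer(qx, train$x, "-")
  dy <- outer(qy, train$y, "-")
  d <- sqrt(dx^2 + dy^2)
  vapply(seq_along(qx), function(i) {
    di <- d[i, ]
    hit <- which(di < 1e-12)
    if (length(hit)) return(train$value[hit[1]])
    w <- 1 / di^power
    sum(w * train$value) / sum(w)
  }, numeric(1))
}

# ordinary kriging with an exponential variogram; sill/range fitted by a
# coarse least-squares on binned empirical semivariances, nugget 0
ok_predict <- function(train, qx, qy) {
  n <- nrow(train)
  if (n < 3) return(idw_predict(train, qx, qy, 2))
  dmat <- as.matrix(dist(cbind(train$x, train$y)))
  gam_emp <- 0.5 * outer(train$value, train$value, "-")^2
  ut <- upper.tri(dmat)
  h <- dmat[ut]
  g <- gam_emp[ut]
  sill0 <- max(var(train$value), 1e-12)
  ranges <- max(h) * c(0.1, 0.25, 0.5, 1, 2)
  sse <- vapply(ranges, function(r) {
    sum((g - sill0 * (1 - exp(-h / r)))^2)
  }, numeric(1))
  rng <- ranges[which.min(sse)]
  covfun <- function(d) sill0 * exp(-d / rng)
  C <- covfun(dmat)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  vapply(seq_along(qx), function(i) {
    d0 <- sqrt((train$x - qx[i])^2 + (train$y - qy[i])^2)
    hit <- which(d0 < 1e-12)
    if (length(hit)) return(train$value[hit[1]])
    sol <- tryCatch(solve(A, c(covfun(d0), 1)), error = function(e) NULL)
    if (is.null(sol)) return(idw_predict(train, qx[i], qy[i], 2))
    sum(sol[seq_len(n)] * train$value)
  }, numeric(1))
}

#' Smooth a plant growth trajectory by local linear regression
#'
#' For each evaluation day the `window` nearest observed time points are
#' fitted by ordinary least squares and the fit is evaluated at that day —
#' a local linear smoother with a 5-point window by default, used to read
#' root-architecture traits off corrected trajectories at a target day.
#' With fewer points than the window, a single global linear fit is used
#' and flagged.
#'
#' @param series Data frame with columns `day`, `value` (one plant).
#' @param window Number of nearest time points per local fit, default 5.
#' @param at_day Day at which the trait value is extracted, default 10.
#' @return Tibble `day`, `value`, `smoothed`, with attributes `value_at`
#'   (smoothed value at `at_day`) and `fallback` (TRUE when the global-fit
#'   fallback was used).
#' @export
smooth_trajectories <- function(series, window = 5, at_day = 10) {
  series <- as_tibble(series)
  stopifnot(all(c("day", "value") %in% names(series)))
  if (nrow(series) < 2) abort("need at least two time points")
  series <- dplyr::arrange(series, .data$day)
  fallback <- nrow(series) < window
  fit_local <- function(d0) {
    if (fallback) {
      f <- lm(value ~ day, data = series)
    } else {
      idx <- order(abs(series$day - d0))[seq_len(window)]
      f <- lm(value ~ day, data = series[idx, ])
    }
    unname(predict(f, tibble(day = d0)))
  }
  out <- series
  out$smoothed <- vapply(series$day, fit_local, numeric(1))
  attr(out, "value_at") <- fit_local(at_day)
  attr(out, "fallback") <- fallback
  if (fallback) {
    warn(sprintf(
      "only %d points for a %d-point window; global linear fit used",
      nrow(series), window
    ))
  }
  out
}
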
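#' Time series container
#'
#' A plain time-indexed scalar signal: strictly increasing times (h) and
#' values of equal length, with an optional label.
#'
#' @param times numeric, strictly increasing (h).
#' @param values numeric, same length.
#' @param label character label (signal name).
#' @return An object of class \code{"time_series"}.
#' @export
time_series <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat("<time_series>", x$label, "-", length(x$times), "points on [",
      min(x$times), ",", max(x$times), "] h\n")
  invisible(x)
}

#' @export
plot.time_series <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (h)", ylab = x$label, ...)
  invisible(x)
}

#' Thioflavin-T signal (polymerized mass proxy)
#'
#' ThT fluorescence reports total amyloid mass above a size threshold,
#' relatively independently of size. The signal is the first moment of
#' the size distribution restricted to sizes at or above
#' \code{threshold}; the default threshold is the model's nucleus size,
#' so the default signal equals M1(t).
#'
#' @param traj an \code{"agg_trajectory"}.
#' @param threshold minimal size contributing to the signal; \code{NULL}
#'   for the nucleus size.
#' @return A \code{\link{time_series}} (uM of polymerized mass).
#' @export
tht_signal <- function(traj, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0
  time_series(traj$times, .traj_moment(traj, 1, threshold = threshold),
              label = "ThT (M1 above threshold)")
}

#' Static light scattering signal (second moment)
#'
#' SLS is governed by the mass-weighted average polymer mass and is
#' modelled as the second moment M2(t) of the size distribution.
#'
#' @param traj an \code{"agg_trajectory"}.
#' @return A \code{\link{time_series}}.
#' @export
sls_signal <- function(traj) {
  time_series(traj$times, .traj_moment(traj, 2), label = "SLS (M2)")
}

#' Transitional parameters of a sigmoidal growth curve
#'
#' Extracts the descriptors used to summarize amyloid progress curves:
#' the maximal slope (by centered finite differences), the inflexion
#' time where it is attained, and the lag time, defined as the intercept
#' of the tangent at the inflexion point with the initial baseline.
#'
#' @param curve a \code{\link{time_series}} with at least 5 points and a
#'   positive net increase.
#' @return An object of class \code{"transition_params"}: a list with
#'   \code{lag_time}, \code{max_slope}, \code{inflexion_time}.
#' @examples
#' t <- seq(0, 20, by = 0.05)
#' ts <- time_series(t, 1 / (1 + exp(-1.5 * (t - 8))))
#' p <- transition_params(ts)    # max_slope ~ 1.5/4, lag ~ 8 - 2/1.5
#' @export
transition_params <- function(curve) {
  t <- curve$times; y <- curve$values
  n <- length(t)
  if (n < 5) stop("curve must have at least 5 points")
  if (!(max(y) - y[1] > 0) || !(y[n] - y[1] > 0))
    stop("no inflexion: curve has no positive total increase")
  slope <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  k <- which.max(slope)
  ms <- slope[k]
  if (!(ms > 0)) stop("no inflexion: curve is flat or decreasing")
  ti <- t[k + 1]
  baseline <- y[1]
  lag <- ti - (y[k + 1] - baseline) / ms
  structure(list(lag_time = lag, max_slope = ms, inflexion_time = ti),
            class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat("<transition_params> lag =", signif(x$lag_time, 4),
      "h, max slope =", signif(x$max_slope, 4),
      "/h, inflexion at", signif(x$inflexion_time, 4), "h\n")
  invisible(x)
}

# plateau value of a curve: mean of the last 5% of points
.plateau_value <- function(ts) {
  n <- length(ts$values)
  k <- max(1L, ceiling(0.05 * n))
  mean(ts$values[(n - k + 1L):n])
}

#' Coalescence diagnostic from paired mass and size signals
#'
#' If polymers coalesce, the mass-weighted size (SLS, proxy M2) keeps
#' growing after the polymerized mass (ThT, proxy M1) has reached its
#' plateau. The diagnostic is the gap between the plateau-crossing times
#' of the two normalized curves,
#' \code{t_plateau(M2) - t_plateau(M1)}; a near-zero gap indicates that
#' coalescence is negligible.
#'
#' @param m1,m2 \code{\link{time_series}} of the first and second moment
#'   signals on a common time grid.
#' @param plateau_frac fraction of the plateau value defining the
#'   crossing (default 0.95). The plateau value is the mean of the last
#'   5% of points.
#' @return Plateau-time gap in hours.
#' @export
coalescence_diagnostic <- function(m1, m2, plateau_frac = 0.95) {
  tp <- function(ts) {
    plat <- .plateau_value(ts)
    hit <- which(ts$values >= plateau_frac * plat)
    if (!length(hit) || plat <= 0)
      stop("plateau not reached at fraction ", plateau_frac)
    ts$times[hit[1]]
  }
  tp(m2) - tp(m1)
}
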
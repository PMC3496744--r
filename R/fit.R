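#' Experimental (or synthetic) kinetic curve
#'
#' A ThT-like polymerized-mass curve at a known initial precursor
#' concentration, the unit the fitting protocol consumes.
#'
#' @param times sampling times (h), strictly increasing.
#' @param values signal values (mass units or proportional).
#' @param w0 initial precursor concentration for this curve (uM).
#' @return An object of class \code{"experimental_curve"}.
#' @export
experimental_curve <- function(times, values, w0) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("signal must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 w0 = w0), class = "experimental_curve")
}

#' @export
print.experimental_curve <- function(x, ...) {
  cat("<experimental_curve> w0 =", x$w0, "uM,", length(x$times),
      "points on [", min(x$times), ",", max(x$times), "] h\n")
  invisible(x)
}

#' Fitting protocol configuration
#'
#' Settings for the multi-start CMA-ES least-squares protocol: a first
#' phase of \code{n_starts} independent runs from random points in the
#' (log10) search box, then \code{n_refine_starts} runs seeded at the
#' incumbent optimum with a smaller initial step. All parameters are
#' searched in log10 space because the rates span decades.
#'
#' @param n_starts number of independent first-phase starts.
#' @param n_refine_starts number of refinement starts at the incumbent.
#' @param max_evals CMA-ES evaluation budget per start.
#' @param sigma0 initial CMA-ES step (decades).
#' @param seed integer seed making the whole fit deterministic.
#' @param backend simulation backend, \code{"discrete"} or
#'   \code{"pde"}.
#' @param normalize curve normalization for the adimensioned error:
#'   \code{"plateau"} (mean of last 5% of points) or \code{"max"}.
#' @param bounds named list of \code{c(lower, upper)} log10 bounds per
#'   free parameter; defaults to \code{\link{polyq_fit_bounds}()}.
#' @param ftol CMA-ES stopping tolerance.
#' @return An object of class \code{"fit_config"}.
#' @export
fit_config <- function(n_starts = 50, n_refine_starts = 50,
                       max_evals = 2000, sigma0 = 0.6, seed = 1L,
                       backend = c("discrete", "pde"),
                       normalize = c("plateau", "max"),
                       bounds = polyq_fit_bounds(), ftol = 1e-10) {
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (!all(is.finite(unlist(bounds)))) stop("bounds must be finite")
  structure(list(n_starts = as.integer(n_starts),
                 n_refine_starts = as.integer(n_refine_starts),
                 max_evals = as.integer(max_evals), sigma0 = sigma0,
                 seed = as.integer(seed), backend = match.arg(backend),
                 normalize = match.arg(normalize), bounds = bounds,
                 ftol = ftol),
            class = "fit_config")
}

#' Default log10 search box for the PolyQ fit
#'
#' Bounds (in log10 of the natural units) for the six free PolyQ
#' parameters. The elongation breakpoints are fixed, as in the reference
#' configuration.
#' @return Named list of \code{c(lower, upper)} pairs.
#' @export
polyq_fit_bounds <- function() {
  list(k_act   = c(-2, 1),
       k_plus  = c(-2, 1.5),
       k_minus = c(-3, 1.5),
       k_on    = c(-3, 1),
       k_off   = c(-2, 1.5),
       tau_max = c(-3, 1))
}

#' Adimensioned L2 error between a simulation and a data curve
#'
#' Both curves are normalized by the data curve's plateau (or maximum)
#' value and the error is
#' \deqn{\sqrt{\sum_k (s_k - d_k)^2 / \sum_k d_k^2}}
#' over the data's (uniform) time grid. The error is invariant under a
#' joint rescaling of the signal axis. For simultaneous fits of several
#' curves, per-curve errors are aggregated as the root of the mean of
#' their squares.
#'
#' @param sim simulated curve: a \code{\link{time_series}} or a numeric
#'   vector already sampled at \code{data$times}.
#' @param data an \code{\link{experimental_curve}}.
#' @param normalize \code{"plateau"} or \code{"max"}.
#' @return The error (dimensionless fraction).
#' @export
adimensioned_l2_error <- function(sim, data, normalize = c("plateau", "max")) {
  normalize <- match.arg(normalize)
  s <- if (inherits(sim, "time_series")) {
    if (min(sim$times) > min(data$times) || max(sim$times) < max(data$times))
      stop("simulation must cover the data time range")
    stats::approx(sim$times, sim$values, xout = data$times)$y
  } else as.numeric(sim)
  d <- data$values
  ref <- if (normalize == "plateau")
    .plateau_value(time_series(data$times, d)) else max(d)
  if (!(ref != 0) || !sum((d / ref)^2) > 0) stop("data curve has zero norm")
  sqrt(sum((s - d)^2) / sum(d^2))
}

# simulate the PolyQ ThT curve for one parameter set / one w0
.polyq_tht <- function(params, times, backend = "discrete") {
  model <- polyq_model(params, backend = backend)
  tt <- times
  if (tt[1] > 0) tt <- c(0, tt)
  traj <- if (backend == "discrete")
    integrate_discrete(model, initial_state(model, w = params$w0),
                       times = tt, method = "rk4")
  else
    integrate_pde(model, continuous_state(model, w = params$w0), times = tt)
  ts <- tht_signal(traj)
  if (length(tt) != length(times)) ts <- time_series(times, ts$values[-1])
  ts
}

.polyq_objective <- function(curves, i0, cfg, fixed = list()) {
  nms <- names(cfg$bounds)
  if (cfg$backend != "discrete" || i0 < 1)
    return(.polyq_objective_slow(curves, i0, cfg, fixed))
  # fast path: one template model; per evaluation only the scalar rates
  # and the tau vector (linear in tau_max) are swapped into the tables
  p0 <- polyq_params(i0 = i0)
  template <- polyq_model(p0, backend = "discrete")
  tab <- template$tables
  tau_shape <- tab$tau / p0$tau_max
  sizes <- tab$sizes
  n <- length(sizes)
  prep <- lapply(curves, function(cu) {
    tt <- cu$times
    pad <- tt[1] > 0
    list(times = if (pad) c(0, tt) else tt, pad = pad,
         denom = sum(cu$values^2), vals = cu$values,
         thr_idx = which(sizes >= i0))
  })
  function(logpar) {
    vals <- as.list(10^logpar)
    names(vals) <- nms
    vals[names(fixed)] <- fixed
    tab$k_act <- vals$k_act; tab$k_plus <- vals$k_plus
    tab$k_minus <- vals$k_minus; tab$k_on <- vals$k_on
    tab$k_off <- vals$k_off
    tab$tau <- tau_shape * vals$tau_max
    errs <- vapply(curves, function(cu) NA_real_, numeric(1))
    for (k in seq_along(curves)) {
      pr <- prep[[k]]
      y0 <- c(curves[[k]]$w0, 0, 0, double(n))
      res <- tryCatch(
        integrate_discrete_cpp(y0, pr$times, tab, 0.0),
        error = function(e) NULL)
      if (is.null(res)) return(1e10)
      cmat <- res$states[, -(1:3), drop = FALSE]
      sim <- as.numeric(cmat %*% as.numeric(sizes))
      if (pr$pad) sim <- sim[-1]
      errs[k] <- sqrt(sum((sim - pr$vals)^2) / pr$denom)
    }
    if (any(!is.finite(errs))) return(1e10)
    sqrt(mean(errs^2))
  }
}

.polyq_objective_slow <- function(curves, i0, cfg, fixed = list()) {
  nms <- names(cfg$bounds)
  function(logpar) {
    vals <- as.list(10^logpar)
    names(vals) <- nms
    vals[names(fixed)] <- fixed
    errs <- vapply(curves, function(cu) {
      p <- do.call(polyq_params, c(vals, list(i0 = i0, w0 = cu$w0)))
      sim <- tryCatch(.polyq_tht(p, cu$times, backend = cfg$backend),
                      error = function(e) NULL)
      if (is.null(sim)) return(NA_real_)
      adimensioned_l2_error(sim, cu, normalize = cfg$normalize)
    }, numeric(1))
    if (any(!is.finite(errs))) return(1e10)
    sqrt(mean(errs^2))
  }
}

.run_multistart <- function(obj, cfg) {
  lower <- vapply(cfg$bounds, `[`, numeric(1), 1)
  upper <- vapply(cfg$bounds, `[`, numeric(1), 2)
  n <- length(lower)
  trace <- list()
  best <- list(value = Inf)
  for (s in seq_len(cfg$n_starts)) {
    x0 <- lower + stats::runif(n) * (upper - lower)
    r <- cmaes_minimize(obj, x0, cfg$sigma0, lower, upper,
                        max_evals = cfg$max_evals, ftol = cfg$ftol)
    trace[[length(trace) + 1]] <- c(phase = 1, start = s, value = r$value,
                                    evals = r$evals)
    if (r$value < best$value) best <- r
  }
  for (s in seq_len(cfg$n_refine_starts)) {
    r <- cmaes_minimize(obj, best$par, cfg$sigma0 / 3, lower, upper,
                        max_evals = cfg$max_evals, ftol = cfg$ftol)
    trace[[length(trace) + 1]] <- c(phase = 2, start = s, value = r$value,
                                    evals = r$evals)
    if (r$value < best$value) best <- r
  }
  best$trace <- do.call(rbind, trace)
  best
}

#' Fit the PolyQ model to kinetic curves
#'
#' The estimation protocol: adimensioned L2 least squares on
#' polymerized-mass curves, minimized by multi-start CMA-ES in log10
#' parameter space (a first phase of independent random starts, then a
#' refinement phase seeded at the incumbent). In \code{"simultaneous"}
#' mode one shared parameter set is fitted to all curves (each curve
#' keeping its own \code{w0}); in \code{"separate"} mode each curve is
#' fitted independently and the spread of the per-curve optima is
#' reported. Deterministic given \code{config$seed}.
#'
#' @param curves list of \code{\link{experimental_curve}} objects.
#' @param i0 nucleus size of the fitted model family.
#' @param mode \code{"simultaneous"} or \code{"separate"}.
#' @param config a \code{\link{fit_config}}.
#' @param fixed named list of parameters to hold fixed (natural scale)
#'   instead of fitting.
#' @return An object of class \code{"agg_fit"} with the best parameters
#'   (\code{coef()}), per-curve and global errors, the optimizer trace
#'   and the data; methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @export
fit_polyq <- function(curves, i0, mode = c("simultaneous", "separate"),
                      config = fit_config(), fixed = list()) {
  mode <- match.arg(mode)
  if (inherits(curves, "experimental_curve")) curves <- list(curves)
  if (!length(curves)) stop("at least one curve is required")
  set.seed(config$seed)
  nms <- names(config$bounds)
  if (mode == "simultaneous") {
    obj <- .polyq_objective(curves, i0, config, fixed)
    best <- .run_multistart(obj, config)
    par <- stats::setNames(10^best$par, nms)
    per_curve <- vapply(curves, function(cu) {
      .polyq_objective(list(cu), i0, config, fixed)(best$par)
    }, numeric(1))
    global <- best$value
    par_matrix <- NULL
  } else {
    fits <- lapply(curves, function(cu) {
      obj <- .polyq_objective(list(cu), i0, config, fixed)
      .run_multistart(obj, config)
    })
    par_matrix <- do.call(rbind, lapply(fits, function(f)
      stats::setNames(10^f$par, nms)))
    per_curve <- vapply(fits, `[[`, numeric(1), "value")
    global <- sqrt(mean(per_curve^2))
    par <- par_matrix[which.min(per_curve), ]
    best <- fits[[which.min(per_curve)]]
  }
  structure(list(par = par, log10_par = log10(par), i0 = i0, mode = mode,
                 per_curve_errors = per_curve, global_error = global,
                 par_matrix = par_matrix, trace = best$trace,
                 fixed = fixed, config = config, curves = curves),
            class = "agg_fit")
}

#' @export
print.agg_fit <- function(x, ...) {
  cat("<agg_fit> PolyQ fit, i0 =", x$i0, ", mode =", x$mode, "\n")
  cat("  global adimensioned L2 error:", signif(x$global_error, 4), "\n")
  cat("  parameters:\n")
  print(signif(x$par, 4))
  invisible(x)
}

#' @export
coef.agg_fit <- function(object, ...) object$par

#' @export
summary.agg_fit <- function(object, ...) {
  cat("PolyQ kinetic fit (", object$mode, " mode), nucleus size i0 = ",
      object$i0, "\n", sep = "")
  cat("Curves: ", length(object$curves), " (w0 = ",
      paste(vapply(object$curves, `[[`, numeric(1), "w0"), collapse = ", "),
      " uM)\n", sep = "")
  cat("Per-curve errors: ", paste(signif(object$per_curve_errors, 3),
                                  collapse = ", "), "\n", sep = "")
  cat("Global error: ", signif(object$global_error, 4), "\n", sep = "")
  cat("Optimizer: ", nrow(object$trace), " CMA-ES starts, best value ",
      signif(min(object$trace[, "value"]), 4), "\n", sep = "")
  if (!is.null(object$par_matrix)) {
    cat("Across-curve parameter spread (sd of log10):\n")
    print(signif(apply(log10(object$par_matrix), 2, stats::sd), 3))
  }
  cat("Best parameters:\n")
  print(signif(object$par, 5))
  invisible(object)
}

#' @export
predict.agg_fit <- function(object, w0, times, ...) {
  vals <- as.list(object$par)
  vals[names(object$fixed)] <- object$fixed
  p <- do.call(polyq_params, c(vals, list(i0 = object$i0, w0 = w0)))
  .polyq_tht(p, times, backend = object$config$backend)
}

#' @export
residuals.agg_fit <- function(object, ...) {
  lapply(object$curves, function(cu) {
    sim <- predict(object, w0 = cu$w0, times = cu$times)
    time_series(cu$times, sim$values - cu$values, label = "residual")
  })
}

#' @export
plot.agg_fit <- function(x, ...) {
  rng_t <- range(unlist(lapply(x$curves, `[[`, "times")))
  rng_y <- range(unlist(lapply(x$curves, `[[`, "values")))
  plot(NA, xlim = rng_t, ylim = rng_y, xlab = "time (h)",
       ylab = "polymerized mass signal", ...)
  for (k in seq_along(x$curves)) {
    cu <- x$curves[[k]]
    graphics::points(cu$times, cu$values, col = k, pch = 20, cex = 0.5)
    sim <- predict(x, w0 = cu$w0, times = cu$times)
    graphics::lines(sim$times, sim$values, col = k)
  }
  invisible(x)
}

#' Nucleus-size model selection
#'
#' Runs the simultaneous fit for each candidate nucleus size and
#' tabulates the global adimensioned error; the selected size is the
#' candidate with the smallest error, ties broken toward the smaller
#' nucleus. Each candidate's fit derives its own seed from
#' \code{config$seed}.
#'
#' @param curves list of \code{\link{experimental_curve}} objects.
#' @param i0_candidates integer candidates (at least one).
#' @param config a \code{\link{fit_config}}.
#' @param fixed named list of fixed parameters.
#' @return A data frame \code{(i0, global_error)} of class
#'   \code{"i0_selection"} with attribute \code{"best"}.
#' @export
select_nucleus_size <- function(curves, i0_candidates = 1:3,
                                config = fit_config(), fixed = list()) {
  errs <- vapply(seq_along(i0_candidates), function(k) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * k
    fit_polyq(curves, i0 = i0_candidates[k], mode = "simultaneous",
              config = cfg, fixed = fixed)$global_error
  }, numeric(1))
  out <- data.frame(i0 = i0_candidates, global_error = errs)
  best <- i0_candidates[order(errs, i0_candidates)][1]
  structure(out, best = best, class = c("i0_selection", "data.frame"))
}

#' @export
print.i0_selection <- function(x, ...) {
  cat("Nucleus-size selection (global adimensioned L2 error):\n")
  print.data.frame(x)
  cat("Selected i0 =", attr(x, "best"), "\n")
  invisible(x)
}

#' Export a fit result to JSON
#'
#' @param fit an \code{"agg_fit"}.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(i0 = fit$i0, mode = fit$mode, par = as.list(fit$par),
         per_curve_errors = fit$per_curve_errors,
         global_error = fit$global_error, seed = fit$config$seed),
    path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
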
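#' PolyQ aggregation model parameters
#'
#' Parameters of the polyglutamine (PolyQ41) application: an inert
#' precursor W (GST-tagged peptide) is irreversibly activated by
#' enzymatic cleavage into a native monomer V (rate \code{k_act}), which
#' exchanges with an aggregation-prone conformer V*
#' (\code{k_plus}/\code{k_minus}). Nucleation produces the smallest
#' stable aggregate of size \code{i0}; for \code{i0 = 1} the nucleus is
#' itself a monomeric conformer C1 in first-order exchange with V*
#' (rates \code{k_on}, \code{k_off}), and growth initiates when V* adds
#' to C1 at rate \code{tau(1) v_star}. Elongation follows the
#' tent-shaped piecewise-linear rate with breakpoints \code{x1, x2, x3}
#' and plateau \code{tau_max}; fragmentation, coalescence and
#' degradation are absent by construction (the experimental size
#' distribution is insensitive to sonication, and the ThT and SLS
#' signals plateau simultaneously).
#'
#' Default values are the package's reference configuration: an
#' order-of-magnitude realistic setting for tens-of-uM PolyQ kinetics
#' over a two-day reaction, documented in the methods vignette.
#'
#' @param k_act activation rate W -> V (1/h).
#' @param k_plus,k_minus conformational exchange V <-> V* (1/h).
#' @param k_on nucleation rate (1/h when \code{i0 = 1}, else
#'   1/(uM^(i0-1) h)).
#' @param k_off nucleus dissociation rate (1/h).
#' @param i0 nucleus size.
#' @param tau_max elongation plateau rate (1/(uM h)).
#' @param x1,x2,x3 elongation-rate breakpoints (monomer units).
#' @param w0 initial precursor concentration (uM).
#' @return An object of class \code{"polyq_params"}.
#' @export
polyq_params <- function(k_act = 0.15, k_plus = 0.4, k_minus = 0.2,
                         k_on = 0.02, k_off = 2.0, i0 = 1,
                         tau_max = 0.3, x1 = 5, x2 = 15, x3 = 30,
                         w0 = 40) {
  p <- list(k_act = k_act, k_plus = k_plus, k_minus = k_minus,
            k_on = k_on, k_off = k_off, i0 = as.integer(i0),
            tau_max = tau_max, x1 = x1, x2 = x2, x3 = x3, w0 = w0)
  if (any(unlist(p) < 0)) stop("all PolyQ parameters must be >= 0")
  structure(p, class = "polyq_params")
}

#' Build the PolyQ model
#'
#' Assembles a \code{\link{discrete_model}} (or \code{\link{pde_model}})
#' from \code{\link{polyq_params}}: no fragmentation, no coalescence, no
#' degradation; the initial state holds only precursor
#' (\code{w = w0}, everything else zero — no seeding). The truncation
#' \code{N_max} defaults to just above the breakpoint \code{x3}, beyond
#' which the elongation rate vanishes and no mass can travel.
#'
#' A nucleus size of zero (polymerization directly from V* with no
#' stable nucleus) is rejected: that scheme cannot reproduce the
#' observed lag kinetics. For reproducing that negative result it can be
#' forced with \code{no_nucleus = TRUE}, which builds direct
#' dimerization at the elongation rate.
#'
#' @param params a \code{"polyq_params"}.
#' @param backend \code{"discrete"} or \code{"pde"}.
#' @param N_max truncation size for the discrete backend.
#' @param grid optional \code{\link{size_grid}} for the PDE backend.
#' @param no_nucleus explicit override building the nucleus-free scheme.
#' @return A model object (discrete or PDE) with the PolyQ parameters
#'   attached as attribute \code{"polyq_params"}.
#' @export
polyq_model <- function(params, backend = c("discrete", "pde"),
                        N_max = ceiling(params$x3) + 10, grid = NULL,
                        no_nucleus = FALSE) {
  backend <- match.arg(backend)
  if (!inherits(params, "polyq_params")) stop("params must be polyq_params")
  tau <- rate_piecewise_linear(params$x1, params$x2, params$x3, params$tau_max)
  if (params$i0 == 0 && !no_nucleus)
    stop("i0 = 0 (no nucleus) is rejected: it cannot fit lag-phase kinetics; ",
         "set no_nucleus = TRUE to force the scheme")
  if (no_nucleus) {
    i0 <- 2L; n_nuc <- 2; k_on <- tau(1); k_off <- 0
  } else {
    i0 <- params$i0; n_nuc <- params$i0
    k_on <- params$k_on; k_off <- params$k_off
  }
  m <- if (backend == "discrete") {
    discrete_model(i0 = i0, N_max = N_max, k_on = k_on, k_off = k_off,
                   tau = tau, k_plus = params$k_plus,
                   k_minus = params$k_minus, k_act = params$k_act,
                   n_nuc = n_nuc)
  } else {
    if (is.null(grid)) grid <- size_grid(max(i0, 1), ceiling(params$x3) + 10, 80)
    pde_model(grid, k_on = k_on, k_off = k_off, tau = tau,
              k_plus = params$k_plus, k_minus = params$k_minus,
              k_act = params$k_act, n_nuc = n_nuc)
  }
  attr(m, "polyq_params") <- params
  class(m) <- c("polyq_model", class(m))
  m
}

#' Simulate the PolyQ model
#'
#' Integrates a PolyQ model from its unseeded initial condition
#' (\code{w = w0}, all else zero). The precursor decays exactly as
#' \code{w0 exp(-k_act t)} (its equation is decoupled).
#'
#' @param model a \code{"polyq_model"}.
#' @param times output times (h).
#' @param ... passed to \code{\link{integrate_discrete}} /
#'   \code{\link{integrate_pde}} (e.g. \code{method}).
#' @return An \code{"agg_trajectory"}.
#' @export
simulate_polyq <- function(model, times, ...) {
  p <- attr(model, "polyq_params")
  if (inherits(model, "discrete_model")) {
    integrate_discrete(model, initial_state(model, w = p$w0),
                       times = times, ...)
  } else {
    integrate_pde(model, continuous_state(model, w = p$w0),
                  times = times, ...)
  }
}

#' Lag-phase monomer approximation check
#'
#' During the lag phase the polymer sink terms in the monomer equations
#' are negligible, so W, V, V* (and the nucleus pool) follow the reduced
#' monomer-only system in which elongation is switched off. This
#' function integrates that reduced system and returns the maximal
#' relative deviation of V* inside the lag window (ThT below 5% of its
#' plateau), together with the deviation after the lag ends, which must
#' be larger once polymerization consumes monomer.
#'
#' @param traj a trajectory of \code{model} covering the full reaction.
#' @param model the \code{"polyq_model"} (discrete backend) that
#'   produced it.
#' @return A list with \code{max_dev_lag}, \code{max_dev_post} and
#'   \code{lag_end_time}.
#' @export
lag_phase_check <- function(traj, model) {
  tht <- tht_signal(traj)
  plat <- .plateau_value(tht)
  if (!(plat > 0)) stop("plateau undefined: no polymerized mass formed")
  in_lag <- tht$values < 0.05 * plat
  if (!any(in_lag)) stop("trajectory does not cover the lag phase")
  lag_idx <- seq_len(which.min(in_lag) - 1L)   # leading run below 5%
  if (all(in_lag)) lag_idx <- seq_along(in_lag)
  tb <- model$tables
  red_rhs <- function(t, y, p) {
    nuc <- tb$k_on * max(y[3], 0)^tb$n_nuc
    dis <- tb$k_off * y[4]
    list(c(-tb$k_act * y[1],
           tb$k_act * y[1] - tb$k_plus * y[2] + tb$k_minus * y[3],
           tb$k_plus * y[2] - tb$k_minus * y[3] - tb$i0 * (nuc - dis),
           nuc - dis))
  }
  p0 <- attr(model, "polyq_params")
  red <- deSolve::lsoda(c(p0$w0, 0, 0, 0), traj$times, red_rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  vs_red <- red[, 4]
  floor_val <- 1e-6 * max(vs_red)
  dev <- abs(traj$v_star - vs_red) / pmax(vs_red, floor_val)
  post_idx <- setdiff(seq_along(dev), lag_idx)
  list(max_dev_lag = max(dev[lag_idx]),
       max_dev_post = if (length(post_idx)) max(dev[post_idx]) else NA_real_,
       lag_end_time = traj$times[max(lag_idx)])
}
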
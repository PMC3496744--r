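#' Knowles-type breakable-filament configuration
#'
#' Parameters of the classic breakable-filament model: constant
#' (size-independent) elongation at rate \code{k_p} per fibril end with
#' \code{n_ends = 2} growing ends, per-bond fragmentation at rate
#' \code{k_f} with sub-nucleus fragments dissolving to monomer, nucleus
#' size \code{n_c = 2} with nucleation rate \code{k_n}, no
#' depolymerization, degradation or coalescence. Under these
#' assumptions the infinite system closes by summation into two coupled
#' ODEs for the polymerized mass \code{M} and polymer number \code{P}.
#'
#' @param k_p elongation rate per end (1/(uM h)).
#' @param k_f per-bond fragmentation rate (1/h).
#' @param k_n nucleation rate (1/(uM^(n_c-1) h)).
#' @param m0 initial monomer concentration (uM).
#' @param n_c nucleus size (2 in the classic model).
#' @param n_ends number of growing ends per fibril.
#' @return An object of class \code{"knowles_params"}.
#' @export
knowles_params <- function(k_p = 5, k_f = 4e-3, k_n = 1e-5, m0 = 10,
                           n_c = 2, n_ends = 2) {
  p <- list(k_p = k_p, k_f = k_f, k_n = k_n, m0 = m0,
            n_c = as.integer(n_c), n_ends = n_ends)
  if (any(unlist(p) < 0)) stop("all parameters must be >= 0")
  structure(p, class = "knowles_params")
}

#' Two-moment reduction of the breakable-filament model
#'
#' \code{knowles_moment_rhs()} evaluates the closed moment system
#' \deqn{dP/dt = k_f [M - (2 n_c - 1) P] + k_n m^{n_c}}
#' \deqn{dM/dt = n_{ends} k_p m P + n_c k_n m^{n_c} - n_c (n_c - 1) k_f P}
#' \deqn{dm/dt = -dM/dt}
#' where \code{m} is free monomer, \code{M} polymerized mass and
#' \code{P} polymer number. \code{knowles_moments()} integrates it.
#'
#' @param m,M,P current monomer, mass and number concentrations (uM).
#' @param params a \code{"knowles_params"}.
#' @return \code{knowles_moment_rhs}: numeric \code{c(dm, dM, dP)};
#'   \code{knowles_moments}: a data frame with columns
#'   \code{t, m, M, P}.
#' @export
knowles_moment_rhs <- function(m, M, P, params) {
  nc <- params$n_c
  nuc <- params$k_n * m^nc
  dP <- params$k_f * (M - (2 * nc - 1) * P) + nuc
  dM <- params$n_ends * params$k_p * m * P + nc * nuc -
    nc * (nc - 1) * params$k_f * P
  c(dm = -dM, dM = dM, dP = dP)
}

#' @rdname knowles_moment_rhs
#' @param times output times (h).
#' @param m0,M0,P0 initial conditions (default: all monomer).
#' @export
knowles_moments <- function(params, times, m0 = params$m0, M0 = 0, P0 = 0) {
  fn <- function(t, y, p) list(unname(knowles_moment_rhs(y[1], y[2], y[3], params)))
  sol <- deSolve::lsoda(c(m0, M0, P0), times, fn, parms = NULL,
                        rtol = 1e-10, atol = 1e-13)
  data.frame(t = sol[, 1], m = sol[, 2], M = sol[, 3], P = sol[, 4])
}

#' Discrete and PDE models for the Knowles configuration
#'
#' \code{knowles_discrete_model()} builds the exact truncated discrete
#' system under the breakable-filament assumptions (the brute-force
#' oracle); \code{knowles_pde_model()} builds the corresponding
#' continuum model with constant transport speed, linear-in-size
#' fragmentation and the QSS nucleation boundary at \code{n_c}. In both,
#' all monomer starts as the elongating species
#' (\code{v_star = m0}; there is no precursor or exchange).
#'
#' @param params a \code{"knowles_params"}.
#' @param N_max truncation size for the discrete oracle; the
#'   recommendation is about 10x the expected mean size
#'   \code{sqrt(n_ends k_p m0 / k_f)}.
#' @return A \code{"discrete_model"} / \code{"pde_model"}.
#' @export
knowles_discrete_model <- function(params, N_max) {
  discrete_model(i0 = params$n_c, N_max = N_max,
                 k_on = params$k_n, k_off = 0,
                 tau = rate_constant(params$n_ends * params$k_p),
                 frag = fragmentation_kernel("linear_bonds", params$k_f),
                 n_nuc = params$n_c)
}

#' @rdname knowles_discrete_model
#' @param grid a \code{\link{size_grid}} starting at \code{n_c}.
#' @export
knowles_pde_model <- function(params, grid) {
  pde_model(grid, k_on = params$k_n, k_off = 0,
            tau = rate_constant(params$n_ends * params$k_p),
            frag = fragmentation_kernel("linear_bonds", params$k_f),
            n_nuc = params$n_c)
}

#' Expected stationary mean size of the Knowles configuration
#'
#' The balance of elongation and fragmentation sets the quasi-stationary
#' mean polymer size at approximately
#' \code{sqrt(n_ends k_p m0 / k_f)}; its reciprocal is the continuum
#' small parameter eps.
#' @param params a \code{"knowles_params"}.
#' @export
knowles_mean_size <- function(params) {
  sqrt(params$n_ends * params$k_p * params$m0 / params$k_f)
}

# observable extraction that also understands moment data frames
.obs_values <- function(obj, what, times) {
  if (inherits(obj, "agg_trajectory")) {
    w <- switch(what, M1 = "M1", mean_size = "mean_size", monomer = "monomer")
    ts <- observable_series(obj, w)
    stats::approx(ts$times, ts$values, xout = times)$y
  } else if (is.data.frame(obj) && all(c("t", "m", "M", "P") %in% names(obj))) {
    vals <- switch(what, M1 = obj$M,
                   mean_size = ifelse(obj$P > 0, obj$M / obj$P, NA_real_),
                   monomer = obj$m)
    stats::approx(obj$t, vals, xout = times)$y
  } else stop("unsupported trajectory object")
}

.traj_times <- function(obj) if (inherits(obj, "agg_trajectory")) obj$times else obj$t

#' Relative L2 distance between two model trajectories
#'
#' Interpolates both trajectories onto their common time range (using
#' the reference trajectory's grid) and returns
#' \eqn{\|a - b\|_2 / \|b\|_2} for the chosen observable. Mean size is
#' M1/M0. Accepts \code{"agg_trajectory"} objects and the moment data
#' frames of \code{\link{knowles_moments}}; \code{b} is the reference.
#'
#' @param traj_a,traj_b trajectories to compare (\code{traj_b} is the
#'   reference in the denominator).
#' @param observable \code{"M1"}, \code{"mean_size"} or
#'   \code{"monomer"}.
#' @return The relative L2 error (dimensionless fraction).
#' @export
compare_models <- function(traj_a, traj_b,
                           observable = c("M1", "mean_size", "monomer")) {
  observable <- match.arg(observable)
  ta <- .traj_times(traj_a); tb_t <- .traj_times(traj_b)
  times <- tb_t[tb_t >= max(ta[1], tb_t[1]) & tb_t <= min(max(ta), max(tb_t))]
  a <- .obs_values(traj_a, observable, times)
  b <- .obs_values(traj_b, observable, times)
  ok <- is.finite(a) & is.finite(b)
  if (!sum(b[ok]^2) > 0) stop("reference trajectory has zero norm")
  sqrt(sum((a[ok] - b[ok])^2) / sum(b[ok]^2))
}
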
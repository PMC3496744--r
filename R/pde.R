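#' Uniform size grid for the continuous model
#'
#' Finite-volume grid on \code{[x0, x_max]} with \code{n_cells} uniform
#' cells; \code{x0} is the nucleus size (left boundary of the
#' continuum).
#'
#' @param x0 left boundary (size units), the nucleus size.
#' @param x_max right boundary.
#' @param n_cells number of cells.
#' @return An object of class \code{"size_grid"} with \code{edges},
#'   \code{centers} and spacing \code{dx}.
#' @export
size_grid <- function(x0, x_max, n_cells) {
  if (x0 >= x_max) stop("x0 must be < x_max")
  if (n_cells < 2) stop("n_cells must be >= 2")
  edges <- seq(x0, x_max, length.out = n_cells + 1)
  structure(list(x0 = x0, x_max = x_max, n = as.integer(n_cells),
                 dx = edges[2] - edges[1], edges = edges,
                 centers = (edges[-1] + edges[-(n_cells + 1)]) / 2),
            class = "size_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat("<size_grid> [", x$x0, ",", x$x_max, "] in", x$n,
      "cells, dx =", signif(x$dx, 4), "\n")
  invisible(x)
}

# Conservative allocation of fragmentation daughters of a continuum
# parent of size X onto target intervals (lo_k, hi_k) represented at
# size x_rep_k; mass below the first interval is returned as the
# monomer share. Exact mass conservation by construction.
.frag_mass_cdf <- function(kernel, X, y) {
  y <- pmin(pmax(y, 0), X)
  switch(kernel$kind,
    linear_bonds = ,
    uniform = y^2 / X,
    mechanical = 4 * y^3 / X^2 - 3 * y^4 / X^3)
}

.frag_alloc_row <- function(kernel, X, lo, hi, xrep) {
  g <- numeric(length(lo))
  mono <- .frag_mass_cdf(kernel, X, lo[1])
  mass <- .frag_mass_cdf(kernel, X, hi) - .frag_mass_cdf(kernel, X, lo)
  mass[mass < 0] <- 0
  list(g = mass / xrep, mono = mono)
}

#' Continuous (PDE) kinetic model
#'
#' The size-structured continuum limit of \code{\link{discrete_model}}:
#' monomer pools W, V, V* coupled to a number density \eqn{u(t, x)} on a
#' size grid, with transport at speed \eqn{\tau(x) V^* - d(x)}
#' (first-order upwind), degradation, mass-conservative fragmentation
#' and coalescence operators, and a quasi-steady-state (QSS) nucleation
#' boundary at \code{x0}: the nucleus concentration is slaved to
#' \deqn{c_{QSS} = k_{on} (V^*)^{n_{nuc}} / (k_{off} + \tau(x_0) V^*)}
#' and feeds the density through the advective in-flux
#' \eqn{J = \tau(x_0) V^* c_{QSS}} deposited in the first cell. The
#' matching monomer sink is \eqn{x_{c1} J} (first cell center), which
#' makes the scheme's global mass balance exact by construction. When
#' the transport speed at \code{x0} is negative, the upwind outflow is
#' returned to V* as nucleus dissociation.
#'
#' The model is simulated in physical size units (x = monomer count);
#' the small parameter eps = 1/(mean polymer size) is reported as a
#' diagnostic of the continuum approximation, not used as an input.
#'
#' @inheritParams discrete_model
#' @param grid a \code{\link{size_grid}}; \code{grid$x0} plays the role
#'   of the nucleus size.
#' @param keep_ratio_term retain the boundary-density correction term
#'   \eqn{(d(x_0) - \tau(x_0) V^*)\, u(t, x_0)} in the V* equation
#'   (negligible in the asymptotic regime; off by default).
#' @return An object of class \code{c("pde_model", "agg_model")}.
#' @export
pde_model <- function(grid, k_on, k_off,
                      tau = rate_constant(0), d = rate_constant(0),
                      gamma = rate_constant(0),
                      frag = NULL, coag = NULL,
                      k_plus = 0, k_minus = 0, k_act = 0,
                      n_nuc = 2, keep_ratio_term = FALSE) {
  if (!inherits(grid, "size_grid")) stop("grid must be a size_grid")
  for (r in c(k_on, k_off, k_plus, k_minus, k_act))
    if (r < 0) stop("all rate constants must be >= 0")
  m <- structure(list(grid = grid, x0 = grid$x0, n_nuc = n_nuc,
                      k_on = k_on, k_off = k_off,
                      k_plus = k_plus, k_minus = k_minus, k_act = k_act,
                      tau = tau, d = d, gamma = gamma,
                      frag = frag, coag = coag,
                      keep_ratio_term = keep_ratio_term),
                 class = c("pde_model", "agg_model"))
  m$tables <- .pde_tables(m)
  m
}

.pde_tables <- function(m) {
  g <- m$grid
  xc <- g$centers; xe <- g$edges; n <- g$n
  tb <- list(
    n = n, dx = g$dx, xc = xc, xe = xe,
    tau_c = m$tau(xc), tau_e = m$tau(xe),
    d_c = m$d(xc), d_e = m$d(xe),
    gamma_c = m$gamma(xc),
    tau_x0 = m$tau(g$x0), d_x0 = m$d(g$x0),
    frag_on = FALSE, coag_on = FALSE)
  if (!is.null(m$frag) && m$frag$k_f > 0) {
    tb$frag_on <- TRUE
    B <- m$frag$k_f * pmax(xc - 1, 0)
    B[xc < 2 * m$frag$min_fragment] <- 0
    tb$B <- B
    G <- matrix(0, n, n)
    fmono <- numeric(n)
    for (p in seq_len(n)) {
      if (B[p] == 0) next
      al <- .frag_alloc_row(m$frag, xc[p], xe[-(n + 1)], xe[-1], xc)
      G[p, ] <- al$g
      fmono[p] <- al$mono
    }
    tb$G <- G; tb$fmono <- fmono
  }
  if (!is.null(m$coag)) {
    if (n > 512) stop("coalescence on the grid is limited to n_cells <= 512")
    tb$coag_on <- TRUE
    tb$K <- outer(xc, xc, m$coag$fn)
    sz <- outer(xc, xc, "+")
    tk <- findInterval(sz, xe, rightmost.closed = TRUE)
    tk[sz > g$x_max] <- 0L           # zero-flux beyond x_max: suppressed
    tb$coag_target <- tk
    tb$coag_size <- sz
  }
  tb
}

#' Continuous model state
#'
#' @param model a \code{"pde_model"}.
#' @param w,v,v_star monomer pools (uM).
#' @param u number density over the grid cells (uM per unit size);
#'   defaults to zero.
#' @param t time (h).
#' @return An object of class \code{"continuous_state"}.
#' @export
continuous_state <- function(model, w = 0, v = 0, v_star = 0, u = NULL, t = 0) {
  n <- model$grid$n
  if (is.null(u)) u <- double(n)
  if (length(u) != n) stop("u must have length n_cells")
  structure(list(t = t, w = w, v = v, v_star = v_star, u = as.double(u)),
            class = "continuous_state", grid = model$grid)
}

#' @rdname state_moment
#' @export
state_moment.continuous_state <- function(state, order) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  g <- attr(state, "grid")
  sum(g$centers^order * state$u) * g$dx
}

#' @rdname state_moment
#' @export
continuous_moment <- function(state, order) state_moment(state, order)

#' Quasi-steady-state nucleation boundary flux
#'
#' The QSS nucleus concentration and the resulting number and mass
#' fluxes feeding the density at the left boundary \code{x0}:
#' \code{c_qss = k_on v_star^n_nuc / (k_off + tau(x0) v_star)},
#' \code{number_flux = tau(x0) v_star c_qss} and
#' \code{mass_flux = x_c1 * number_flux} with \code{x_c1} the first cell
#' center (the mass actually deposited by the scheme, fixed so that the
#' global mass balance holds exactly).
#'
#' @param v_star activated monomer concentration (uM).
#' @param model a \code{"pde_model"}.
#' @return A list with \code{c_qss}, \code{number_flux},
#'   \code{mass_flux}.
#' @export
nucleation_boundary_flux <- function(v_star, model) {
  if (v_star < 0) v_star <- 0
  tb <- model$tables
  num <- model$k_on * v_star^model$n_nuc
  denom <- model$k_off + tb$tau_x0 * v_star
  if (model$k_off == 0) {
    # limit of the QSS expression: every nucleus formed elongates
    c_qss <- if (denom > 0) num / denom else 0
    J <- num
  } else {
    c_qss <- num / denom
    J <- tb$tau_x0 * v_star * c_qss
  }
  list(c_qss = c_qss, number_flux = J, mass_flux = tb$xc[1] * J)
}

# Core derivative: y = c(w, v, v_star, u). Returns derivative plus the
# CFL-relevant maximal speed as an attribute.
.pde_deriv <- function(y, model, tb) {
  n <- tb$n; dx <- tb$dx
  w <- y[1]; v <- y[2]; vs <- max(y[3], 0); u <- y[-(1:3)]
  dw <- -model$k_act * w
  dv <- model$k_act * w - model$k_plus * v + model$k_minus * y[3]
  dvs <- model$k_plus * v - model$k_minus * y[3]
  du <- numeric(n)
  # transport: first-order upwind on interior edges, zero flux at x_max
  s_e <- tb$tau_e * vs - tb$d_e                 # speeds at edges
  si <- s_e[2:n]                                # interior edges
  Fi <- ifelse(si > 0, si * u[1:(n - 1)], si * u[2:n])
  du[1:(n - 1)] <- du[1:(n - 1)] - Fi / dx
  du[2:n] <- du[2:n] + Fi / dx
  dvs <- dvs - sum(Fi) * dx                     # net elongation/depoly sink
  # left boundary: QSS nucleation in-flux; upwind outflow dissolves
  nf <- nucleation_boundary_flux(vs, model)
  J <- nf$number_flux
  du[1] <- du[1] + J / dx
  dvs <- dvs - tb$xc[1] * J
  if (s_e[1] < 0) {
    R_out <- -s_e[1] * u[1]
    du[1] <- du[1] - R_out / dx
    dvs <- dvs + tb$xc[1] * R_out
  }
  if (model$keep_ratio_term)
    dvs <- dvs + (tb$d_x0 - tb$tau_x0 * vs) * u[1]
  du <- du - tb$gamma_c * u
  rate_cap <- max(tb$gamma_c)
  if (tb$frag_on) {
    ev <- tb$B * u * dx                         # breakage events per cell
    du <- du + as.numeric(crossprod(tb$G, ev)) / dx - tb$B * u
    dvs <- dvs + sum(ev * tb$fmono)
    rate_cap <- max(rate_cap, max(tb$B))
  }
  if (tb$coag_on) {
    nn <- pmax(u, 0) * dx
    ev <- tb$K * outer(nn, nn)                  # ordered-pair rates
    ev[lower.tri(ev)] <- 0                      # count each pair once
    diag(ev) <- diag(ev) / 2
    ev[tb$coag_target == 0] <- 0                # zero-flux beyond x_max
    loss <- rowSums(ev) + colSums(ev)           # self-pairs consume two
    du <- du - loss / dx
    keep <- ev > 0
    if (any(keep)) {
      gain_mass <- tapply(ev[keep] * tb$coag_size[keep], tb$coag_target[keep], sum)
      idx <- as.integer(names(gain_mass))
      du[idx] <- du[idx] + as.numeric(gain_mass) / (tb$xc[idx] * dx)
    }
    rate_cap <- max(rate_cap, max(tb$K) * sum(nn))
  }
  out <- c(dw, dv, dvs, du)
  attr(out, "max_speed") <- max(abs(s_e))
  attr(out, "rate_cap") <- rate_cap +
    model$k_act + model$k_plus + model$k_minus
  out
}

#' Right-hand side of the continuous system
#'
#' One derivative evaluation of the PDE model at a given state, using
#' the conservative upwind discretization. The attribute \code{"cfl_dt"}
#' of the result carries the admissible explicit time step
#' \code{0.9 * dx / max |speed|}.
#'
#' @param state a \code{"continuous_state"}.
#' @param model the matching \code{"pde_model"}.
#' @return A \code{"continuous_state"} holding the derivative.
#' @export
pde_rhs <- function(state, model) {
  y <- c(state$w, state$v, state$v_star, state$u)
  if (any(is.na(y))) stop("NaN in state")
  dy <- .pde_deriv(y, model, model$tables)
  ms <- attr(dy, "max_speed")
  out <- continuous_state(model, w = dy[1], v = dy[2], v_star = dy[3],
                          u = dy[-(1:3)], t = state$t)
  attr(out, "cfl_dt") <- if (ms > 0) 0.9 * model$grid$dx / ms else Inf
  out
}

#' Integrate the continuous system
#'
#' Explicit first-order (upwind-in-size, Euler-in-time) integration with
#' the time step chosen from the CFL bound at every step
#' (\code{cfl * dx / max |speed|}, additionally capped by the fastest
#' local reaction rate). The scheme conserves total mass
#' \code{w + v + v_star + integral(x u)} to rounding when degradation is
#' zero, preserves positivity under the CFL bound, and records the
#' continuum small parameter eps = M0/M1 at the final time as a
#' diagnostic.
#'
#' @param model a \code{"pde_model"}.
#' @param init a \code{"continuous_state"}.
#' @param times strictly increasing output times (h).
#' @param cfl CFL safety factor (default 0.9).
#' @return An object of class \code{c("pde_trajectory",
#'   "agg_trajectory")}.
#' @export
integrate_pde <- function(model, init = continuous_state(model), times,
                          cfl = 0.9) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  tb <- model$tables
  n <- tb$n
  y <- c(init$w, init$v, init$v_star, init$u)
  nt <- length(times)
  out <- matrix(0, nt, length(y))
  out[1, ] <- y
  for (it in 2:nt) {
    t <- times[it - 1]; t_end <- times[it]
    while (t < t_end) {
      dy <- .pde_deriv(y, model, tb)
      ms <- attr(dy, "max_speed"); rc <- attr(dy, "rate_cap")
      dt <- min(if (ms > 0) cfl * tb$dx / ms else Inf,
                if (rc > 0) 0.5 / rc else Inf,
                t_end - t)
      if (!is.finite(dt) || dt <= 0) dt <- t_end - t
      y <- y + dt * as.numeric(dy)
      t <- t + dt
      if (any(!is.finite(y)))
        stop("PDE blow-up at t = ", signif(t, 6),
             " (max |speed| = ", signif(ms, 4), ")")
    }
    out[it, ] <- y
  }
  u_fin <- out[nt, -(1:3)]
  m0 <- sum(u_fin) * tb$dx; m1 <- sum(tb$xc * u_fin) * tb$dx
  structure(list(times = times, w = out[, 1], v = out[, 2],
                 v_star = out[, 3], u = out[, -(1:3), drop = FALSE],
                 grid = model$grid, model = model,
                 diagnostics = list(eps = if (m1 > 0) m0 / m1 else NA_real_)),
            class = c("pde_trajectory", "agg_trajectory"))
}

#' @export
simulate.pde_model <- function(object, nsim = 1, seed = NULL, times,
                               init = continuous_state(object), ...) {
  integrate_pde(object, init = init, times = times, ...)
}

.traj_moment.pde_trajectory <- function(traj, order, threshold = 0) {
  keep <- traj$grid$centers >= threshold
  as.numeric(traj$u[, keep, drop = FALSE] %*%
               (traj$grid$centers[keep]^order)) * traj$grid$dx
}

#' @export
final_distribution.pde_trajectory <- function(traj) {
  data.frame(size = traj$grid$centers, density = traj$u[nrow(traj$u), ])
}

#' @export
print.pde_model <- function(x, ...) {
  cat("<pde_model> x0 =", x$grid$x0, " x_max =", x$grid$x_max,
      " n_cells =", x$grid$n, " n_nuc =", x$n_nuc, "\n")
  cat("  k_act =", x$k_act, " k_plus =", x$k_plus, " k_minus =", x$k_minus,
      " k_on =", x$k_on, " k_off =", x$k_off,
      " ratio term:", if (x$keep_ratio_term) "kept" else "dropped", "\n")
  invisible(x)
}

#' Write density snapshots to CSV
#'
#' Two-column (x, u) snapshots of the density at each output time,
#' written as \code{snapshot_<k>.csv} files in \code{dir}.
#' @param traj a \code{"pde_trajectory"}.
#' @param dir output directory (created if missing).
#' @export
write_density_snapshots <- function(traj, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(traj$times)) {
    utils::write.csv(data.frame(x = traj$grid$centers, u = traj$u[k, ]),
                     file.path(dir, sprintf("snapshot_%03d.csv", k)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
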
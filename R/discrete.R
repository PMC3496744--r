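#' Truncated discrete nucleation-polymerization model
#'
#' Builds the size-discrete kinetic model: a precursor pool W activated
#' into native monomer V (rate \code{k_act}), conformational exchange
#' V <-> V* (rates \code{k_plus}, \code{k_minus}), nucleation of
#' \code{i0} activated monomers into the smallest stable aggregate at
#' rate \code{k_on (V*)^n_nuc} with dissociation \code{k_off}, single
#' monomer elongation/depolymerization at size-dependent rates
#' \eqn{\tau(i)} and \eqn{d(i)}, size-dependent degradation
#' \eqn{\gamma(i)}, binary fragmentation and coalescence. The system is
#' truncated at \code{N_max} with a zero-flux closure: elongation out of
#' the top size and coalescence beyond \code{N_max} are suppressed, and
#' the suppressed elongation flux is integrated as a mass-leak
#' diagnostic.
#'
#' Depolymerization below the nucleus does not exist: the nucleus loses
#' mass only through its dissociation at \code{k_off}, which returns
#' \code{i0} activated monomers. Fragmentation daughters smaller than
#' \code{i0} are unstable and dissolve instantly into activated
#' monomers.
#'
#' @param i0 nucleus size (integer >= 1).
#' @param N_max truncation size (> i0).
#' @param k_on nucleation rate constant (1/(uM^(n_nuc-1) h)).
#' @param k_off nucleus dissociation rate (1/h).
#' @param tau,d,gamma \code{\link{rate_piecewise_linear}}-style
#'   \code{"rate_fn"} objects for polymerization (1/(uM h)),
#'   depolymerization (1/h) and degradation (1/h).
#' @param frag optional \code{\link{fragmentation_kernel}}.
#' @param coag optional \code{\link{coalescence_kernel}}.
#' @param k_plus,k_minus conformational exchange rates V -> V* and
#'   V* -> V (1/h).
#' @param k_act precursor activation rate W -> V (1/h).
#' @param n_nuc kinetic order of nucleation; defaults to \code{i0}.
#' @return An object of class \code{c("discrete_model", "agg_model")}.
#' @seealso [integrate_discrete()], [discrete_rhs()], [initial_state()]
#' @export
discrete_model <- function(i0, N_max, k_on, k_off,
                           tau = rate_constant(0),
                           d = rate_constant(0),
                           gamma = rate_constant(0),
                           frag = NULL, coag = NULL,
                           k_plus = 0, k_minus = 0, k_act = 0,
                           n_nuc = i0) {
  i0 <- as.integer(i0); N_max <- as.integer(N_max)
  if (i0 < 1) stop("i0 must be >= 1")
  if (N_max <= i0) stop("N_max must be > i0")
  for (r in c(k_on, k_off, k_plus, k_minus, k_act))
    if (r < 0) stop("all rate constants must be >= 0")
  if (!inherits(tau, "rate_fn")) stop("tau must be a rate_fn")
  if (!is.null(frag) && !inherits(frag, "frag_kernel")) stop("frag must be a frag_kernel")
  if (!is.null(coag) && !inherits(coag, "coag_kernel")) stop("coag must be a coag_kernel")
  m <- structure(list(i0 = i0, N_max = N_max, n_nuc = n_nuc,
                      k_on = k_on, k_off = k_off,
                      k_plus = k_plus, k_minus = k_minus, k_act = k_act,
                      tau = tau, d = d, gamma = gamma,
                      frag = frag, coag = coag),
                 class = c("discrete_model", "agg_model"))
  m$tables <- .discrete_tables(m)
  m
}

# Precompute the numeric tables handed to the compiled RHS.
.discrete_tables <- function(m) {
  sizes <- seq.int(m$i0, m$N_max)
  n <- length(sizes)
  tab <- list(
    i0 = as.double(m$i0), n_nuc = as.double(m$n_nuc),
    k_act = m$k_act, k_plus = m$k_plus, k_minus = m$k_minus,
    k_on = m$k_on, k_off = m$k_off,
    sizes = as.double(sizes),
    tau = as.double(m$tau(sizes)),
    d = as.double(m$d(sizes)),
    gamma = as.double(m$gamma(sizes)),
    frag_mode = 0L, k_f = 0.0, B = double(n),
    G = matrix(0, 0, 0), fmono = double(0),
    coag_mode = 0L, kappa = 0.0, K = matrix(0, 0, 0))
  if (!is.null(m$frag) && m$frag$k_f > 0) {
    tab$k_f <- m$frag$k_f
    tab$B <- as.double(frag_total_rate(m$frag, sizes))
    uniform_fast <- m$frag$kind %in% c("linear_bonds", "uniform") &&
      m$frag$min_fragment == 1L
    if (uniform_fast) {
      tab$frag_mode <- 1L
    } else {
      tab$frag_mode <- 2L
      G <- matrix(0, n, n)
      fmono <- double(n)
      for (p in seq_len(n)) {
        i <- sizes[p]
        b <- frag_daughter_weights(m$frag, i)
        if (!length(b)) next
        js <- seq.int(m$frag$min_fragment, i - m$frag$min_fragment)
        keep <- js >= m$i0
        idx <- js[keep] - m$i0 + 1L
        G[p, idx] <- b[keep]
        fmono[p] <- i - sum(js[keep] * b[keep])
      }
      tab$G <- G; tab$fmono <- fmono
    }
  }
  if (!is.null(m$coag)) {
    if (!is.na(m$coag$constant)) {
      if (m$coag$constant > 0) { tab$coag_mode <- 1L; tab$kappa <- m$coag$constant }
    } else {
      if (n > 1024) stop("general coalescence kernels are limited to N_max - i0 <= 1024")
      K <- outer(sizes, sizes, m$coag$fn)
      if (max(abs(K - t(K))) > 1e-12 * max(abs(K), 1))
        stop("coalescence kernel must be symmetric")
      tab$coag_mode <- 2L; tab$K <- K
    }
  }
  tab
}

#' Discrete model state
#'
#' A state of the discrete system: time, precursor \code{w}, native
#' monomer \code{v}, activated monomer \code{v_star} (all uM) and the
#' polymer concentrations \code{c[i]} for sizes \code{i0 .. N_max}.
#'
#' @param model a \code{"discrete_model"}.
#' @param w,v,v_star monomer pool concentrations (uM).
#' @param c polymer concentrations, length \code{N_max - i0 + 1}
#'   (defaults to all zero).
#' @param t time (h).
#' @return An object of class \code{"discrete_state"}.
#' @export
initial_state <- function(model, w = 0, v = 0, v_star = 0, c = NULL, t = 0) {
  n <- model$N_max - model$i0 + 1L
  if (is.null(c)) c <- double(n)
  if (length(c) != n) stop("c must have length N_max - i0 + 1")
  if (any(!is.finite(c(w, v, v_star, c)))) stop("state must be finite")
  structure(list(t = t, w = w, v = v, v_star = v_star, c = as.double(c)),
            class = "discrete_state",
            sizes = seq.int(model$i0, model$N_max))
}

.state_to_vec <- function(s) c(s$w, s$v, s$v_star, s$c)
.vec_to_state <- function(y, model, t = 0) {
  structure(list(t = t, w = y[1], v = y[2], v_star = y[3], c = y[-(1:3)]),
            class = "discrete_state",
            sizes = seq.int(model$i0, model$N_max))
}

#' Right-hand side of the discrete system
#'
#' Time derivative of a \code{"discrete_state"} under a
#' \code{"discrete_model"}. This is the exact deterministic transcription
#' of the reaction scheme (activation, exchange, nucleation/dissociation,
#' single-monomer elongation and depolymerization, degradation, binary
#' fragmentation, coalescence with zero-flux truncation). A pure R
#' reference implementation; the integrators use an equivalent compiled
#' version, and the two are cross-checked in the test suite.
#'
#' @param state a \code{"discrete_state"}.
#' @param model the matching \code{"discrete_model"}.
#' @return A \code{"discrete_state"} holding the derivative.
#' @export
discrete_rhs <- function(state, model) {
  y <- .state_to_vec(state)
  if (any(is.na(y))) stop("NaN in state")
  tb <- model$tables
  sizes <- tb$sizes; n <- length(sizes)
  w <- y[1]; v <- y[2]; vs <- y[3]; cc <- y[-(1:3)]
  dw <- -tb$k_act * w
  dv <- tb$k_act * w - tb$k_plus * v + tb$k_minus * vs
  nuc <- tb$k_on * vs^tb$n_nuc
  dis <- tb$k_off * cc[1]
  dvs <- tb$k_plus * v - tb$k_minus * vs - tb$i0 * (nuc - dis)
  E <- tb$tau * vs * cc
  E[n] <- 0                      # zero-flux closure at N_max
  dcc <- numeric(n)
  dcc[1] <- nuc - dis
  if (n > 1) {
    dcc[2:n] <- dcc[2:n] + E[1:(n - 1)]
    dcc <- dcc - E
    dpl <- tb$d * cc
    dpl[1] <- 0                  # nucleus leaves via k_off only
    dcc <- dcc - dpl
    dcc[1:(n - 1)] <- dcc[1:(n - 1)] + dpl[2:n]
    dvs <- dvs - sum(E) + sum(dpl)
  }
  dcc <- dcc - tb$gamma * cc
  if (tb$frag_mode == 1L) {
    S <- rev(cumsum(rev(cc))) - cc          # sum over parents strictly larger
    dcc <- dcc + 2 * tb$k_f * S - tb$B * cc
    dvs <- dvs + tb$k_f * tb$i0 * (tb$i0 - 1) * sum(cc)
  } else if (tb$frag_mode == 2L) {
    ev <- tb$B * cc
    dcc <- dcc + as.numeric(crossprod(tb$G, ev)) - ev
    dvs <- dvs + sum(ev * tb$fmono)
  }
  if (tb$coag_mode != 0L) {
    Kfun <- if (tb$coag_mode == 1L) function(i, j) tb$kappa else function(i, j) tb$K[i, j]
    for (i in seq_len(n)) {
      if (cc[i] == 0 && tb$coag_mode == 1L) next
      for (j in i:n) {
        s <- sizes[i] + sizes[j]
        if (s > model$N_max) break
        r <- Kfun(i, j) * cc[i] * cc[j] * if (i == j) 0.5 else 1
        k <- s - model$i0 + 1L
        dcc[k] <- dcc[k] + r
        dcc[i] <- dcc[i] - r
        dcc[j] <- dcc[j] - r
      }
    }
  }
  .vec_to_state(c(dw, dv, dvs, dcc), model, t = state$t)
}

#' Integrate the discrete system
#'
#' Solves the truncated discrete system from an initial state over the
#' requested output times. Two backends are available: \code{"lsoda"},
#' the stiff-capable adaptive integrator from \pkg{deSolve} at
#' controlled tolerance (default for moderate truncation sizes), and
#' \code{"rk4"}, a compiled fixed-step classical Runge-Kutta driver with
#' a per-step stability-bounded step size (default for large systems and
#' used inside the fitting loop). \code{"auto"} picks by system size.
#'
#' @param model a \code{"discrete_model"}.
#' @param init a \code{"discrete_state"}; defaults to the empty state.
#' @param times strictly increasing output times (h), first element is
#'   the initial time.
#' @param method \code{"auto"}, \code{"lsoda"} or \code{"rk4"}.
#' @param rtol,atol tolerances for \code{"lsoda"}.
#' @param dt_max maximal step for \code{"rk4"} (h).
#' @param leak_warn warn if the suppressed elongation flux at
#'   \code{N_max} exceeds this share of total initial mass.
#' @return An object of class \code{c("discrete_trajectory",
#'   "agg_trajectory")} with elements \code{times}, \code{w}, \code{v},
#'   \code{v_star}, matrix \code{c} (times x sizes), \code{sizes},
#'   \code{model} and \code{diagnostics} (incl. \code{leak_frac}).
#' @export
integrate_discrete <- function(model, init = initial_state(model), times,
                               method = c("auto", "lsoda", "rk4"),
                               rtol = 1e-8, atol = 1e-12, dt_max = Inf,
                               leak_warn = 1e-3) {
  method <- match.arg(method)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  y0 <- .state_to_vec(init)
  tb <- model$tables
  n <- length(tb$sizes)
  if (method == "auto") method <- if (n <= 400) "lsoda" else "rk4"
  if (method == "lsoda") {
    fn <- function(t, y, p) list(rhs_discrete_cpp(y, tb))
    sol <- deSolve::lsoda(y0, times, fn, parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure at t = ", max(sol[, 1]))
    mat <- unname(sol[, -1, drop = FALSE])
    flux <- tb$tau[n] * mat[, 3] * mat[, 3 + n]
    leak <- sum(diff(times) * (head(flux, -1) + tail(flux, -1)) / 2)
  } else {
    res <- integrate_discrete_cpp(y0, as.double(times), tb,
                                  if (is.finite(dt_max)) dt_max else 0.0)
    mat <- res$states
    leak <- res$leak
  }
  mass0 <- sum(y0[1:3]) + sum(tb$sizes * y0[-(1:3)])
  leak_frac <- if (mass0 > 0) leak / mass0 else 0
  if (leak_frac > leak_warn)
    warning(sprintf("truncation leak diagnostic: %.3g%% of initial mass (suppressed elongation flux at N_max = %d)",
                    100 * leak_frac, model$N_max))
  structure(list(times = times, w = mat[, 1], v = mat[, 2], v_star = mat[, 3],
                 c = mat[, -(1:3), drop = FALSE], sizes = tb$sizes,
                 model = model,
                 diagnostics = list(leak_mass = leak, leak_frac = leak_frac,
                                    method = method)),
            class = c("discrete_trajectory", "agg_trajectory"))
}

#' @export
simulate.discrete_model <- function(object, nsim = 1, seed = NULL, times,
                                    init = initial_state(object), ...) {
  integrate_discrete(object, init = init, times = times, ...)
}

#' Moments of a state
#'
#' \code{discrete_moment()} computes \eqn{\sum_i i^k c_i} over the
#' polymer sizes of a discrete state; \code{state_moment()} is the
#' generic working on both discrete and continuous states.
#'
#' @param state a \code{"discrete_state"} or \code{"continuous_state"}.
#' @param order moment order, one of 0, 1, 2.
#' @return The moment (uM times size^order).
#' @export
state_moment <- function(state, order) UseMethod("state_moment")

#' @rdname state_moment
#' @export
state_moment.discrete_state <- function(state, order) {
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  sum(as.numeric(attr(state, "sizes"))^order * state$c)
}

#' @rdname state_moment
#' @export
discrete_moment <- function(state, order) state_moment(state, order)

# moment time series of a trajectory, optionally restricted to sizes >= threshold
.traj_moment <- function(traj, order, threshold = 0) UseMethod(".traj_moment")

.traj_moment.discrete_trajectory <- function(traj, order, threshold = 0) {
  keep <- traj$sizes >= threshold
  as.numeric(traj$c[, keep, drop = FALSE] %*% (as.numeric(traj$sizes[keep])^order))
}

#' Extract a scalar observable time series from a trajectory
#'
#' @param traj an \code{"agg_trajectory"}.
#' @param what one of \code{"M0"}, \code{"M1"}, \code{"M2"},
#'   \code{"mean_size"} (M1/M0), \code{"monomer"} (activated monomer
#'   V*), \code{"w"}, \code{"v"}.
#' @return A \code{\link{time_series}}.
#' @export
observable_series <- function(traj, what = c("M1", "M0", "M2", "mean_size",
                                             "monomer", "w", "v")) {
  what <- match.arg(what)
  vals <- switch(what,
    M0 = .traj_moment(traj, 0), M1 = .traj_moment(traj, 1),
    M2 = .traj_moment(traj, 2),
    mean_size = {
      m0 <- .traj_moment(traj, 0)
      ifelse(m0 > 0, .traj_moment(traj, 1) / m0, NA_real_)
    },
    monomer = traj$v_star, w = traj$w, v = traj$v)
  time_series(traj$times, vals, label = what)
}

#' @export
print.discrete_model <- function(x, ...) {
  cat("<discrete_model> i0 =", x$i0, " N_max =", x$N_max,
      " n_nuc =", x$n_nuc, "\n")
  cat("  k_act =", x$k_act, " k_plus =", x$k_plus, " k_minus =", x$k_minus,
      " k_on =", x$k_on, " k_off =", x$k_off, "\n")
  cat("  tau:", attr(x$tau, "kind"), " d:", attr(x$d, "kind"),
      " gamma:", attr(x$gamma, "kind"),
      " frag:", if (is.null(x$frag)) "none" else x$frag$kind,
      " coag:", if (is.null(x$coag)) "none" else "on", "\n")
  invisible(x)
}

#' @export
print.agg_trajectory <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$times), " output times on [",
      min(x$times), ", ", max(x$times), "] h\n", sep = "")
  m1 <- .traj_moment(x, 1)
  cat("  polymerized mass: ", signif(m1[1], 4), " -> ",
      signif(m1[length(m1)], 4), " uM\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.agg_trajectory <- function(x, ...) {
  data.frame(t = x$times, w = x$w, v = x$v, v_star = x$v_star,
             M0 = .traj_moment(x, 0), M1 = .traj_moment(x, 1),
             M2 = .traj_moment(x, 2))
}

#' @export
plot.agg_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  df <- as.data.frame(x)
  plot(df$t, df$M1, type = "l", xlab = "time (h)",
       ylab = "polymerized mass (uM)", ...)
  d <- final_distribution(x)
  plot(d$size, d$density, type = "l", xlab = "size (monomers)",
       ylab = "number density (uM/size)")
  invisible(x)
}

#' Final size distribution of a trajectory
#'
#' Number density over size at the last output time, as a two-column
#' data frame \code{(size, density)} in uM per unit size.
#' @param traj an \code{"agg_trajectory"}.
#' @export
final_distribution <- function(traj) UseMethod("final_distribution")

#' @export
final_distribution.discrete_trajectory <- function(traj) {
  data.frame(size = as.numeric(traj$sizes),
             density = traj$c[nrow(traj$c), ])
}

#' Export a trajectory to CSV
#'
#' Writes the full state (t, w, v, v_star, c_i0 .. c_Nmax or the density
#' cells) as an RFC-4180 CSV with a header row.
#' @param traj an \code{"agg_trajectory"}.
#' @param path output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = traj$times, w = traj$w, v = traj$v, v_star = traj$v_star)
  if (inherits(traj, "discrete_trajectory")) {
    cmat <- as.data.frame(traj$c)
    names(cmat) <- paste0("c", traj$sizes)
  } else {
    cmat <- as.data.frame(traj$u)
    names(cmat) <- paste0("u", signif(traj$grid$centers, 8))
  }
  utils::write.csv(cbind(df, cmat), path, row.names = FALSE, quote = FALSE)
}
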
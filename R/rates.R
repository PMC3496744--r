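#' Size-dependent reaction rate functions
#'
#' Constructors for the rate functions used throughout the kinetic models:
#' the polymerization rate \eqn{\tau(x)} (units 1/(uM h)), the
#' depolymerization rate \eqn{d(x)} (1/h) and the degradation rate
#' \eqn{\gamma(x)} (1/h) are all represented as objects of class
#' \code{"rate_fn"}, callable at any size \eqn{x \ge 0} and vectorized.
#'
#' \code{rate_piecewise_linear()} rises linearly from 0 at size 0 to
#' \code{tau_max} at \code{x1}, stays at \code{tau_max} on
#' \code{[x1, x2]}, decreases linearly to 0 at \code{x3} and is 0 beyond.
#' This is the tent-shaped elongation profile used for PolyQ, where
#' fibril ends become non-reactive past a maximal length.
#'
#' \code{rate_step()} is the one-step profile used for Xue-type growth:
#' \code{k_low} for sizes below \code{n_c} and \code{k_high} at or above
#' \code{n_c} (the step size itself takes the high value, so the nucleus
#' at the step elongates at the fast rate).
#'
#' \code{rate_constant()} is the size-independent rate of the classic
#' constant-coefficient models.
#'
#' @param x1,x2,x3 breakpoints in monomer units, \code{0 < x1 <= x2 <= x3}.
#' @param tau_max plateau value (rate units), non-negative.
#' @param n_c step location (size units), \code{>= 1}.
#' @param k_low,k_high rate below / at-and-above the step, non-negative.
#' @param value constant rate, non-negative.
#' @return A function of class \code{"rate_fn"} mapping sizes to rates.
#' @examples
#' tau <- rate_piecewise_linear(2, 10, 20, 1)
#' tau(c(1, 10, 25))   # 0.5, 1, 0
#' @export
rate_piecewise_linear <- function(x1, x2, x3, tau_max) {
  if (!(x1 > 0 && x1 <= x2 && x2 <= x3))
    stop("breakpoints must satisfy 0 < x1 <= x2 <= x3")
  if (tau_max < 0) stop("tau_max must be >= 0")
  f <- function(x) {
    x <- as.numeric(x)
    out <- numeric(length(x))
    up <- x >= 0 & x < x1
    out[up] <- tau_max * x[up] / x1
    out[x >= x1 & x <= x2] <- tau_max
    dn <- x > x2 & x < x3
    if (x3 > x2) out[dn] <- tau_max * (x3 - x[dn]) / (x3 - x2)
    out
  }
  structure(f, class = "rate_fn", kind = "piecewise_linear",
            params = list(x1 = x1, x2 = x2, x3 = x3, tau_max = tau_max))
}

#' @rdname rate_piecewise_linear
#' @export
rate_step <- function(n_c, k_low, k_high) {
  if (n_c < 1) stop("n_c must be >= 1")
  if (k_low < 0 || k_high < 0) stop("rates must be >= 0")
  f <- function(x) ifelse(as.numeric(x) >= n_c, k_high, k_low)
  structure(f, class = "rate_fn", kind = "step",
            params = list(n_c = n_c, k_low = k_low, k_high = k_high))
}

#' @rdname rate_piecewise_linear
#' @export
rate_constant <- function(value) {
  if (value < 0) stop("rate must be >= 0")
  f <- function(x) rep(value, length(x))
  structure(f, class = "rate_fn", kind = "constant",
            params = list(value = value))
}

#' @export
print.rate_fn <- function(x, ...) {
  p <- attr(x, "params")
  cat("<rate_fn>", attr(x, "kind"), "\n  ",
      paste(names(p), unlist(p), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Binary fragmentation kernel
#'
#' A fragmentation kernel specifies the total breakage rate \eqn{B(i)} of
#' an \eqn{i}-mer (1/h) and the distribution of the two daughter sizes
#' \eqn{(j, i-j)}. Every kind uses the per-bond rate parametrization
#' \eqn{B(i) = k_f (i - 1)} (an \eqn{i}-mer has \eqn{i-1} internal bonds),
#' so that two kernels of different \code{kind} but equal \code{k_f} have
#' matched total rates and differ only in the daughter-size distribution:
#' \describe{
#'   \item{\code{linear_bonds}, \code{uniform}}{every internal bond is
#'     equally likely to break, i.e. the daughter size is uniform on
#'     \code{min_fragment .. i - min_fragment}.}
#'   \item{\code{mechanical}}{central breakpoints are favoured, with
#'     daughter-pair weight proportional to \eqn{j (i - j)} (breakage
#'     stress grows towards the fibril midpoint); the weight shape is
#'     the package's documented choice.}
#' }
#' The daughter distribution is symmetric (\eqn{(j, i-j)} and
#' \eqn{(i-j, j)} have equal density) and conserves mass exactly:
#' the expected daughter numbers \eqn{b(j|i)} satisfy
#' \eqn{\sum_j b(j|i) = 2} and \eqn{\sum_j j\, b(j|i) = i}.
#' \eqn{B(i) = 0} below \code{2 * min_fragment}.
#'
#' @param kind one of \code{"linear_bonds"}, \code{"uniform"},
#'   \code{"mechanical"}.
#' @param k_f per-bond fragmentation rate (1/h), non-negative.
#' @param min_fragment smallest daughter size produced (monomer units,
#'   \code{>= 1}). Daughters smaller than a model's nucleus are routed
#'   back to the monomer pool by the model, not by the kernel.
#' @return An object of class \code{"frag_kernel"}.
#' @examples
#' k <- fragmentation_kernel("linear_bonds", k_f = 0.1)
#' frag_total_rate(k, 20)        # 1.9
#' sum(frag_daughter_weights(k, 20))  # 2
#' @export
fragmentation_kernel <- function(kind = c("linear_bonds", "uniform", "mechanical"),
                                 k_f, min_fragment = 1L) {
  kind <- match.arg(kind)
  if (k_f < 0) stop("k_f must be >= 0")
  if (min_fragment < 1) stop("min_fragment must be >= 1")
  structure(list(kind = kind, k_f = k_f, min_fragment = as.integer(min_fragment)),
            class = "frag_kernel")
}

#' @rdname fragmentation_kernel
#' @param kernel a \code{"frag_kernel"}.
#' @param i parent size(s) (monomer units).
#' @export
frag_total_rate <- function(kernel, i) {
  ifelse(i >= 2 * kernel$min_fragment, kernel$k_f * (i - 1), 0)
}

#' @rdname fragmentation_kernel
#' @details \code{frag_daughter_weights()} returns, for a single parent
#'   size \code{i}, the vector \eqn{b(j|i)} of expected daughters of size
#'   \code{j} per breakage event, for \code{j = min_fragment, ...,
#'   i - min_fragment} (zero-length if the parent cannot break).
#' @export
frag_daughter_weights <- function(kernel, i) {
  mf <- kernel$min_fragment
  if (i < 2 * mf) return(numeric(0))
  j <- seq.int(mf, i - mf)
  w <- switch(kernel$kind,
    linear_bonds = ,
    uniform = rep(1, length(j)),
    mechanical = j * (i - j))
  2 * w / sum(w)
}

#' @export
print.frag_kernel <- function(x, ...) {
  cat("<frag_kernel>", x$kind, " k_f =", x$k_f,
      " min_fragment =", x$min_fragment, "\n")
  invisible(x)
}

#' Coalescence (coagulation) kernel
#'
#' End-to-end joining of two polymers of sizes \eqn{x} and \eqn{y} at
#' rate \eqn{\kappa(x, y)} (1/(uM h)), symmetric in its arguments.
#' Either a single non-negative constant or a symmetric function of two
#' size arguments may be supplied.
#'
#' @param rate non-negative constant, or function \code{f(x, y)} with
#'   \code{f(x, y) == f(y, x) >= 0}.
#' @return An object of class \code{"coag_kernel"}.
#' @export
coalescence_kernel <- function(rate) {
  if (is.numeric(rate)) {
    if (length(rate) != 1 || rate < 0) stop("constant rate must be a single value >= 0")
    fn <- local({ r <- rate; function(x, y) rep(r, length(x)) })
    structure(list(fn = fn, constant = rate), class = "coag_kernel")
  } else if (is.function(rate)) {
    structure(list(fn = rate, constant = NA_real_), class = "coag_kernel")
  } else stop("rate must be a constant or a function(x, y)")
}

#' @export
print.coag_kernel <- function(x, ...) {
  if (is.na(x$constant)) cat("<coag_kernel> general symmetric kernel\n")
  else cat("<coag_kernel> constant kappa =", x$constant, "\n")
  invisible(x)
}
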
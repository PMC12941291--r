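#' Finite-bath diffusion series solution
#'
#' Fraction of the equilibrium-migratable amount that has entered the food
#' at time t, for one-dimensional Fickian diffusion out of a plane film of
#' thickness L (zero-flux back face) into a well-stirred finite bath of
#' capacity ratio alpha:
#'
#'   M_F,t / M_F,inf =
#'     1 - sum_n 2 alpha (1 + alpha) / (1 + alpha + alpha^2 q_n^2) *
#'         exp(-D t q_n^2 / L^2)
#'
#' with q_n the roots of tan(q) = -alpha q (see [solve_roots()]). The sum
#' is truncated adaptively: terms are accumulated in order until the next
#' term falls below `tol` (hard cap `n_terms`). At t = 0 the value 0 is
#' returned exactly by convention. Results are clamped to \[0, 1\].
#'
#' If for some small positive t the cap is reached before the term bound
#' is met, the result carries the attribute `underresolved = TRUE` (a
#' truncation warning flag), and the attribute `n_terms` reports the
#' largest number of terms used at any time point.
#'
#' @param D Diffusion coefficient in cm^2/s.
#' @param t_s Times in seconds (vectorised, >= 0).
#' @param L Film thickness in cm.
#' @param alpha Capacity ratio, > 0.
#' @param roots Optional precomputed [solve_roots()] result for `alpha`.
#' @param n_terms Series truncation cap.
#' @param tol Truncation bound: stop once the next term is below this.
#' @return Numeric vector of fractions in \[0, 1\] with attributes
#'   `n_terms` and `underresolved`.
#' @export
series_fraction <- function(D, t_s, L, alpha, roots = NULL,
                            n_terms = 200, tol = 1e-12) {
  if (!is.finite(D) || D <= 0) stop("D must be strictly positive")
  if (!is.finite(L) || L <= 0) stop("L must be strictly positive")
  if (any(!is.finite(t_s)) || any(t_s < 0)) stop("times must be non-negative")
  if (is.null(roots)) roots <- solve_roots(alpha, n_terms)
  stopifnot(inherits(roots, "root_set"), roots$alpha == alpha)
  q <- roots$roots
  if (length(q) < n_terms) n_terms <- length(q)
  q <- q[seq_len(n_terms)]
  coefs <- 2 * alpha * (1 + alpha) / (1 + alpha + alpha^2 * q^2)
  tau <- D * t_s / L^2
  used <- 0L
  under <- FALSE
  out <- vapply(tau, function(tt) {
    if (tt == 0) return(0)
    terms <- coefs * exp(-tt * q^2)
    cut <- which(terms < tol)
    k <- if (length(cut)) cut[1] else length(terms)
    if (terms[k] >= tol) under <<- TRUE
    used <<- max(used, k)
    min(max(1 - sum(terms[seq_len(k)]), 0), 1)
  }, numeric(1))
  structure(out, n_terms = used, underresolved = under)
}

#' Series coefficients and their infinite-bath limit
#'
#' The n-th series coefficient 2 alpha (1 + alpha) / (1 + alpha +
#' alpha^2 q_n^2). As alpha -> Inf these approach the classical
#' infinite-bath coefficients 8 / ((2n - 1)^2 pi^2); the coefficients of
#' any valid root set sum to 1 (the series equals 0 at t = 0).
#'
#' @param roots A [solve_roots()] result.
#' @return Numeric vector of coefficients.
#' @keywords internal
series_coefficients <- function(roots) {
  stopifnot(inherits(roots, "root_set"))
  a <- roots$alpha
  q <- roots$roots
  2 * a * (1 + a) / (1 + a + a^2 * q^2)
}

#' Infinite-bath series solution
#'
#' Classical solution for desorption from a plane sheet (thickness L,
#' sealed back face) into a perfectly absorbing, infinitely large bath:
#' M_t/M_inf = 1 - sum 8/((2n-1)^2 pi^2) exp(-D (2n-1)^2 pi^2 t /(4 L^2)).
#' Used as the closed-form limit check of the finite-bath model at very
#' large alpha.
#'
#' @inheritParams series_fraction
#' @return Numeric vector of fractions.
#' @export
infinite_bath_fraction <- function(D, t_s, L, n_terms = 200) {
  tau <- D * t_s / L^2
  n <- seq_len(n_terms)
  lam <- (2 * n - 1)^2 * pi^2 / 4
  co <- 8 / ((2 * n - 1)^2 * pi^2)
  vapply(tau, function(tt) {
    if (tt == 0) return(0)
    min(max(1 - sum(co * exp(-lam * tt)), 0), 1)
  }, numeric(1))
}

#' Model migration curve
#'
#' Migration ratio in percent as a function of contact time, obtained by
#' composing the equilibrium plateau with the finite-bath series:
#' MR(t) = 100 * alpha/(1 + alpha) * M_F,t/M_F,inf. Monotone
#' non-decreasing in t, with long-time plateau 100 * alpha/(1 + alpha).
#'
#' @param time_h Contact times in hours (converted to seconds internally).
#' @param D Diffusion coefficient in cm^2/s.
#' @param alpha Capacity ratio.
#' @param L Film thickness in cm (default: the 80 um reference film).
#' @param ... Passed to [series_fraction()].
#' @return Migration ratio in percent at each time.
#' @examples
#' migration_profile(c(0, 6, 72), D = 8e-11, alpha = 0.328)
#' @export
migration_profile <- function(time_h, D, alpha, L = 8e-3, ...) {
  frac <- series_fraction(D, time_h * 3600, L, alpha, ...)
  out <- 100 * equilibrium_fraction(alpha) * as.numeric(frac)
  attributes(out) <- attributes(frac)[c("n_terms", "underresolved")]
  out
}
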
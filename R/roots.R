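#' Roots of the finite-bath eigenvalue condition
#'
#' The series solution for diffusion out of a plane sheet into a stirred
#' bath of finite capacity alpha requires the positive roots q_n of
#'
#'   tan(q) = -alpha * q .
#'
#' For alpha > 0 there is exactly one root in each interval
#' ((n - 1/2) * pi, n * pi), n = 1, 2, ...; as alpha -> 0 the roots
#' approach n*pi from below and as alpha -> Inf they approach
#' (n - 1/2)*pi from above. Each root is isolated by vectorised bisection
#' on the equivalent smooth form sin(q) + alpha * q * cos(q) (which avoids
#' the tan singularity at the left bracket edge) and then polished by
#' Newton steps.
#'
#' @param alpha Capacity ratio, > 0.
#' @param n_roots Number of roots to return.
#' @param tol Residual bound on |tan(q_n) + alpha * q_n|. The solver
#'   always iterates to machine precision in q; `tol` is the acceptance
#'   bound checked afterwards. At very large alpha the tan-form residual
#'   is ill-conditioned near q = (n - 1/2)*pi and the check is skipped
#'   (the roots themselves remain accurate to machine precision).
#' @return An object of class `"root_set"`: list with `alpha`, `roots`
#'   (ascending), `residuals`.
#' @examples
#' solve_roots(1, 3)$roots[1]  # 2.028757838...
#' @export
solve_roots <- function(alpha, n_roots = 64, tol = 1e-10) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be strictly positive")
  if (n_roots < 1) stop("n_roots must be >= 1")
  n <- seq_len(n_roots)
  lo <- (n - 0.5) * pi + 1e-9
  hi <- n * pi - 1e-9
  # g(q) = sin q + alpha q cos q; sign at the left edge is (-1)^(n+1)
  sgn <- (-1)^(n + 1)
  g <- function(q) sgn * (sin(q) + alpha * q * cos(q))
  if (any(g(lo) < 0) || any(g(hi) > 0))
    stop("root bracketing failed; alpha out of supported range")
  for (i in 1:70) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  q <- (lo + hi) / 2
  # Newton polish on sin q + alpha q cos q
  for (i in 1:3) {
    fq <- sin(q) + alpha * q * cos(q)
    dq <- (1 + alpha) * cos(q) - alpha * q * sin(q)
    step <- fq / dq
    step[!is.finite(step)] <- 0
    q <- pmin(pmax(q - step, (n - 0.5) * pi), n * pi)
  }
  res <- abs(tan(q) + alpha * q)
  # The tan-form residual of a machine-precision root is bounded below by
  # |d/dq(tan q + alpha q)| * eps * q ~ (1 + alpha^2 q^2) * eps * q, so the
  # tolerance is only checkable where that floor sits beneath it.
  floor_res <- (1 + alpha^2 * q^2) * .Machine$double.eps * q * 16
  bad <- res > tol & floor_res < tol
  if (any(bad))
    stop(sprintf("root %d failed residual tolerance %.1e (residual %.1e)",
                 which(bad)[1], tol, res[which(bad)[1]]))
  structure(list(alpha = alpha, roots = q, residuals = res),
            class = "root_set")
}

#' @export
print.root_set <- function(x, ...) {
  cat(sprintf("Eigenvalue roots of tan(q) = -alpha q,  alpha = %.4g\n", x$alpha))
  k <- min(5, length(x$roots))
  cat("  q_1..: ", paste(sprintf("%.6f", x$roots[seq_len(k)]), collapse = ", "),
      if (length(x$roots) > k) "..." else "", "\n")
  cat(sprintf("  n = %d, max |tan q + alpha q| = %.2e\n",
              length(x$roots), max(x$residuals)))
  invisible(x)
}
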
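#' Partition coefficient and finite-bath capacity ratio
#'
#' At equilibrium the additive distributes between polymer and food with
#' partition coefficient K_P/F = C_P,inf / C_F,inf (concentration in the
#' polymer over concentration in the food). The dimensionless capacity
#' ratio of the food phase relative to the polymer phase is
#'
#'   alpha = V_F / (K_P/F * V_P),
#'
#' the ratio of additive masses m_F,inf / m_P,inf held by the two phases at
#' equilibrium. A large K (additive prefers the polymer) gives a small
#' alpha and a low equilibrium migration plateau. `alpha_from_partition()`
#' and `partition_from_alpha()` are exact inverses for a given system.
#'
#' @param K_PF Partition coefficient, dimensionless, > 0.
#' @param alpha Capacity ratio, dimensionless, > 0.
#' @param system A [contact_system()] supplying V_F and V_P.
#' @return A single dimensionless number.
#' @examples
#' sys <- contact_system()
#' alpha_from_partition(volume_ratio(sys), sys)  # 1: symmetric partitioning
#' @export
alpha_from_partition <- function(K_PF, system) {
  if (any(!is.finite(K_PF)) || any(K_PF <= 0))
    stop("K_PF must be strictly positive")
  volume_ratio(system) / K_PF
}

#' @rdname alpha_from_partition
#' @export
partition_from_alpha <- function(alpha, system) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be strictly positive")
  volume_ratio(system) / alpha
}

#' Partition equilibrium state
#'
#' Bundles K_P/F and alpha for one contact system and validates their
#' mutual constraint alpha * K_P/F = V_F/V_P (relative tolerance 1e-6).
#' Supply either one; the other is derived.
#'
#' @param system A [contact_system()].
#' @param K_PF,alpha Supply exactly one (or both, in which case they are
#'   checked for consistency).
#' @return An object of class `"partition_equilibrium"`: list with `K_PF`,
#'   `alpha`, `volume_ratio`, `equilibrium_fraction`.
#' @export
partition_equilibrium <- function(system, K_PF = NULL, alpha = NULL) {
  stopifnot(inherits(system, "contact_system"))
  vr <- volume_ratio(system)
  if (is.null(K_PF) && is.null(alpha))
    stop("supply K_PF or alpha")
  if (is.null(alpha)) alpha <- alpha_from_partition(K_PF, system)
  if (is.null(K_PF)) K_PF <- partition_from_alpha(alpha, system)
  if (abs(alpha * K_PF - vr) > 1e-6 * vr)
    stop("alpha and K_PF are inconsistent: alpha * K_PF must equal V_F/V_P")
  structure(list(K_PF = K_PF, alpha = alpha, volume_ratio = vr,
                 equilibrium_fraction = equilibrium_fraction(alpha)),
            class = "partition_equilibrium")
}

#' @export
print.partition_equilibrium <- function(x, ...) {
  cat(sprintf("Partition equilibrium: K_P/F = %.4g, alpha = %.4g (V_F/V_P = %.4g)\n",
              x$K_PF, x$alpha, x$volume_ratio))
  cat(sprintf("  equilibrium fraction in food: %.3f\n", x$equilibrium_fraction))
  invisible(x)
}

#' Equilibrium fraction of additive in the food phase
#'
#' Mass balance of the two-compartment equilibrium with m_F/m_P = alpha:
#' the fraction of the total additive residing in the food at equilibrium
#' is alpha / (1 + alpha). This is the plateau of the migration ratio
#' (divided by 100). alpha = 0 means no migration at equilibrium;
#' alpha -> Inf is the infinite-bath limit where everything migrates.
#'
#' @param alpha Capacity ratio, >= 0 (vectorised).
#' @return Fraction in \[0, 1\].
#' @export
equilibrium_fraction <- function(alpha) {
  if (any(!is.finite(alpha) & !is.infinite(alpha)) || any(alpha < 0))
    stop("alpha must be non-negative")
  ifelse(is.infinite(alpha), 1, alpha / (1 + alpha))
}
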
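#' Film specification
#'
#' Describes a single polymer film specimen: its thickness, the contact
#' area exposed to the food, the polymer density, and the mass fraction of
#' the additive incorporated during compounding. The defaults correspond to
#' an 80 um polypropylene film cut to a 3 cm x 3 cm square (single-sided
#' contact), density 0.90 g/cm^3, loaded with the additive at 0.1 g/kg
#' (100 ug additive per g polymer).
#'
#' @param thickness_cm Film thickness L in cm. For a thin film in
#'   single-sided contact (zero-flux back face) this is the full thickness.
#' @param area_cm2 Contact area in cm^2 (single-sided).
#' @param density_g_cm3 Polymer density in g/cm^3.
#' @param loading_ug_g Additive loading in ug per g polymer.
#' @return An object of class `"film_spec"`.
#' @seealso [contact_system()], [initial_amount()]
#' @examples
#' f <- film_spec()
#' initial_amount(f)  # 6480 ng
#' @export
film_spec <- function(thickness_cm = 8e-3, area_cm2 = 9,
                      density_g_cm3 = 0.90, loading_ug_g = 100) {
  vals <- c(thickness_cm = thickness_cm, area_cm2 = area_cm2,
            density_g_cm3 = density_g_cm3, loading_ug_g = loading_ug_g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all film_spec fields must be strictly positive and finite")
  structure(as.list(vals), class = "film_spec")
}

#' @export
print.film_spec <- function(x, ...) {
  cat(sprintf(
    "Polymer film: %.0f um thick, %.1f cm2 contact area, %.2f g/cm3, %g ug/g loading\n",
    x$thickness_cm * 1e4, x$area_cm2, x$density_g_cm3, x$loading_ug_g))
  cat(sprintf("  film mass %.4f g, initial additive amount %.1f ng\n",
              film_mass(x), initial_amount(x)))
  invisible(x)
}

#' Film mass and initial additive amount
#'
#' `film_mass()` returns the specimen mass in g (area x thickness x
#' density); `initial_amount()` returns the additive amount initially
#' present in the film, in ng (film mass x loading, with ug -> ng).
#'
#' @param film A [film_spec()].
#' @return A single number (g, resp. ng).
#' @export
film_mass <- function(film) {
  stopifnot(inherits(film, "film_spec"))
  film$area_cm2 * film$thickness_cm * film$density_g_cm3
}

#' @rdname film_mass
#' @export
initial_amount <- function(film) {
  film_mass(film) * film$loading_ug_g * 1e3
}

#' Film-food contact system
#'
#' A film specimen in contact with a fixed volume of a well-stirred food
#' phase. Defaults reproduce the standard migration-cell condition: 15 mL
#' of food against a 9 cm^2 film, i.e. a surface-to-volume ratio of
#' 6 dm^2/L, at 40 degrees C.
#'
#' @param film A [film_spec()].
#' @param food_volume_ml Food volume V_F in mL (= cm^3).
#' @param temperature_c Contact temperature in degrees C (metadata only;
#'   no temperature model is applied).
#' @return An object of class `"contact_system"` with elements `film`,
#'   `food_volume_ml`, `temperature_c`.
#' @examples
#' sys <- contact_system()
#' surface_to_volume(sys)  # 6 dm^2/L
#' @export
contact_system <- function(film = film_spec(), food_volume_ml = 15,
                           temperature_c = 40) {
  stopifnot(inherits(film, "film_spec"))
  if (!is.finite(food_volume_ml) || food_volume_ml <= 0)
    stop("food_volume_ml must be strictly positive")
  structure(list(film = film, food_volume_ml = food_volume_ml,
                 temperature_c = temperature_c),
            class = "contact_system")
}

#' @export
print.contact_system <- function(x, ...) {
  print(x$film)
  cat(sprintf("Food phase: %.1f mL at %g C  (S/V = %.2f dm2/L, V_F/V_P = %.1f)\n",
              x$food_volume_ml, x$temperature_c, surface_to_volume(x),
              volume_ratio(x)))
  invisible(x)
}

#' Geometry ratios of a contact system
#'
#' `surface_to_volume()` reports the contact area per food volume in
#' dm^2/L, the unit used by migration-testing standards (the reference
#' condition is 6 dm^2/L). `volume_ratio()` returns the dimensionless
#' phase-volume ratio V_F/V_P used by the finite-bath partition relation.
#'
#' @param system A [contact_system()].
#' @return A single number.
#' @export
surface_to_volume <- function(system) {
  stopifnot(inherits(system, "contact_system"))
  # cm^2 / cm^3 -> dm^2 / L : (A/100) / (V/1000) = 10 A / V
  10 * system$film$area_cm2 / system$food_volume_ml
}

#' @rdname surface_to_volume
#' @export
volume_ratio <- function(system) {
  stopifnot(inherits(system, "contact_system"))
  v_p <- system$film$area_cm2 * system$film$thickness_cm
  system$food_volume_ml / v_p
}

#' Migration ratio
#'
#' The fraction of the additive initially present in the film that has
#' migrated into the food at a given contact time, expressed in percent:
#' MR = 100 * m_m / m_i.
#'
#' Values above 100 percent can arise from measurement noise; they are
#' kept, but a warning is raised so that they are flagged rather than
#' silently propagated.
#'
#' @param m_m Migrated additive mass in ng (vectorised).
#' @param m_i Initial additive mass in the film, in ng.
#' @return Migration ratio in percent.
#' @examples
#' migration_ratio(64.8, initial_amount(film_spec()))  # 1 %
#' @export
migration_ratio <- function(m_m, m_i) {
  if (!all(is.finite(m_i)) || any(m_i <= 0))
    stop("initial amount m_i must be strictly positive")
  if (any(!is.finite(m_m)) || any(m_m < 0))
    stop("migrated mass m_m must be non-negative")
  mr <- 100 * m_m / m_i
  if (any(mr > 100))
    warning(sprintf("%d migration ratio value(s) exceed 100%% (kept, flagged)",
                    sum(mr > 100)))
  mr
}
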
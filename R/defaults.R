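# Package defaults for a fully synthetic workflow: a simulated insert scan
# through the parameterized attenuation model stands in for the physical
# calibration phantom, so the whole pipeline runs without measured data.

#' Default kV-like attenuation coefficients
#'
#' Coefficient ratios chosen so that the simulated scan behaves like a
#' low-kVp acquisition: a strong photoelectric term (Z^4.62) makes composition
#' dosimetrically visible, and cortical bone lands near +2700 HU while
#' inflated lung sits near -750 HU. These drive the synthetic forward model
#' only; fits against measured data estimate their own coefficients.
#'
#' @return An [attenuation_coeffs()].
#' @export
default_kv_coeffs <- function() attenuation_coeffs(k_kn = 1, k_ph = 1e-4, k_sca = 5e-3)

# the simulated insert battery: 11 reference tissues spanning the full
# rho*Zeff range, mimicking a calibration phantom's insert set
insert_names <- c(
  "lung_inflated", "adipose", "water", "muscle", "liver", "cartilage",
  "thyroid", "spongiosa", "femur", "humerus", "cortical_bone"
)

#' Simulated calibration-insert scan
#'
#' Predicts the CBCT number of 11 reference tissues spanning inflated lung to
#' cortical bone through the parameterized attenuation model, optionally with
#' additive Gaussian HU noise, and returns calibration points ready for
#' [fit_hu_curve()].
#'
#' @param coeffs Forward-model coefficients, default [default_kv_coeffs()].
#' @param sigma Gaussian HU noise standard deviation (0 = noiseless).
#' @param seed Seed used when `sigma > 0`.
#' @return Tibble with columns `name`, `rho_zeff`, `hu`.
#' @examples
#' simulated_insert_points()
#' @export
simulated_insert_points <- function(coeffs = default_kv_coeffs(),
                                    sigma = 0, seed = 1L) {
  t <- icru_tissues()
  t <- t[match(insert_names, t$name), ]
  t <- ct_number(t, coeffs)
  hu <- t$hu_pred
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hu <- hu + rnorm(length(hu), 0, sigma)
  }
  tibble::tibble(name = t$name, rho_zeff = t$printed_rho_zeff, hu = hu)
}

#' Default calibration curve from the simulated insert scan
#'
#' Cubic fit of [simulated_insert_points()] (noiseless), cached per session.
#' Monotonic over [2.05, 26.84] g/cm3 by construction of the forward model.
#'
#' @return An `hu_curve`.
#' @export
default_hu_curve <- function() {
  if (is.null(.rhozeff_cache$hu_curve)) {
    .rhozeff_cache$hu_curve <- fit_hu_curve(simulated_insert_points())
  }
  .rhozeff_cache$hu_curve
}

# save/restore global RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
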
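# Monotonic cubic calibration between rho*Zeff and CBCT number, fitted on
# scanned inserts of known composition and inverted numerically for voxel
# assignment.

#' Fit the cubic CBCT-number calibration curve
#'
#' Ordinary least-squares fit of HU = c0 + c1 x + c2 x^2 + c3 x^3 with
#' x = rho*Zeff, on at least five distinct calibration points (one per scanned
#' insert). The reported `r_squared` is the squared Pearson correlation
#' between fitted and observed HU. Monotonicity of the fitted polynomial over
#' the data range is checked analytically (sign of the derivative at the
#' domain endpoints and at the derivative's interior extremum); voxel
#' assignment through [invert_hu()] requires a monotonic curve.
#'
#' @param points Data frame with columns `rho_zeff` (> 0, g/cm3) and `hu`.
#' @return An object of class `hu_curve`: `coeffs` (c0..c3), `domain`
#'   (range of `rho_zeff`), `r_squared`, `monotonic`, `n`.
#' @examples
#' pts <- tibble::tibble(rho_zeff = 2:7, hu = -773 + 100 * (2:7))
#' fit_hu_curve(pts)
#' @export
fit_hu_curve <- function(points) {
  if (!all(c("rho_zeff", "hu") %in% names(points))) {
    abort("`points` needs `rho_zeff` and `hu` columns.")
  }
  x <- points$rho_zeff
  y <- points$hu
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0)) {
    abort("Calibration points must be finite with rho_zeff > 0.")
  }
  if (length(unique(x)) < 5L) {
    abort("At least 5 distinct calibration points are required for a cubic fit.")
  }
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  co <- unname(coef(fit))
  co[is.na(co)] <- 0
  names(co) <- paste0("c", 0:3)
  domain <- range(x)
  r2 <- stats::cor(fitted(fit), y)^2
  curve <- structure(
    list(coeffs = co, domain = domain, r_squared = r2,
         monotonic = poly3_monotonic(co, domain), n = length(x)),
    class = "hu_curve"
  )
  if (!curve$monotonic) {
    warn("Fitted calibration curve is not monotonic over its domain; inversion is disabled. Recalibrate with better-spread inserts.")
  }
  curve
}

poly3_eval <- function(co, x) unname(co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3)

# dHU/dx > 0 over [domain]? derivative is quadratic: check endpoints and the
# interior stationary point of the derivative.
poly3_monotonic <- function(co, domain) {
  d <- function(x) co[2] + 2 * co[3] * x + 3 * co[4] * x^2
  xs <- domain
  if (co[4] != 0) {
    xv <- -co[3] / (3 * co[4])
    if (xv > domain[1] && xv < domain[2]) xs <- c(xs, xv)
  }
  all(d(xs) > 0)
}

#' @export
print.hu_curve <- function(x, ...) {
  cat(sprintf("<hu_curve> HU = %.4g + %.4g x + %.4g x^2 + %.4g x^3  (x = rho*Zeff)\n",
              x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4]))
  cat(sprintf("  domain [%.3g, %.3g] g/cm3, n = %d, R^2 = %.5f, %s\n",
              x$domain[1], x$domain[2], x$n, x$r_squared,
              if (x$monotonic) "monotonic" else "NOT monotonic"))
  invisible(x)
}

#' @export
tidy.hu_curve <- function(x, ...) {
  tibble::tibble(term = names(x$coeffs), estimate = unname(x$coeffs))
}

#' @export
glance.hu_curve <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, monotonic = x$monotonic,
                 n = x$n, domain_lo = x$domain[1], domain_hi = x$domain[2])
}

#' Predict CBCT number from rho*Zeff
#'
#' Evaluates the calibration polynomial. Values outside the calibrated domain
#' are extrapolated, with a warning identifying how many points fell outside.
#'
#' @param curve An [fit_hu_curve()] result.
#' @param rho_zeff Numeric vector of density--Zeff products (g/cm3).
#' @return Numeric vector of HU.
#' @export
predict_hu <- function(curve, rho_zeff) {
  stopifnot(inherits(curve, "hu_curve"))
  outside <- rho_zeff < curve$domain[1] | rho_zeff > curve$domain[2]
  if (any(outside)) {
    warn(sprintf("%d value(s) outside the calibrated domain [%.3g, %.3g]; extrapolating.",
                 sum(outside), curve$domain[1], curve$domain[2]))
  }
  poly3_eval(curve$coeffs, rho_zeff)
}

#' @export
predict.hu_curve <- function(object, rho_zeff, ...) predict_hu(object, rho_zeff)

#' Invert the calibration curve: CBCT number to rho*Zeff
#'
#' Numerical inversion by bisection to |delta HU| < 1e-6. HU values below the
#' curve's value at the lower domain end clamp to the lower end (and likewise
#' at the top), so out-of-range voxels (air streaks, beam-hardening
#' artifacts, metal) map to the nearest physical material; the `clamped`
#' column reports which inputs were clamped.
#'
#' @param curve A monotonic [fit_hu_curve()] result.
#' @param hu Numeric vector of CBCT numbers.
#' @param detail If `TRUE` return a tibble with columns `hu`, `rho_zeff`,
#'   `clamped`; otherwise a bare numeric vector.
#' @param tol Bisection tolerance in HU.
#' @return Numeric vector (or tibble, see `detail`) of rho*Zeff values.
#' @export
invert_hu <- function(curve, hu, detail = FALSE, tol = 1e-6) {
  stopifnot(inherits(curve, "hu_curve"))
  if (!curve$monotonic) {
    abort("Calibration curve is not monotonic; inversion is undefined. Recalibrate (see fit_hu_curve).")
  }
  lo <- curve$domain[1]; hi <- curve$domain[2]
  f_lo <- poly3_eval(curve$coeffs, lo)
  f_hi <- poly3_eval(curve$coeffs, hi)
  one <- function(h) {
    if (h <= f_lo) return(c(lo, h < f_lo))
    if (h >= f_hi) return(c(hi, h > f_hi))
    a <- lo; b <- hi
    repeat {
      m <- (a + b) / 2
      fm <- poly3_eval(curve$coeffs, m)
      if (abs(fm - h) < tol || (b - a) < .Machine$double.eps * max(1, abs(b))) {
        return(c(m, FALSE))
      }
      if (fm < h) a <- m else b <- m
    }
  }
  res <- vapply(hu, one, numeric(2))
  if (detail) {
    tibble::tibble(hu = hu, rho_zeff = res[1, ], clamped = as.logical(res[2, ]))
  } else {
    res[1, ]
  }
}

#' Serialize a calibration curve to JSON and back
#'
#' @param curve An `hu_curve`.
#' @param path JSON file path.
#' @return `write_hu_curve()` returns `path` invisibly; `read_hu_curve()`
#'   returns the curve.
#' @export
write_hu_curve <- function(curve, path) {
  stopifnot(inherits(curve, "hu_curve"))
  jsonlite::write_json(
    list(coeffs = as.list(curve$coeffs), domain = curve$domain,
         r_squared = curve$r_squared, monotonic = curve$monotonic, n = curve$n),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_hu_curve
#' @export
read_hu_curve <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(coeffs = setNames(as.numeric(j$coeffs), paste0("c", 0:3)),
         domain = as.numeric(j$domain), r_squared = j$r_squared,
         monotonic = j$monotonic, n = j$n),
    class = "hu_curve"
  )
}
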
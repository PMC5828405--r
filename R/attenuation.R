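# Parameterized photon attenuation (Jackson-Hawkes form) and the classic
# stoichiometric Hounsfield calibration. The attenuation coefficient is
#   mu = rho * sum_i (w_i / A_i) * (kKN * Z_i + kph * Z_i^4.62 + ksca * Z_i^2.86)
# in arbitrary units: Avogadro's number and the overall scale cancel in the
# CT-number ratio mu / mu_water, so only coefficient ratios are identifiable.

PH_EXPONENT  <- 4.62
SCA_EXPONENT <- 2.86

#' Attenuation coefficient set
#'
#' The three coefficients of the parameterized attenuation model:
#' Klein--Nishina (Compton, proportional to Z), photoelectric (Z^4.62) and
#' coherent/incoherent scattering (Z^2.86). Units are arbitrary; only ratios
#' affect CT numbers, so fits fix `k_kn = 1`.
#'
#' @param k_kn,k_ph,k_sca Non-negative coefficients, at least one nonzero.
#' @return An object of class `attenuation_coeffs`.
#' @examples
#' attenuation_coeffs(1, 1e-4, 5e-3)
#' @export
attenuation_coeffs <- function(k_kn = 1, k_ph = 0, k_sca = 0) {
  k <- c(k_kn = k_kn, k_ph = k_ph, k_sca = k_sca)
  if (!is.numeric(k) || anyNA(k)) abort("Coefficients must be numeric.")
  if (all(k == 0)) abort("At least one attenuation coefficient must be nonzero.")
  structure(as.list(k), class = "attenuation_coeffs")
}

#' @export
print.attenuation_coeffs <- function(x, ...) {
  cat(sprintf("<attenuation_coeffs> kKN = %g, kph = %g, ksca = %g\n",
              x$k_kn, x$k_ph, x$k_sca))
  invisible(x)
}

# per-material basis integrals F = (F_kn, F_ph, F_sca), with
# F_term = sum_i (w_i / A_i) Z_i^p; mu = rho * F %*% k
attenuation_basis <- function(data) {
  cols <- element_cols(data)
  if (length(cols) == 0L) abort("No element columns found in `data`.")
  pd <- periodic_elements()
  idx <- match(cols, pd$symbol)
  w <- as.matrix(data[cols])
  w[is.na(w)] <- 0
  wa <- sweep(w, 2L, pd$a[idx], "/")
  cbind(
    f_kn  = as.vector(wa %*% pd$z[idx]),
    f_ph  = as.vector(wa %*% pd$z[idx]^PH_EXPONENT),
    f_sca = as.vector(wa %*% pd$z[idx]^SCA_EXPONENT)
  )
}

#' Parameterized attenuation coefficient of each material
#'
#' Tidy verb: appends a `mu` column (arbitrary units) to a materials table.
#' `mu` is linear in `rho` and in each coefficient.
#'
#' @param data Materials table with `rho` and element mass-fraction columns.
#' @param coeffs An [attenuation_coeffs()].
#' @return `data` as a tibble with a `mu` column appended.
#' @export
attenuation_mu <- function(data, coeffs) {
  stopifnot(inherits(coeffs, "attenuation_coeffs"))
  if (!"rho" %in% names(data)) abort("`data` needs a `rho` column (g/cm3).")
  f <- attenuation_basis(data)
  k <- c(coeffs$k_kn, coeffs$k_ph, coeffs$k_sca)
  out <- tibble::as_tibble(data)
  out$mu <- data$rho * as.vector(f %*% k)
  out
}

water_composition <- function() {
  w <- icru_tissues()
  w[w$name == "water", ]
}

#' Predicted CT number of each material
#'
#' CT number = 1000 * (mu / mu_water - 1), with mu_water computed from the
#' packaged water composition using the same coefficients. Water maps to 0 HU
#' by construction; a material with zero attenuation maps to -1000 HU.
#'
#' @inheritParams attenuation_mu
#' @return `data` as a tibble with a `hu_pred` column appended.
#' @examples
#' ct_number(icru_tissues(), attenuation_coeffs(1, 1e-4, 5e-3))[, c("name", "hu_pred")]
#' @export
ct_number <- function(data, coeffs) {
  mu <- attenuation_mu(data, coeffs)$mu
  mu_w <- attenuation_mu(water_composition(), coeffs)$mu
  if (mu_w == 0) abort("mu(water) is zero with these coefficients; CT numbers are undefined.")
  out <- tibble::as_tibble(data)
  out$hu_pred <- 1000 * (mu / mu_w - 1)
  out
}

#' Stoichiometric Hounsfield calibration
#'
#' Fits the photoelectric and scattering coefficients of the parameterized
#' attenuation model (Klein--Nishina fixed at 1 for identifiability) to
#' measured CT numbers of materials of known density and composition, by
#' least squares on predicted-vs-measured HU. Because the fitted coefficients
#' also enter the water normalization, the linear solve is alternated with a
#' water renormalization until predicted HU change by less than `tol`
#' (default 1e-6 HU).
#'
#' This is the classic fan-beam CT calibration; on cone-beam data with heavy
#' scatter it typically leaves residuals of hundreds of HU, which is the
#' motivation for the rho*Zeff calibration in [fit_hu_curve()].
#'
#' @param data Materials table with `rho`, element columns, and a measured HU
#'   column.
#' @param hu_col Name of the measured HU column (default `"measured_hu"`).
#' @param tol,max_iter Convergence tolerance on predicted HU and iteration cap.
#' @return An object of class `stoich_fit` with elements `coefficients`
#'   (an [attenuation_coeffs()]), `residuals` (tibble: name, measured, fitted,
#'   residual), `rms_hu`, `iterations`, `converged`.
#' @export
fit_stoichiometric <- function(data, hu_col = "measured_hu",
                               tol = 1e-6, max_iter = 100L) {
  if (!hu_col %in% names(data)) {
    abort(paste0("`data` has no `", hu_col, "` column."))
  }
  if (nrow(data) < 3L) abort("At least 3 materials are required for the stoichiometric fit.")
  hu <- data[[hu_col]]
  f <- attenuation_basis(data) * data$rho           # mu = F_rho %*% k
  fw <- attenuation_basis(water_composition()) * 1.00
  if (qr(f)$rank < 3L) {
    abort("Design is rank-deficient (materials do not span the three attenuation terms).")
  }
  k <- c(1, 0, 0)
  pred_old <- rep(Inf, nrow(data))
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    mu_w <- as.vector(fw %*% k)
    # with mu_w frozen, HU = 1000 * (F k / mu_w) - 1000 is linear in k
    x <- 1000 * f / mu_w
    k_new <- qr.solve(x, hu + 1000)
    if (k_new[1] == 0) abort("Degenerate fit: Klein-Nishina coefficient collapsed to zero.")
    k <- k_new / k_new[1]                            # fix kKN = 1
    mu_w <- as.vector(fw %*% k)
    pred <- 1000 * (as.vector(f %*% k) / mu_w - 1)
    if (max(abs(pred - pred_old)) < tol) { converged <- TRUE; break }
    pred_old <- pred
  }
  # the alternating fixed point ignores the dependence of mu_water on the
  # coefficients, so under noise it can sit off the true least-squares
  # optimum; polish with a full nonlinear minimization of the HU objective
  obj <- function(p) {
    kk <- c(1, p)
    mw <- as.vector(fw %*% kk)
    if (mw <= 0) return(Inf)
    sum((1000 * (as.vector(f %*% kk) / mw - 1) - hu)^2)
  }
  ps <- pmax(abs(k[2:3]), c(1e-6, 1e-4))
  pol <- stats::optim(k[2:3], obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15, parscale = ps))
  if (pol$value <= obj(k[2:3])) k <- c(1, pol$par)
  mu_w <- as.vector(fw %*% k)
  pred <- 1000 * (as.vector(f %*% k) / mu_w - 1)
  resid <- pred - hu
  structure(
    list(
      coefficients = attenuation_coeffs(k[1], k[2], k[3]),
      residuals = tibble::tibble(
        name = if ("name" %in% names(data)) data$name else as.character(seq_along(hu)),
        measured = hu, fitted = pred, residual = resid
      ),
      rms_hu = sqrt(mean(resid^2)),
      iterations = iterations,
      converged = converged
    ),
    class = "stoich_fit"
  )
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat("<stoich_fit> stoichiometric HU calibration\n")
  print(x$coefficients)
  cat(sprintf("  %d materials, RMS residual %.2f HU, %d iteration(s)%s\n",
              nrow(x$residuals), x$rms_hu, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
tidy.stoich_fit <- function(x, ...) x$residuals

#' @export
glance.stoich_fit <- function(x, ...) {
  tibble::tibble(
    k_kn = x$coefficients$k_kn, k_ph = x$coefficients$k_ph,
    k_sca = x$coefficients$k_sca, rms_hu = x$rms_hu,
    n = nrow(x$residuals), iterations = x$iterations, converged = x$converged
  )
}
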
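# Artificial "dose-equivalent" tissue database: materials interpolated between
# reference ICRU tissues on a regular rho*Zeff lattice so that neighboring
# materials differ by a dose-equivalence step, with an HU interval attached to
# each for voxel assignment.

#' Regular rho*Zeff grid for the tissue database
#'
#' The default lattice `{2.0 + 0.2 k, k = 0..124}` spans inflated lung to
#' cortical bone in steps of 0.2 g/cm3 and carries 125 values.
#'
#' @param start,stop Grid endpoints (g/cm3), `start < stop`.
#' @param step Grid spacing (g/cm3), default 0.2.
#' @return Numeric vector of grid values.
#' @examples
#' length(tissue_grid())  # 125
#' @export
tissue_grid <- function(start = 2.0, stop = 26.8, step = 0.2) {
  if (!(start < stop) || step <= 0) abort("Need start < stop and step > 0.")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9) {
    abort("(stop - start) / step must be an integer.")
  }
  start + step * (0:round(k))
}

# neighbors of `target` in the reference table's rho_zeff coordinate; at the
# extreme ends the nearest pair is kept and t is clamped to [0, 1].
anchor_pair <- function(target, x) {
  n <- length(x)
  i <- findInterval(target, x, rightmost.closed = TRUE)
  if (i < 1L) i <- 1L
  if (i >= n) i <- n - 1L
  below <- i; above <- i + 1L
  dx <- x[above] - x[below]
  t <- if (dx == 0) 0 else (target - x[below]) / dx
  list(below = below, above = above, t = min(max(t, 0), 1))
}

#' Interpolate one artificial dose-equivalent tissue
#'
#' Constructs a material of prescribed rho*Zeff by constrained interpolation
#' between the two nearest reference tissues (neighbors in rho*Zeff):
#' the target Zeff and the elemental mass fractions are linearly interpolated
#' with the same weight; Zeff is then recomputed from the interpolated
#' fractions, and while it deviates from the interpolated target by more than
#' `zeff_tol` (relative), 0.001 of mass is transferred within the
#' regime-dependent element pair - carbon/oxygen below `pair_switch` g/cm3,
#' phosphorus/calcium at or above it - raising the higher-Z member when Zeff
#' is too low. The mass-fraction sum is then restored to 1 through hydrogen
#' (whose Z = 1 has negligible leverage on Zeff), and the density follows as
#' rho = target / Zeff.
#'
#' @param target Prescribed rho*Zeff (g/cm3), within the reference table's
#'   span.
#' @param icru_table Reference table sorted by `printed_rho_zeff`
#'   (default [icru_tissues()]).
#' @param zeff_def Zeff convention, default [default_zeff_definition()].
#' @param zeff_tol Relative Zeff tolerance triggering mass adjustment
#'   (default 0.05).
#' @param pair_switch rho*Zeff boundary between the C/O and P/Ca adjustment
#'   regimes (default 10; targets at exactly 10 use P/Ca).
#' @param max_iter Iteration cap for the 0.001-step adjustment.
#' @return One-row tibble: `target_rho_zeff`, `zeff`, `rho`, `anchor_lo`,
#'   `anchor_hi`, `t`, `adjustment_iterations`, and element mass-fraction
#'   columns.
#' @examples
#' interpolate_tissue(25.0)  # anchored on child and adult cortical bone
#' @export
interpolate_tissue <- function(target,
                               icru_table = icru_tissues(),
                               zeff_def = default_zeff_definition(),
                               zeff_tol = 0.05,
                               pair_switch = 10,
                               max_iter = 2000L) {
  x <- icru_table$printed_rho_zeff
  if (is.unsorted(x)) abort("`icru_table` must be sorted by printed_rho_zeff.")
  if (target < x[1] - 0.25 || target > x[length(x)] + 0.25) {
    abort(sprintf("Target rho*Zeff = %.3g is outside the reference table range [%.3g, %.3g].",
                  target, x[1], x[length(x)]))
  }
  a <- anchor_pair(target, x)
  z_lo <- icru_table$printed_zeff[a$below]
  z_hi <- icru_table$printed_zeff[a$above]
  z_target <- z_lo + a$t * (z_hi - z_lo)
  cols <- element_cols(icru_table)
  w_lo <- as.numeric(icru_table[a$below, cols])
  w_hi <- as.numeric(icru_table[a$above, cols])
  w <- setNames((1 - a$t) * w_lo + a$t * w_hi, cols)

  pair <- if (target < pair_switch) c("C", "O") else c("P", "Ca")
  step <- 0.001
  z_cur <- compute_zeff(w[w > 0], zeff_def)
  iter <- 0L
  while (abs(z_cur - z_target) / z_target > zeff_tol) {
    if (iter >= max_iter) {
      abort(sprintf("Zeff adjustment did not converge for target %.3g after %d iterations.",
                    target, max_iter))
    }
    raise <- z_cur < z_target     # need more of the higher-Z member
    recipient <- if (raise) pair[2] else pair[1]
    donor     <- if (raise) pair[1] else pair[2]
    if (w[donor] >= step) {
      w[donor] <- w[donor] - step
      w[recipient] <- w[recipient] + step
    } else if (raise && w["H"] >= step) {
      # donor exhausted: push the high-Z recipient up, hydrogen compensating
      w[recipient] <- w[recipient] + step
      w["H"] <- w["H"] - step
    } else if (!raise && w[recipient] >= step) {
      # donor exhausted: pull the low-Z recipient down into hydrogen
      w[recipient] <- w[recipient] - step
      w["H"] <- w["H"] + step
    } else {
      abort(sprintf("Adjustment pair %s/%s exhausted for target %.3g.",
                    pair[1], pair[2], target))
    }
    if (w[recipient] < 0 || w["H"] < 0) {
      abort(sprintf("Mass fraction driven below zero for target %.3g.", target))
    }
    z_cur <- compute_zeff(w[w > 0], zeff_def)
    iter <- iter + 1L
  }
  # restore the mass-fraction sum to exactly 1 through hydrogen
  w["H"] <- w["H"] + (1 - sum(w))
  if (w["H"] < 0) {
    abort(sprintf("Hydrogen renormalization drove H below zero for target %.3g.", target))
  }
  z_cur <- compute_zeff(w[w > 0], zeff_def)
  out <- tibble::tibble(
    target_rho_zeff = target,
    zeff = z_cur,
    rho = target / z_cur,
    anchor_lo = icru_table$name[a$below],
    anchor_hi = icru_table$name[a$above],
    t = a$t,
    adjustment_iterations = iter
  )
  out[cols] <- as.list(w)
  out
}

#' Attach an HU interval to each tissue of an ordered database
#'
#' The boundary between two consecutive tissues is the midpoint of their
#' predicted CBCT numbers; intervals are half-open `[lo, hi)` and tile the HU
#' axis without gaps, the first extending down to -1000 (in practice floored
#' by the air threshold during segmentation) and the last up to 32767.
#'
#' @param tissues Tibble sorted by `target_rho_zeff`.
#' @param curve A monotonic [fit_hu_curve()] result.
#' @return `tissues` with `hu_center`, `hu_lo`, `hu_hi` columns.
#' @export
assign_hu_intervals <- function(tissues, curve) {
  stopifnot(inherits(curve, "hu_curve"))
  if (is.unsorted(tissues$target_rho_zeff, strictly = TRUE)) {
    abort("`tissues` must be strictly increasing in target_rho_zeff.")
  }
  hu <- suppressWarnings(predict_hu(curve, tissues$target_rho_zeff))
  if (is.unsorted(hu, strictly = TRUE)) {
    abort("Predicted HU sequence is not strictly increasing; the curve is unusable for interval assignment.")
  }
  mid <- (head(hu, -1) + tail(hu, -1)) / 2
  out <- tissues
  out$hu_center <- hu
  out$hu_lo <- c(-1000, mid)
  out$hu_hi <- c(mid, 32767)
  out
}

#' Build the artificial dose-equivalent tissue database
#'
#' Runs [interpolate_tissue()] for every grid value and attaches HU intervals
#' through [assign_hu_intervals()]. With the default grid this produces 125
#' artificial tissues from rho*Zeff = 2.0 to 26.8 g/cm3 in steps of 0.2.
#'
#' @param curve A monotonic [fit_hu_curve()] result (default
#'   [default_hu_curve()]).
#' @param grid Numeric grid of target rho*Zeff values, default
#'   [tissue_grid()].
#' @inheritParams interpolate_tissue
#' @return An object of class `tissue_db`: `tissues` (tibble with
#'   compositions and HU intervals), `curve`, `grid`, `fixture_version`.
#' @examples
#' \donttest{
#' db <- build_tissue_db()
#' nrow(db$tissues)  # 125
#' }
#' @export
build_tissue_db <- function(curve = default_hu_curve(),
                            grid = tissue_grid(),
                            icru_table = icru_tissues(),
                            zeff_def = default_zeff_definition()) {
  stopifnot(inherits(curve, "hu_curve"))
  if (!curve$monotonic) abort("Database construction requires a monotonic calibration curve.")
  rows <- lapply(grid, function(g) {
    tryCatch(
      interpolate_tissue(g, icru_table, zeff_def),
      error = function(e) {
        abort(sprintf("Tissue generation failed at grid value %.3g: %s",
                      g, conditionMessage(e)))
      }
    )
  })
  tissues <- bind_rows(rows)
  tissues$name <- sprintf("tissue_rz_%05.1f", tissues$target_rho_zeff)
  tissues <- assign_hu_intervals(tissues, curve)
  tissues <- tissues[c("name", setdiff(names(tissues), "name"))]
  structure(
    list(tissues = tissues, curve = curve,
         grid = list(start = grid[1], stop = grid[length(grid)],
                     step = if (length(grid) > 1) grid[2] - grid[1] else NA_real_),
         fixture_version = icru_fixture_version),
    class = "tissue_db"
  )
}

#' @export
print.tissue_db <- function(x, ...) {
  cat(sprintf("<tissue_db> %d artificial dose-equivalent tissues, rho*Zeff %.3g to %.3g (step %.3g) g/cm3\n",
              nrow(x$tissues), x$grid$start, x$grid$stop, x$grid$step))
  cat(sprintf("  HU span [%.1f, %.1f], fixture %s\n",
              min(x$tissues$hu_center), max(x$tissues$hu_center), x$fixture_version))
  invisible(x)
}

#' @export
tidy.tissue_db <- function(x, ...) x$tissues

#' @export
glance.tissue_db <- function(x, ...) {
  tibble::tibble(
    n_tissues = nrow(x$tissues),
    grid_start = x$grid$start, grid_stop = x$grid$stop, grid_step = x$grid$step,
    hu_min = min(x$tissues$hu_center), hu_max = max(x$tissues$hu_center),
    fixture_version = x$fixture_version
  )
}

#' Serialize a tissue database to JSON / CSV and back
#'
#' JSON keeps the full provenance (grid, curve, fixture version) and is
#' loss-free at double precision; the CSV holds one row per tissue.
#'
#' @param db A `tissue_db`.
#' @param path Output path.
#' @return Writers return `path` invisibly; `read_tissue_db()` returns the
#'   database.
#' @export
write_tissue_db <- function(db, path) {
  stopifnot(inherits(db, "tissue_db"))
  jsonlite::write_json(
    list(tissues = db$tissues, grid = db$grid,
         curve = list(coeffs = as.list(db$curve$coeffs), domain = db$curve$domain,
                      r_squared = db$curve$r_squared, monotonic = db$curve$monotonic,
                      n = db$curve$n),
         fixture_version = db$fixture_version),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname write_tissue_db
#' @export
read_tissue_db <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      tissues = tibble::as_tibble(j$tissues),
      curve = structure(
        list(coeffs = setNames(as.numeric(j$curve$coeffs), paste0("c", 0:3)),
             domain = as.numeric(j$curve$domain), r_squared = j$curve$r_squared,
             monotonic = j$curve$monotonic, n = j$curve$n),
        class = "hu_curve"
      ),
      grid = j$grid,
      fixture_version = j$fixture_version
    ),
    class = "tissue_db"
  )
}

#' @rdname write_tissue_db
#' @export
write_tissue_db_csv <- function(db, path) {
  stopifnot(inherits(db, "tissue_db"))
  write.csv(db$tissues, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
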
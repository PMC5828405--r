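# Synthetic digital phantoms: geometric ground-truth label volumes plus a
# forward model (calibration curve + additive Gaussian HU noise) that turns
# them into CBCT-like images, so the whole segmentation pipeline is testable
# without a scanner.

#' Specify a digital phantom
#'
#' A phantom is a voxel grid with an ordered list of geometric regions; later
#' regions overwrite earlier ones, and a voxel belongs to a region when its
#' center does (no partial-volume mixing, so ground truth is unambiguous).
#'
#' @param dim Grid dimensions `(nx, ny, nz)`.
#' @param spacing Voxel spacing in mm.
#' @param origin World position of voxel (0, 0, 0) in mm.
#' @param regions Tibble with columns `material` (name), `shape` (`"cylinder"`
#'   along z, `"ellipsoid"`, or `"box"`), `cx, cy, cz` (center, mm) and
#'   `rx, ry, rz` (radii / half-widths, mm; a cylinder uses `rx` as radius and
#'   `rz` as half-length).
#' @param background Background material name, or `"air"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim, spacing = c(0.2, 0.2, 0.2), origin = c(0, 0, 0),
                         regions = NULL, background = "air") {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) abort("`dim` must be 3 positive integers.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) abort("`spacing` must be 3 positive numbers.")
  if (is.null(regions)) {
    regions <- tibble::tibble(material = character(), shape = character(),
                              cx = numeric(), cy = numeric(), cz = numeric(),
                              rx = numeric(), ry = numeric(), rz = numeric())
  }
  stopifnot(all(c("material", "shape", "cx", "cy", "cz", "rx", "ry", "rz") %in% names(regions)))
  if (!all(regions$shape %in% c("cylinder", "ellipsoid", "box"))) {
    abort("Region shapes must be cylinder, ellipsoid or box.")
  }
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin),
                 regions = tibble::as_tibble(regions), background = background),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d voxels at (%g, %g, %g) mm, %d region(s), background %s\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$spacing[2], x$spacing[3],
              nrow(x$regions), x$background))
  invisible(x)
}

#' Rasterize a phantom into a ground-truth label volume
#'
#' Voxels take the label of the last region containing their center;
#' elsewhere the background (label 0 when the background is `"air"`). The
#' legend maps each label to its material name; region materials get labels
#' 1, 2, ... in order of first appearance, a non-air background gets its own
#' label.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mats <- unique(c(if (spec$background != "air") spec$background,
                   spec$regions$material))
  legend <- tibble::tibble(label = seq_along(mats), name = mats)
  lab0 <- if (spec$background == "air") 0L else legend$label[legend$name == spec$background]
  labels <- array(lab0, dim = spec$dim)
  cx <- spec$origin[1] + (seq_len(spec$dim[1]) - 1) * spec$spacing[1]
  cy <- spec$origin[2] + (seq_len(spec$dim[2]) - 1) * spec$spacing[2]
  cz <- spec$origin[3] + (seq_len(spec$dim[3]) - 1) * spec$spacing[3]
  gx <- array(cx, dim = spec$dim)
  gy <- array(rep(cy, each = spec$dim[1]), dim = spec$dim)
  gz <- array(rep(cz, each = spec$dim[1] * spec$dim[2]), dim = spec$dim)
  for (k in seq_len(nrow(spec$regions))) {
    r <- spec$regions[k, ]
    dx <- gx - r$cx; dy <- gy - r$cy; dz <- gz - r$cz
    inside <- switch(r$shape,
      cylinder  = (dx / r$rx)^2 + (dy / r$rx)^2 <= 1 & abs(dz) <= r$rz,
      ellipsoid = (dx / r$rx)^2 + (dy / r$ry)^2 + (dz / r$rz)^2 <= 1,
      box       = abs(dx) <= r$rx & abs(dy) <= r$ry & abs(dz) <= r$rz
    )
    labels[inside] <- legend$label[legend$name == r$material]
  }
  label_volume(labels, legend, spacing = spec$spacing, origin = spec$origin)
}

#' Simulate a CBCT volume from a ground-truth label map
#'
#' Forward model: each voxel's HU is the calibration curve evaluated at its
#' material's rho*Zeff, plus additive Gaussian noise (air voxels take
#' -1000 + noise). Acquisition noise on this scanner class is bounded by
#' about 30 HU, so `sigma` in `[0, 30]` is the realistic range; the same seed
#' always reproduces the same volume bit for bit.
#'
#' @param truth A [label_volume()] ground truth.
#' @param materials Data frame mapping `name` to `rho_zeff` for every legend
#'   material (e.g. [icru_tissues()] renamed, or `db$tissues`).
#' @param curve A monotonic [fit_hu_curve()] result.
#' @param sigma Gaussian HU noise standard deviation, >= 0.
#' @param seed Integer seed for the noise.
#' @return An [image_volume()] of simulated CBCT numbers.
#' @export
simulate_hu <- function(truth, materials, curve = default_hu_curve(),
                        sigma = 0, seed = 1L) {
  stopifnot(inherits(truth, "label_volume"), inherits(curve, "hu_curve"))
  if (sigma < 0) abort("`sigma` must be >= 0.")
  rz_col <- if ("rho_zeff" %in% names(materials)) "rho_zeff" else "target_rho_zeff"
  if (!all(c("name", rz_col) %in% names(materials))) {
    abort("`materials` needs `name` and `rho_zeff` (or `target_rho_zeff`) columns.")
  }
  missing <- setdiff(truth$legend$name, materials$name)
  if (length(missing) > 0L) {
    abort(paste0("No rho_zeff known for material(s): ", paste(missing, collapse = ", ")))
  }
  rz <- materials[[rz_col]][match(truth$legend$name, materials$name)]
  hu_by_label <- c(-1000, suppressWarnings(predict_hu(curve, rz)))  # index 1 = label 0 (air)
  hu <- hu_by_label[as.vector(truth$labels) + 1L]
  if (sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    hu <- hu + rnorm(length(hu), 0, sigma)
  }
  image_volume(array(hu, dim = dim(truth$labels)),
               spacing = truth$spacing, origin = truth$origin)
}

#' Default digital phantoms
#'
#' Two deterministic specs: an eight-insert cylinder battery spanning soft
#' tissue to cortical bone (a digital stand-in for a physical calibration
#' phantom), and a mouse-like phantom (ellipsoidal soft-tissue body with two
#' inflated-lung pockets and two femur-like bone rods in air background).
#' Materials are named after [icru_tissues()] rows.
#'
#' @param spacing Voxel spacing in mm (default 0.2 isotropic).
#' @return A list with elements `cylinders` and `mouse`, both
#'   [phantom_spec()]s.
#' @export
make_default_phantoms <- function(spacing = c(0.2, 0.2, 0.2)) {
  ins <- c("lung_inflated", "adipose", "water", "muscle",
           "thyroid", "spongiosa", "humerus", "cortical_bone")
  ang <- 2 * pi * (seq_along(ins) - 1) / length(ins)
  cylinders <- phantom_spec(
    dim = round(c(16, 16, 4.8) / spacing), spacing = spacing,
    regions = tibble::tibble(
      material = ins, shape = "cylinder",
      cx = 8 + 5 * cos(ang), cy = 8 + 5 * sin(ang), cz = 2.4,
      rx = 1.6, ry = 1.6, rz = 2.0
    ),
    background = "water"
  )
  mouse <- phantom_spec(
    dim = round(c(24, 16, 9.6) / spacing), spacing = spacing,
    regions = tibble::tibble(
      material = c("soft_tissue_male", "lung_inflated", "lung_inflated",
                   "femur", "femur"),
      shape = c("ellipsoid", "ellipsoid", "ellipsoid", "cylinder", "cylinder"),
      cx = c(12, 9.0, 15.0, 7, 17),
      cy = c(8, 8, 8, 8, 8),
      cz = c(4.8, 4.8, 4.8, 4.8, 4.8),
      rx = c(10, 2.0, 2.0, 0.8, 0.8),
      ry = c(6, 1.6, 1.6, 0.8, 0.8),
      rz = c(4.0, 1.8, 1.8, 3.4, 3.4)
    ),
    background = "air"
  )
  list(cylinders = cylinders, mouse = mouse)
}

#' rho*Zeff lookup for the reference tissues
#'
#' Convenience mapping from reference tissue name to its tabulated rho*Zeff,
#' for use as the `materials` argument of [simulate_hu()].
#'
#' @return Tibble with `name` and `rho_zeff`.
#' @export
icru_rho_zeff <- function() {
  t <- icru_tissues()
  tibble::tibble(name = t$name, rho_zeff = t$printed_rho_zeff)
}
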
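# Per-voxel tissue assignment: a pure map from HU through the database's
# half-open intervals, with an explicit air rule below a configurable
# threshold (mice contain air cavities and the scanner background is air,
# although published tissue tables start at inflated lung).

#' Assign an artificial tissue to every voxel
#'
#' Voxels with HU below `air_threshold` become label 0 (air); every other
#' voxel gets the unique tissue whose half-open HU interval `[lo, hi)`
#' contains its value. Ties at a boundary go to the upper tissue. HU above the
#' last interval clamps into the last tissue (interval tops at 32767). The
#' mapping is per-voxel, so it is idempotent and independent of voxel order,
#' and conserves the voxel count.
#'
#' @param volume An [image_volume()] of CBCT numbers.
#' @param db A [build_tissue_db()] result.
#' @param air_threshold HU below which a voxel is air (default -850: between
#'   the -1000 HU of air and the HU the default curve assigns to the lightest
#'   tissue, about -720; configurable because the right value depends on the
#'   scanner's calibration curve).
#' @return A [label_volume()]; label `i` refers to row `i` of `db$tissues`.
#' @export
segment_volume <- function(volume, db, air_threshold = -850) {
  stopifnot(inherits(volume, "image_volume"), inherits(db, "tissue_db"))
  if (length(volume$values) == 0L) abort("Empty volume.")
  lo <- db$tissues$hu_lo
  if (is.unsorted(lo, strictly = TRUE)) abort("Database HU intervals are not ordered.")
  if (air_threshold > db$tissues$hu_center[1]) {
    warn("`air_threshold` exceeds the lightest tissue's nominal HU; that tissue cannot be assigned.")
  }
  hu <- as.vector(volume$values)
  idx <- findInterval(hu, lo)              # [lo_i, lo_{i+1}) -> i
  idx <- pmin(pmax(idx, 1L), nrow(db$tissues))
  idx[hu < air_threshold] <- 0L
  legend <- tibble::tibble(label = seq_len(nrow(db$tissues)),
                           name = db$tissues$name,
                           target_rho_zeff = db$tissues$target_rho_zeff)
  label_volume(array(as.integer(idx), dim = dim(volume$values)),
               legend = legend, spacing = volume$spacing, origin = volume$origin)
}

#' Label histogram of a segmented volume
#'
#' @param labels A [label_volume()].
#' @return Tibble with `label`, `name`, `n_voxels`, sorted by label (label 0
#'   reported as `"air"`).
#' @export
label_histogram <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  tab <- table(factor(as.vector(labels$labels)))
  out <- tibble::tibble(label = as.integer(names(tab)), n_voxels = as.integer(tab))
  legend <- bind_rows(tibble::tibble(label = 0L, name = "air"),
                      labels$legend[c("label", "name")])
  left_join(out, legend, by = "label")[c("label", "name", "n_voxels")]
}

#' Write the label legend as JSON
#'
#' @param labels A [label_volume()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_legend <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  jsonlite::write_json(list(air_label = 0L, legend = labels$legend),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Override labels inside a mask
#'
#' Manual region override for artifact handling (e.g. dense cylinders whose
#' centers suffer beam hardening): voxels where `mask` is nonzero/true are
#' reassigned to `label`.
#'
#' @param labels A [label_volume()].
#' @param mask 3D array (logical or numeric) of the same shape.
#' @param label Integer label to assign inside the mask (must be 0 or present
#'   in the legend).
#' @return The modified [label_volume()].
#' @export
override_labels <- function(labels, mask, label) {
  stopifnot(inherits(labels, "label_volume"))
  if (!all(dim(mask) == dim(labels$labels))) abort("`mask` shape must match the label volume.")
  label <- as.integer(label)
  if (label != 0L && !label %in% labels$legend$label) {
    abort("`label` must be 0 (air) or a legend label.")
  }
  l <- labels$labels
  l[as.logical(mask)] <- label
  label_volume(l, labels$legend, labels$spacing, labels$origin)
}
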
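# 3D image containers and I/O. Axis order is (x, y, z) with 0-based voxel
# indices; world coordinate = origin + index * spacing; orientation is assumed
# axis-aligned (identity direction matrix), which holds for the CBCT exports
# this workflow targets. MetaImage (.mhd + .raw, MET_SHORT or MET_FLOAT,
# little-endian) is parsed directly; NIfTI goes through RNifti.

#' 3D scalar volume with geometry
#'
#' @param values 3D numeric array of voxel values (HU for CBCT input).
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all > 0.
#' @param origin World position of voxel (0, 0, 0) in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) abort("`spacing` must be 3 positive numbers (mm).")
  if (length(origin) != 3L) abort("`origin` must have 3 components (mm).")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Labeled volume with material legend
#'
#' @param labels 3D integer array of tissue labels; 0 is reserved for air.
#' @param legend Tibble mapping `label` to `name` (every nonzero label used
#'   must appear).
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, legend, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  used <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(used %in% legend$label)) {
    abort("Every nonzero label in the volume must appear in the legend.")
  }
  structure(list(labels = labels, legend = tibble::as_tibble(legend),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d legend entries (0 = air)\n",
              d[1], d[2], d[3], nrow(x$legend)))
  invisible(x)
}

mhd_type_map <- c(MET_SHORT = "integer", MET_FLOAT = "double")
mhd_size_map <- c(MET_SHORT = 2L, MET_FLOAT = 4L)

#' Read a 3D volume (MetaImage or NIfTI)
#'
#' Format is chosen from the extension: `.mhd` for MetaImage (with its `.raw`
#' payload next to it), `.nii` / `.nii.gz` for NIfTI. Integer voxel values
#' round-trip bit-exactly; spacing and origin are taken from the header.
#'
#' @param path File path.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    read_mhd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                 spacing = abs(hdr$pixdim[2:4]),
                 origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  } else {
    abort(paste0("Unknown volume format: ", path, " (use .mhd, .nii or .nii.gz)"))
  }
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(key, default = NULL) {
    i <- match(tolower(key), tolower(keys))
    if (is.na(i)) default else vals[i]
  }
  ndims <- as.integer(get("NDims", "3"))
  if (ndims != 3L) abort("Only 3D MetaImage volumes are supported.")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  etype <- get("ElementType")
  if (!etype %in% names(mhd_type_map)) {
    abort(paste0("Unsupported MetaImage ElementType: ", etype))
  }
  if (toupper(get("ElementByteOrderMSB", "False")) == "TRUE" ||
      toupper(get("BinaryDataByteOrderMSB", "False")) == "TRUE") {
    abort("Big-endian MetaImage payloads are not supported.")
  }
  datafile <- get("ElementDataFile")
  if (is.null(datafile) || toupper(datafile) == "LOCAL") {
    abort("MetaImage with embedded (LOCAL) data is not supported; use a .raw payload.")
  }
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) abort(paste0("Missing MetaImage payload: ", raw_path))
  n <- prod(dims)
  sz <- mhd_size_map[[etype]]
  if (file.info(raw_path)$size < n * sz) {
    abort(sprintf("Truncated MetaImage payload: expected %d bytes, found %d.",
                  n * sz, file.info(raw_path)$size))
  }
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = mhd_type_map[[etype]], n = n, size = sz,
               signed = TRUE, endian = "little")
  image_volume(array(as.numeric(v), dim = dims), spacing = spacing, origin = origin)
}

#' Write a 3D volume (MetaImage or NIfTI)
#'
#' @param volume An [image_volume()] (or [label_volume()], written as its
#'   integer label array).
#' @param path Output path; extension selects the format as in
#'   [read_volume()]. For MetaImage, `element_type` picks `MET_SHORT`
#'   (16-bit integer) or `MET_FLOAT`.
#' @param element_type MetaImage element type.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, element_type = c("MET_SHORT", "MET_FLOAT")) {
  element_type <- match.arg(element_type)
  if (inherits(volume, "label_volume")) {
    volume <- image_volume(volume$labels + 0, volume$spacing, volume$origin)
  }
  stopifnot(inherits(volume, "image_volume"))
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    write_mhd(volume, path, element_type)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$values)
    img <- RNifti::`pixdim<-`(img, volume$spacing)
    hdr <- list(qoffset_x = volume$origin[1], qoffset_y = volume$origin[2],
                qoffset_z = volume$origin[3], qform_code = 1L)
    img <- RNifti::asNifti(img, reference = hdr)
    RNifti::writeNifti(img, path)
  } else {
    abort(paste0("Unknown volume format: ", path))
  }
  invisible(path)
}

write_mhd <- function(volume, path, element_type) {
  d <- dim(volume$values)
  datafile <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("Offset = %.10g %.10g %.10g",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", datafile)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), datafile), "wb")
  on.exit(close(con))
  v <- as.vector(volume$values)
  if (element_type == "MET_SHORT") {
    v <- as.integer(round(v))
    if (any(v < -32768 | v > 32767)) abort("Values out of MET_SHORT range; use MET_FLOAT.")
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
}
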
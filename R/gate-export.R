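# Monte-Carlo material export: a GATE/Geant4-compatible materials database and
# the HU-to-material range file that together let a transport code reproduce
# the per-voxel assignment.

#' Export a tissue database for Monte Carlo transport
#'
#' Writes (a) a GATE-style materials database: one record per tissue with its
#' name, density (g/cm3) and per-element mass fractions (6-decimal fixed
#' rounding, largest fraction adjusted so each record sums to exactly the
#' rounded total of 1); and (b) an HU-range file with one line per tissue,
#' `HU_lo HU_hi name`, contiguous half-open ranges matching the database
#' intervals.
#'
#' @param db A [build_tissue_db()] result.
#' @param materials_path Output path for the materials database text.
#' @param ranges_path Output path for the HU-range text.
#' @return Invisibly, a list with both paths.
#' @export
export_mc_materials <- function(db, materials_path, ranges_path) {
  stopifnot(inherits(db, "tissue_db"))
  t <- db$tissues
  if (anyDuplicated(t$name)) abort("Duplicate tissue names; export would be ambiguous.")
  cols <- element_cols(t)
  pd <- periodic_elements()
  lines <- c("[Materials]")
  for (i in seq_len(nrow(t))) {
    w <- as.numeric(t[i, cols])
    keep <- which(w > 0)
    wr <- round(w[keep], 6)
    # absorb the rounding residue into the largest fraction
    wr[which.max(wr)] <- wr[which.max(wr)] + (1 - sum(wr))
    wr <- round(wr, 6)
    lines <- c(lines,
               sprintf("%s: d=%.6f g/cm3; n=%d", t$name[i], t$rho[i], length(keep)),
               sprintf("        +el: name=%s; f=%.6f",
                       pd$mc_name[match(cols[keep], pd$symbol)], wr))
  }
  writeLines(lines, materials_path)
  writeLines(sprintf("%.6f %.6f %s", t$hu_lo, t$hu_hi, t$name), ranges_path)
  invisible(list(materials = materials_path, ranges = ranges_path))
}

#' Re-parse exported Monte Carlo material files
#'
#' Round-trip reader for [export_mc_materials()] output, used to verify that
#' densities and compositions survive the fixed-precision writer.
#'
#' @param materials_path,ranges_path Paths written by [export_mc_materials()].
#' @return A tibble with `name`, `rho`, element columns, `hu_lo`, `hu_hi`.
#' @export
read_mc_materials <- function(materials_path, ranges_path) {
  lines <- readLines(materials_path)
  pd <- periodic_elements()
  recs <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) next
    if (grepl("^\\s*\\+el:", ln)) {
      nm <- sub(".*name=([^;]+);.*", "\\1", ln)
      f <- as.numeric(sub(".*f=([0-9.eE+-]+).*", "\\1", ln))
      cur$w[[pd$symbol[match(nm, pd$mc_name)]]] <- f
    } else if (nzchar(trimws(ln))) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      cur <- list(name = sub(":.*", "", ln),
                  rho = as.numeric(sub(".*d=([0-9.eE+-]+) g/cm3.*", "\\1", ln)),
                  w = list())
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  mats <- bind_rows(lapply(recs, function(r) {
    row <- tibble::tibble(name = r$name, rho = r$rho)
    row[names(r$w)] <- r$w
    row
  }))
  rng <- read.table(ranges_path, col.names = c("hu_lo", "hu_hi", "name"))
  left_join(mats, tibble::as_tibble(rng), by = "name")
}
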
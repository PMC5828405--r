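#' Read and write materials tables as CSV
#'
#' The materials CSV has columns `name`, `rho_g_cm3`, then one column per
#' element symbol holding mass fractions, plus optionally any further columns
#' (e.g. a measured HU column). On reading, `rho_g_cm3` is renamed to `rho`
#' and each row's element fractions are validated (non-negative, summing to 1
#' within rounding).
#'
#' @param path File path.
#' @return `read_materials_csv()` returns a tibble; `write_materials_csv()`
#'   returns `path` invisibly.
#' @export
read_materials_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  d <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  if (!all(c("name", "rho_g_cm3") %in% names(d))) {
    abort("Materials CSV needs `name` and `rho_g_cm3` columns.")
  }
  d <- rename(d, rho = "rho_g_cm3")
  cols <- element_cols(d)
  if (length(cols) == 0L) abort("Materials CSV has no element columns.")
  m <- as.matrix(d[cols])
  m[is.na(m)] <- 0
  for (i in seq_len(nrow(m))) check_fractions(m[i, ][m[i, ] > 0], strict = TRUE)
  d[cols] <- m
  d
}

#' @param data Materials table with `name`, `rho` and element columns.
#' @rdname read_materials_csv
#' @export
write_materials_csv <- function(data, path) {
  cols <- element_cols(data)
  out <- data[c("name", "rho", cols)]
  names(out)[names(out) == "rho"] <- "rho_g_cm3"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
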
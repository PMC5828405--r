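#' Periodic data for the elements occurring in body tissues
#'
#' Atomic number and standard atomic mass for the thirteen elements that occur
#' in the packaged reference tissue compositions (H, C, N, O, Na, Mg, P, S, Cl,
#' K, Ca, Fe, I). The `mc_name` column carries the element names expected by
#' GATE/Geant4 material database files.
#'
#' @return A tibble with columns `symbol`, `z` (atomic number), `a` (standard
#'   atomic mass, g/mol) and `mc_name`.
#' @examples
#' periodic_elements()
#' @export
periodic_elements <- function() {
  tibble::tribble(
    ~symbol, ~z,   ~a,       ~mc_name,
    "H",      1L,   1.008,   "Hydrogen",
    "C",      6L,  12.011,   "Carbon",
    "N",      7L,  14.007,   "Nitrogen",
    "O",      8L,  15.999,   "Oxygen",
    "Na",    11L,  22.990,   "Sodium",
    "Mg",    12L,  24.305,   "Magnesium",
    "P",     15L,  30.974,   "Phosphor",
    "S",     16L,  32.060,   "Sulfur",
    "Cl",    17L,  35.450,   "Chlorine",
    "K",     19L,  39.098,   "Potassium",
    "Ca",    20L,  40.078,   "Calcium",
    "Fe",    26L,  55.845,   "Iron",
    "I",     53L, 126.904,   "Iodine"
  )
}

# symbols recognised as element columns in materials tables
element_symbols <- function() periodic_elements()$symbol

#' Identify element columns of a materials table
#'
#' @param data A data frame possibly containing per-element mass-fraction
#'   columns named by chemical symbol (`H`, `C`, `O`, ...).
#' @return Character vector of the element column names present, in periodic
#'   order.
#' @export
element_cols <- function(data) {
  intersect(element_symbols(), names(data))
}
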
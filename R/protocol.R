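#' Concentration after dilution
#'
#' `C_final = C_stock * V_stock / V_final`, in whatever unit the stock
#' concentration carries (fold, percent, molar). Covers the working-stain
#' recipe (25 uL of a 10,000X SYBR Green stock into 125.025 mL gives ~2X)
#' and the hypochlorite dilution (300 mL of 3% active chlorine to 900 mL
#' gives 1%).
#'
#' @param stock_conc Stock concentration (any unit).
#' @param stock_volume Volume of stock used (same unit as `final_volume`).
#' @param final_volume Total final volume (>= `stock_volume`).
#' @return Final concentration in the stock's unit.
#' @examples
#' dilution_concentration(10000, 0.025, 125.025)  # ~2X
#' dilution_concentration(3, 300, 900)            # 1 (%)
#' @export
dilution_concentration <- function(stock_conc, stock_volume, final_volume) {
  if (any(stock_volume <= 0)) abort("Stock volume must be positive.")
  if (any(final_volume < stock_volume)) {
    abort("Final volume must be >= stock volume.")
  }
  stock_conc * stock_volume / final_volume
}

#' Molarity of a dissolved mass
#'
#' `mM = 1000 * mass / (MW * volume)`. Molecular weights are caller-supplied
#' (e.g. anhydrous sodium thiosulfate, 158.11 g/mol: 15.8 g in 1 L gives
#' 99.93 mM, nominally 100 mM).
#'
#' @param mass Solute mass, g.
#' @param molecular_weight g/mol.
#' @param volume Final volume, L.
#' @param signif_digits Optional rounding of the reported value (the raw
#'   value is always what the function returns unless this is set).
#' @return Concentration in mM.
#' @examples
#' molarity(15.8, 158.11, 1)  # 99.93 mM
#' @export
molarity <- function(mass, molecular_weight, volume, signif_digits = NULL) {
  if (any(c(mass, molecular_weight, volume) <= 0)) {
    abort("Mass, molecular weight and volume must be positive.")
  }
  out <- 1000 * mass / (molecular_weight * volume)
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' Cruise reagent worked examples
#'
#' The four solution-preparation calculations of the automated protocol, as
#' a labelled table: working SYBR Green concentration, diluted hypochlorite
#' strength, and the two thiosulfate molarities.
#'
#' @return Tibble: `solution`, `value`, `unit`, `nominal`.
#' @export
protocol_table <- function() {
  tibble::tibble(
    solution = c(
      "SYBR Green I working solution",
      "Sodium hypochlorite (diluted)",
      "Sodium thiosulfate cleaning solution",
      "Sodium thiosulfate in TRIS buffer"
    ),
    value = c(
      dilution_concentration(10000, 0.025, 125.025),
      dilution_concentration(3, 300, 900),
      molarity(15.8, 158.11, 1),
      molarity(7.9, 158.11, 1)
    ),
    unit = c("X", "% active chlorine", "mM", "mM"),
    nominal = c(2, 1, 100, 50)
  )
}
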
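#' Supported chemical elements
#'
#' The package tracks the twelve macro- and micronutrients routinely measured
#' in plant tissue stoichiometry: C, N, P, S, K, Na, Ca, Mg, Cu, Zn, Fe, Mn.
#' C, N, P and S are conventionally reported as percent of dry mass (CHNS
#' analysers and colorimetry), the remainder as mg per kg dry mass (AAS).
#'
#' @return A data.frame with columns \code{symbol}, \code{atomic_mass}
#'   (g/mol) and \code{default_unit}.
#' @examples
#' element_info()
#' @export
element_info <- function() {
  data.frame(
    symbol = c("C", "N", "P", "S", "K", "Na",
               "Ca", "Mg", "Cu", "Zn", "Fe", "Mn"),
    atomic_mass = c(12.011, 14.007, 30.974, 32.06, 39.098, 22.990,
                    40.078, 24.305, 63.546, 65.38, 55.845, 54.938),
    default_unit = c(rep("percent_dry_mass", 4),
                     rep("mg_per_kg_dry_mass", 8)),
    stringsAsFactors = FALSE
  )
}

supported_elements <- function() element_info()$symbol

#' Atomic mass of a supported element
#'
#' @param symbol Element symbol, e.g. \code{"N"}.
#' @return Atomic mass in g/mol.
#' @export
atomic_mass <- function(symbol) {
  info <- element_info()
  idx <- match(symbol, info$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  info$atomic_mass[idx]
}

supported_units <- function() c("percent_dry_mass", "mg_per_kg_dry_mass")

# 1 % dry mass == 10,000 mg/kg dry mass
MG_PER_KG_PER_PERCENT <- 1e4

convert_concentration <- function(x, from, to) {
  units <- supported_units()
  if (!all(from %in% units)) {
    stop("unrecognised unit(s): ",
         paste(setdiff(unique(from), units), collapse = ", "))
  }
  if (length(to) != 1L || !to %in% units) {
    stop("unrecognised target unit: ", to)
  }
  out <- x
  up <- from == "percent_dry_mass" & to == "mg_per_kg_dry_mass"
  down <- from == "mg_per_kg_dry_mass" & to == "percent_dry_mass"
  out[up] <- x[up] * MG_PER_KG_PER_PERCENT
  out[down] <- x[down] / MG_PER_KG_PER_PERCENT
  out
}
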
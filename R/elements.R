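#' Built-in element table
#'
#' Physical constants for the twelve elements occurring in the reference
#' human-tissue compositions: atomic number `Z`, relative atomic mass `A_r`
#' (CIAAW conventional values), mean excitation energy `I` in eV, and the
#' representative integer mass number `A_nuc` used by the geometric
#' nucleus-nucleus cross-section model.
#'
#' The default `I` values are the ICRU-37 Bragg-additivity set (gas values
#' for H, C, N, O as bound in compounds; condensed-phase elemental values for
#' the heavier elements).  They can be overridden per call in
#' [mean_excitation_energy()] and the stopping-power ratio functions by
#' passing a modified element table.
#'
#' @param I_override optional named numeric vector of mean excitation
#'   energies (eV) replacing the defaults for the named symbols.
#' @return A `data.frame` with columns `symbol`, `Z`, `A_r`, `I`, `A_nuc`.
#' @export
#' @examples
#' element_table()
#' element_table(I_override = c(O = 95))
element_table <- function(I_override = NULL) {
  tab <- data.frame(
    symbol = c("H", "C", "N", "O", "Na", "Mg",
               "P", "S", "Cl", "Ar", "K", "Ca"),
    Z      = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
    A_r    = c(1.008, 12.011, 14.007, 15.999, 22.98977, 24.305,
               30.97376, 32.06, 35.45, 39.948, 39.0983, 40.078),
    I      = c(19.2, 81, 82, 106, 149, 156, 173, 180, 174, 188, 190, 191),
    A_nuc  = c(1, 12, 14, 16, 23, 24, 31, 32, 35, 40, 39, 40),
    stringsAsFactors = FALSE
  )
  if (!is.null(I_override)) {
    if (is.null(names(I_override)) || any(!nzchar(names(I_override))))
      stop("'I_override' must be a named numeric vector")
    unknown <- setdiff(names(I_override), tab$symbol)
    if (length(unknown))
      stop("unknown element symbol(s) in 'I_override': ",
           paste(unknown, collapse = ", "))
    tab$I[match(names(I_override), tab$symbol)] <- as.numeric(I_override)
  }
  stopifnot(all(tab$Z >= 1), all(tab$A_r > 0), all(tab$I > 0))
  tab
}

# rows of the element table for the symbols used by a composition,
# in composition order; errors on unknown symbols
.element_rows <- function(symbols, elements) {
  idx <- match(symbols, elements$symbol)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(symbols[is.na(idx)], collapse = ", "))
  elements[idx, , drop = FALSE]
}
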
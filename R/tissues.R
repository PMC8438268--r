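#' Tissue composition objects
#'
#' A tissue composition is a named material with per-element mass fractions
#' summing to one.  The constructor validates the fractions (non-negative,
#' sum within `sum_tol` of 1) and drops zero entries.
#'
#' @param name material name (unique within a library).
#' @param fractions named numeric vector of mass fractions (0-1 scale),
#'   names are element symbols.
#' @param sum_tol allowed absolute deviation of `sum(fractions)` from 1.
#' @param I_override optional fixed mean excitation energy (eV) for this
#'   material; when set, [mean_excitation_energy()] returns it instead of
#'   the Bragg-rule value.  Used by the built-in water composition.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(name, fractions, sum_tol = 0.002,
                               I_override = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("'fractions' must be a named numeric vector")
  nm <- names(fractions)
  fractions <- stats::setNames(as.numeric(fractions), nm)
  if (any(fractions < 0)) stop("mass fractions must be non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > sum_tol)
    stop(sprintf("mass fractions of '%s' sum to %.4f (must be 1 +/- %.3f)",
                 name, s, sum_tol))
  fractions <- fractions[fractions > 0]
  if (!length(fractions)) stop("composition has no non-zero fractions")
  structure(list(name = name, fractions = fractions,
                 I_override = I_override),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf("<tissue_composition> %s\n", x$name))
  print(round(x$fractions, 5))
  if (!is.null(x$I_override))
    cat(sprintf("  fixed mean excitation energy: %g eV\n", x$I_override))
  invisible(x)
}

# Reference tissue mass fractions in percent (ICRP adult reference
# phantom media plus dry air); columns follow element_table() order.
.builtin_fraction_matrix <- function() {
  m <- rbind(
    air            = c(0.0,   0.012, 75.527, 23.178, 0.0, 0.0, 0.0,  0.0, 0.0, 1.283, 0.0, 0.0),
    lung           = c(10.3,  10.7,  3.2,    74.6,   0.2, 0.0, 0.2,  0.3, 0.3, 0.0,   0.2, 0.0),
    fat            = c(11.96, 76.87, 0.0,    11.17,  0.0, 0.0, 0.0,  0.0, 0.0, 0.0,   0.0, 0.0),
    adipose        = c(11.4,  58.8,  0.8,    28.7,   0.1, 0.0, 0.0,  0.1, 0.1, 0.0,   0.0, 0.0),
    `soft tissue`  = c(10.4,  23.1,  2.8,    62.7,   0.1, 0.0, 0.2,  0.3, 0.2, 0.2,   0.0, 0.0),
    muscle         = c(10.2,  14.2,  3.4,    71.1,   0.1, 0.0, 0.2,  0.3, 0.1, 0.0,   0.4, 0.0),
    `bone-scapula` = c(8.7,   30.9,  2.6,    48.3,   0.2, 0.1, 3.0,  0.4, 0.2, 0.0,   0.0, 5.6),
    `bone-mineral` = c(3.6,   15.9,  4.2,    44.8,   0.3, 0.2, 9.4,  0.3, 0.0, 0.0,   0.0, 21.3),
    tooth          = c(2.2,   9.5,   2.9,    42.1,   0.0, 0.7, 13.7, 0.0, 0.0, 0.0,   0.0, 28.9)
  )
  colnames(m) <- element_table()$symbol
  m
}

#' Built-in reference tissue library
#'
#' The nine built-in materials (air plus eight ICRP reference human
#' tissues) with their elemental mass fractions.  Every composition sums to
#' 1 within 0.002; fractions are on the 0-1 scale.
#'
#' @return Named list of [tissue_composition()] objects: air, lung, fat,
#'   adipose, soft tissue, muscle, bone-scapula, bone-mineral, tooth.
#' @seealso [lookup_tissue()], [water_composition()]
#' @export
#' @examples
#' builtin_tissues()[["tooth"]]
builtin_tissues <- function() {
  m <- .builtin_fraction_matrix() / 100
  out <- lapply(rownames(m), function(nm) tissue_composition(nm, m[nm, ]))
  stats::setNames(out, rownames(m))
}

#' Look up a tissue by name
#'
#' @param name material name.
#' @param tissues a named list of compositions, default [builtin_tissues()].
#' @return The matching [tissue_composition()]; error if absent.
#' @export
lookup_tissue <- function(name, tissues = builtin_tissues()) {
  if (!name %in% names(tissues))
    stop(sprintf("unknown tissue '%s'; available: %s", name,
                 paste(names(tissues), collapse = ", ")))
  tissues[[name]]
}

#' Water composition
#'
#' Stoichiometric H2O mass fractions.  Its mean excitation energy is always
#' the configured water value `I_w` (default 78 eV), never derived from
#' Bragg's rule, so that the material named water is exactly the reference
#' medium of the stopping-power ratio.
#'
#' @param I_w mean excitation energy of water in eV.
#' @return A [tissue_composition()] named `"water"`.
#' @export
water_composition <- function(I_w = 78) {
  M <- 2 * 1.008 + 15.999  # 18.015
  tissue_composition("water",
                     c(H = 2 * 1.008 / M, O = 15.999 / M),
                     I_override = I_w)
}

is_water_composition <- function(comp) {
  inherits(comp, "tissue_composition") && identical(comp$name, "water")
}

#' Mass-fraction weighted Z/A
#'
#' The electron-density factor of the Bethe-Bloch stopping power,
#' `sum_i w_i Z_i / A_i`, for a composition.
#'
#' @param comp a [tissue_composition()].
#' @param elements element table, see [element_table()].
#' @return Dimensionless scalar.
#' @export
#' @examples
#' z_over_a(water_composition())  # ~0.5551
z_over_a <- function(comp, elements = element_table()) {
  stopifnot(inherits(comp, "tissue_composition"))
  el <- .element_rows(names(comp$fractions), elements)
  sum(comp$fractions * el$Z / el$A_r)
}

#' Bragg-rule mean excitation energy
#'
#' Mean excitation energy of a compound by Bragg's additivity rule:
#' `ln I_m = sum(w_i Z_i/A_i ln I_i) / sum(w_i Z_i/A_i)`.  For the built-in
#' water composition the configured water value is returned unchanged (see
#' [water_composition()]).
#'
#' @inheritParams z_over_a
#' @return Mean excitation energy in eV.
#' @export
#' @examples
#' mean_excitation_energy(builtin_tissues()[["fat"]])  # ~61.3 eV
mean_excitation_energy <- function(comp, elements = element_table()) {
  stopifnot(inherits(comp, "tissue_composition"))
  if (!is.null(comp$I_override)) return(comp$I_override)
  el <- .element_rows(names(comp$fractions), elements)
  wza <- comp$fractions * el$Z / el$A_r
  if (sum(wza) <= 0) stop("empty composition")
  exp(sum(wza * log(el$I)) / sum(wza))
}

#' Read / write a composition table as CSV
#'
#' One row per material, a `material` column plus one column per element
#' symbol holding mass fractions on the 0-1 scale.  The packaged file
#' `system.file("extdata", "tissue_compositions.csv", package = "ctspr")`
#' mirrors the built-in library.
#'
#' @param path file path.
#' @return `read_composition_csv`: named list of [tissue_composition()].
#' @export
read_composition_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"material" %in% names(df))
    stop("composition CSV must have a 'material' column: ", path)
  syms <- setdiff(names(df), "material")
  out <- lapply(seq_len(nrow(df)), function(i) {
    fr <- as.numeric(df[i, syms])
    names(fr) <- syms
    tissue_composition(df$material[i], fr[fr > 0])
  })
  nms <- vapply(out, function(x) x$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate material names in ", path)
  stats::setNames(out, nms)
}

#' @rdname read_composition_csv
#' @param tissues named list of compositions to write.
#' @export
write_composition_csv <- function(tissues, path) {
  syms <- element_table()$symbol
  rows <- lapply(tissues, function(tc) {
    fr <- stats::setNames(numeric(length(syms)), syms)
    fr[names(tc$fractions)] <- tc$fractions
    fr
  })
  df <- cbind(data.frame(material = vapply(tissues, function(x) x$name,
                                           character(1)),
                         stringsAsFactors = FALSE),
              as.data.frame(do.call(rbind, rows)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
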
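#' Projectile specification
#'
#' A projectile for the geometric nucleus-nucleus cross-section: either a
#' proton or an ion of mass number `A`.  Strings like `"C12"`, `"He4"`,
#' `"p"` or `"proton"` are accepted by [parse_projectile()].
#'
#' @param kind `"proton"` or `"ion"`.
#' @param A mass number (integer >= 1; protons have A = 1).
#' @return Object of class `projectile`.
#' @export
projectile <- function(kind = c("ion", "proton"), A = 12) {
  kind <- match.arg(kind)
  A <- as.numeric(A)
  if (length(A) != 1L || A < 1 || A != round(A))
    stop("'A' must be an integer >= 1")
  if (kind == "proton" && A != 1) stop("a proton projectile has A = 1")
  structure(list(kind = kind, A = A), class = "projectile")
}

#' @rdname projectile
#' @param text projectile label, e.g. `"C12"`, `"proton"`, `"p"`.
#' @export
parse_projectile <- function(text) {
  if (tolower(text) %in% c("p", "proton", "h1")) return(projectile("proton", 1))
  m <- regmatches(text, regexec("^[A-Za-z]+([0-9]+)$", text))[[1]]
  if (length(m) < 2) stop("cannot parse projectile '", text, "'")
  projectile("ion", as.integer(m[2]))
}

#' Overlap parameter of the geometric cross-section
#'
#' Overlap (transparency) parameter `b_0i` between the projectile and a
#' target nucleus of mass number `A_ri`:
#' proton branch `2.247 - 0.915 (1 + A_ri^(-1/3))`;
#' ion branch `1.581 - 0.876 (A^(-1/3) + A_ri^(-1/3))`.
#'
#' @param proj a [projectile()].
#' @param A_ri target mass number(s), >= 1.
#' @return Dimensionless overlap parameter (vectorized over `A_ri`).
#' @export
overlap_parameter <- function(proj, A_ri) {
  stopifnot(inherits(proj, "projectile"))
  if (any(A_ri < 1)) stop("'A_ri' must be >= 1")
  if (proj$kind == "proton") 2.247 - 0.915 * (1 + A_ri^(-1 / 3))
  else 1.581 - 0.876 * (proj$A^(-1 / 3) + A_ri^(-1 / 3))
}

#' Geometric nucleus-nucleus cross-section
#'
#' Energy-independent geometric reaction cross-section
#' \deqn{\sigma_N = \pi r_0^2 [A^{1/3} + A_{ri}^{1/3}
#'   - b_{0i}(A^{-1/3} + A_{ri}^{-1/3})]^2}
#' with `r0` the effective nucleon radius.
#'
#' @inheritParams overlap_parameter
#' @param k [nuclear_constants()].
#' @return Cross-section in fm^2 (vectorized over `A_ri`).
#' @export
#' @examples
#' sigma_n(projectile("ion", 12), 12)  # ~86.9 fm^2
sigma_n <- function(proj, A_ri, k = nuclear_constants()) {
  stopifnot(inherits(proj, "projectile"), inherits(k, "nuclear_constants"))
  b0 <- overlap_parameter(proj, A_ri)
  bracket <- proj$A^(1 / 3) + A_ri^(1 / 3) -
    b0 * (proj$A^(-1 / 3) + A_ri^(-1 / 3))
  if (any(bracket <= 0))
    stop("nonphysical input: geometric cross-section bracket is not positive")
  pi * k$r0^2 * bracket^2
}

#' Nuclear-interaction probability ratio to water
#'
#' Ratio of a material's macroscopic nuclear-reaction probability per unit
#' path to that of unit-density water:
#' \deqn{\rho_N = \rho_m \sum_i w_i \sigma_{Ni}/A_{ri} \Big/
#'   \frac{2\sigma_{NH} + \sigma_{NO}}{M_{rw}}}
#' The water reference uses the printed stoichiometric form
#' `(2 sigma_NH + sigma_NO) / M_rw`; the built-in water composition is
#' evaluated through the same stoichiometric form so that water at unit
#' density gives exactly 1.  Elements enter with a single representative
#' mass number (see [element_table()] column `A_nuc`).
#'
#' Because the cross-sections are energy independent, `rho_n` is linear in
#' density at fixed composition; for the varying-density-water method it
#' therefore equals the SPR identically, whereas realistic tissue
#' compositions break the proportionality between SPR and `rho_N`.
#'
#' @param comp a [tissue_composition()].
#' @param density mass density in g/cm^3 (vectorized).
#' @param proj a [projectile()], default carbon-12.
#' @param k [nuclear_constants()].
#' @param elements element table supplying representative mass numbers.
#' @return Dimensionless ratio.
#' @export
rho_n <- function(comp, density, proj = projectile("ion", 12),
                  k = nuclear_constants(), elements = element_table()) {
  stopifnot(inherits(comp, "tissue_composition"))
  if (any(density <= 0)) stop("'density' must be positive")
  sigma_h <- sigma_n(proj, 1, k)
  sigma_o <- sigma_n(proj, 16, k)
  water_ref <- (2 * sigma_h + sigma_o) / k$M_rw
  per_mass <- if (is_water_composition(comp)) {
    water_ref
  } else {
    el <- .element_rows(names(comp$fractions), elements)
    sum(comp$fractions * sigma_n(proj, el$A_nuc, k) / el$A_nuc)
  }
  density * per_mass / water_ref
}

#' rho_N versus CT number for both assignment methods
#'
#' Evaluates the nuclear-interaction probability ratio for every bin of a
#' material table under the realistic-tissue assignment and under the
#' varying-density-water assignment of the same SPR, enabling
#' rho_N-versus-HU comparison curves.
#'
#' @param table a [build_material_table()] result built with
#'   `method = "our"`.
#' @param proj a [projectile()].
#' @param k [nuclear_constants()].
#' @param tissues tissue library resolving the table's tissue names.
#' @param elements element table.
#' @param rho_water reference water density in g/cm^3.
#' @return `data.frame` with columns `hu`, `tissue`, `spr`, `rho_n_our`,
#'   `rho_n_water`.
#' @export
rho_n_table <- function(table, proj = projectile("ion", 12),
                        k = nuclear_constants(),
                        tissues = builtin_tissues(),
                        elements = element_table(), rho_water = 1.0) {
  stopifnot(inherits(table, "material_table"))
  if (identical(attr(table, "method"), "water"))
    stop("rho_n_table expects a table built with method = 'our'")
  per_tissue <- vapply(names(tissues), function(nm)
    rho_n(tissues[[nm]], 1, proj, k, elements), numeric(1))
  unknown <- setdiff(unique(table$tissue), names(tissues))
  if (length(unknown))
    stop("table names tissues absent from the library: ",
         paste(unknown, collapse = ", "))
  data.frame(
    hu = table$hu, tissue = table$tissue, spr = table$spr,
    rho_n_our = unname(table$density * per_tissue[table$tissue]),
    rho_n_water = rho_n(
      water_composition(),
      water_density_from_spr(table$spr,
                             physics_constants(rho_water = rho_water)),
      proj, k, elements),
    stringsAsFactors = FALSE
  )
}
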
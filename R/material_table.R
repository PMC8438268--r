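#' Stopping-power ratio of a material to water
#'
#' Bethe-Bloch ratio at the fixed reference carbon velocity:
#' \deqn{SPR_{m,w} = \frac{\rho_m \sum_i w_i Z_i/A_i \,
#'   (\ln(m_ec^2/I_m) - 1/3)}{\rho_w (Z/A)_w (\ln(m_ec^2/I_w) - 1/3)}}
#' with \eqn{I_m} from Bragg's additivity rule and water's mean excitation
#' energy always the configured `I_w`.  The atomic-mass-unit and
#' electron-density prefactors of the absolute stopping power cancel in the
#' water-relative ratio, so only mass densities and \eqn{\sum w Z/A}
#' factors appear.
#'
#' @param comp a [tissue_composition()].
#' @param density mass density of the material in g/cm^3.
#' @param k [physics_constants()].
#' @param elements element table, see [element_table()].
#' @return Dimensionless SPR (vectorized over `density`).
#' @seealso [density_from_spr()] for the inverse.
#' @export
spr_from_material <- function(comp, density, k = physics_constants(),
                              elements = element_table()) {
  if (any(density <= 0)) stop("'density' must be positive")
  density / .density_per_spr(comp, k, elements)
}

# g/cm^3 of material per unit SPR: the constant ratio rho_m / SPR_m,w
.density_per_spr <- function(comp, k, elements) {
  I_m <- if (is_water_composition(comp)) k$I_w
         else mean_excitation_energy(comp, elements)
  if (I_m >= k$mec2) stop("nonphysical mean excitation energy (I >= mec2)")
  L_m <- log(k$mec2 / I_m) - k$velocity_factor
  L_w <- log(k$mec2 / k$I_w) - k$velocity_factor
  za_w <- z_over_a(water_composition(k$I_w), elements)
  k$rho_water * za_w * L_w / (z_over_a(comp, elements) * L_m)
}

#' Mass density from a stopping-power ratio
#'
#' Exact algebraic inverse of [spr_from_material()]: the mass density a
#' material of the given composition must have so that its Bethe-Bloch
#' stopping-power ratio to water equals `spr`.  This is the density solve
#' applied to every CT-number bin when building a material table.
#'
#' @param comp a [tissue_composition()].
#' @param spr stopping-power ratio (positive, vectorized).
#' @inheritParams spr_from_material
#' @return Mass density in g/cm^3.
#' @export
#' @examples
#' density_from_spr(builtin_tissues()[["tooth"]], 1.66)  # ~1.91 g/cm^3
density_from_spr <- function(comp, spr, k = physics_constants(),
                             elements = element_table()) {
  if (any(spr <= 0)) stop("'spr' must be positive")
  spr * .density_per_spr(comp, k, elements)
}

#' Varying-density-water density rule
#'
#' The comparison method keeps the elemental composition of water in every
#' voxel and scales the mass density to match the SPR; for the water
#' composition the density solve collapses to `spr * rho_water`.
#'
#' @inheritParams density_from_spr
#' @return Mass density in g/cm^3.
#' @export
water_density_from_spr <- function(spr, k = physics_constants()) {
  if (any(spr <= 0)) stop("'spr' must be positive")
  spr * k$rho_water
}

#' Build a binned material table
#'
#' Discretizes the CT-number domain into uniform bins (default 10 HU over
#' [-1000, 2000], i.e. 300 bins) and produces one material card per bin:
#' tissue from the allocation scheme at the bin-center CT number, SPR from
#' the calibration curve at the bin center, and mass density solved from
#' that SPR -- via [density_from_spr()] with the assigned tissue
#' composition (`method = "our"`) or via [water_density_from_spr()] with
#' the water composition everywhere (`method = "water"`, the
#' varying-density-water comparison method).
#'
#' @param curve an [hu_spr_curve()].
#' @param scheme an [hu_allocation_scheme()].
#' @param step bin width in HU; `(hi - lo)` must be divisible by it.
#' @param lo,hi CT-number domain covered by the table.
#' @param method `"our"` (tissue compositions) or `"water"`
#'   (varying-density-water).
#' @param tissues tissue library resolving the scheme's names.
#' @param k [physics_constants()].
#' @param elements element table.
#' @return Object of class `material_table`: a `data.frame` with columns
#'   `lo`, `hi`, `hu` (bin center), `tissue`, `spr`, `density`.
#' @export
build_material_table <- function(curve, scheme = default_allocation_scheme(),
                                 step = 10, lo = -1000, hi = 2000,
                                 method = c("our", "water"),
                                 tissues = builtin_tissues(),
                                 k = physics_constants(),
                                 elements = element_table()) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "hu_spr_curve"),
            inherits(scheme, "hu_allocation_scheme"))
  if (step <= 0 || abs((hi - lo) / step - round((hi - lo) / step)) > 1e-9)
    stop("(hi - lo) must be a positive multiple of 'step'")
  domain <- attr(scheme, "domain")
  if (lo < domain[1] || hi > domain[2])
    stop("allocation scheme does not cover the requested HU domain")
  n <- as.integer(round((hi - lo) / step))
  bin_lo <- lo + step * (seq_len(n) - 1)
  center <- bin_lo + step / 2
  tissue <- assign_tissue(center, scheme)
  spr <- evaluate_curve(curve, center)
  density <- if (method == "water") {
    water_density_from_spr(spr, k)
  } else {
    per <- vapply(names(tissues),
                  function(nm) .density_per_spr(tissues[[nm]], k, elements),
                  numeric(1))
    unknown <- setdiff(unique(tissue), names(tissues))
    if (length(unknown))
      stop("scheme names tissues absent from the library: ",
           paste(unknown, collapse = ", "))
    spr * per[tissue]
  }
  comp_name <- if (method == "water") rep("water", n) else tissue
  structure(data.frame(lo = bin_lo, hi = bin_lo + step, hu = center,
                       tissue = tissue, spr = spr,
                       density = unname(density),
                       stringsAsFactors = FALSE),
            class = c("material_table", "data.frame"),
            method = method, step = step, composition = comp_name)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %d bins of %g HU over [%g, %g], method '%s'\n",
              nrow(x), attr(x, "step"), min(x$lo), max(x$hi),
              attr(x, "method")))
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Material card lookup by CT number
#'
#' Returns the card of the half-open bin `[lo, hi)` containing `hu`
#' (top bin closed).
#'
#' @param table a [build_material_table()] result.
#' @param hu CT number(s).
#' @return `data.frame` of the matching rows.
#' @export
material_card_at <- function(table, hu) {
  stopifnot(inherits(table, "material_table"))
  if (any(hu < table$lo[1]) || any(hu > table$hi[nrow(table)]))
    stop("CT number outside the material table domain")
  idx <- findInterval(hu, table$lo, rightmost.closed = FALSE)
  as.data.frame(table)[idx, , drop = FALSE]
}

#' SPR lookup used for range scaling
#'
#' `spr_at_hu` dispatches on the lookup object: the binned SPR of a
#' [build_material_table()] or the continuous [evaluate_curve()] value of
#' an [hu_spr_curve()].
#'
#' @param lookup a `material_table` or `hu_spr_curve`.
#' @param hu CT number(s).
#' @return Numeric SPR values.
#' @export
spr_at_hu <- function(lookup, hu) {
  if (inherits(lookup, "material_table")) material_card_at(lookup, hu)$spr
  else if (inherits(lookup, "hu_spr_curve")) evaluate_curve(lookup, hu)
  else stop("'lookup' must be a material_table or an hu_spr_curve")
}

#' Read / write a material table
#'
#' CSV format: one row per card with columns `lo`, `hi`, `hu`, `tissue`,
#' `spr`, `density` plus a header comment-free layout that round-trips
#' exactly.  The PHITS-style format emits one material block per bin with
#' element-by-mass-fraction lines (negative numbers denote mass fractions
#' in PHITS convention) and the card's density as a comment, in
#' deterministic order.
#'
#' @param table a [build_material_table()] result.
#' @param path file path.
#' @param format `"csv"` or `"phits"`.
#' @param tissues tissue library used to resolve compositions for the
#'   PHITS format.
#' @export
write_material_table <- function(table, path, format = c("csv", "phits"),
                                 tissues = builtin_tissues()) {
  format <- match.arg(format)
  stopifnot(inherits(table, "material_table"))
  if (format == "csv") {
    df <- as.data.frame(table)
    df$method <- attr(table, "method")
    df$step <- attr(table, "step")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    comp_names <- attr(table, "composition")
    lines <- c("[ Material ]")
    for (i in seq_len(nrow(table))) {
      comp <- if (comp_names[i] == "water") water_composition()
              else lookup_tissue(comp_names[i], tissues)
      lines <- c(lines,
                 sprintf("$ bin %d: HU [%g, %g), tissue %s, SPR %.6f, density %.6g g/cm3",
                         i, table$lo[i], table$hi[i], table$tissue[i],
                         table$spr[i], table$density[i]),
                 sprintf("M%d", i),
                 sprintf("  %-2s %.6f", names(comp$fractions),
                         -comp$fractions))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_material_table
#' @return `read_material_table`: a `material_table`.
#' @export
read_material_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lo", "hi", "hu", "tissue", "spr", "density")
  if (!all(need %in% names(df)))
    stop("material table CSV lacks required columns: ", path)
  method <- if ("method" %in% names(df)) df$method[1] else "our"
  step <- if ("step" %in% names(df)) df$step[1] else df$hi[1] - df$lo[1]
  comp_name <- if (method == "water") rep("water", nrow(df)) else df$tissue
  structure(df[, need], class = c("material_table", "data.frame"),
            method = method, step = step, composition = comp_name)
}
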
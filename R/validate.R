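#' Validation run: binned material tables versus the continuous curve
#'
#' Orchestrates the package's end-to-end comparison.  For each assignment
#' method (realistic tissues and varying-density-water) a binned material
#' table is built and the reference SOBP curve is mapped through the
#' phantom by WEPL range scaling.  A TPS-like baseline is obtained by
#' mapping the same reference with the continuous calibration curve (no
#' 10-HU quantization).  The report contains, per method, the signed
#' range-difference metrics against the baseline and the gamma passing
#' rate, plus the rho_N-versus-HU comparison of the two methods.
#'
#' In this 1-D range-scaling emulation the two methods share the same
#' binned SPR values, so their depth-dose curves coincide by construction;
#' the physically meaningful contrasts are (a) the quantization effect of
#' the 10-HU binning against the continuous curve and (b) the
#' nuclear-interaction probability ratio, which differs between the
#' methods even at equal SPR.
#'
#' @param phantom a [phantom_1d()].
#' @param curve an [hu_spr_curve()].
#' @param scheme an [hu_allocation_scheme()].
#' @param reference a [depth_dose_curve()]; default
#'   [generate_sobp_reference()].
#' @param step bin width in HU.
#' @param dta_mm,dose_pct gamma criteria.
#' @param proj projectile for the rho_N comparison.
#' @param tissues tissue library.
#' @param k [physics_constants()].
#' @return List of class `validation_report`.
#' @export
validate_methods <- function(phantom,
                             curve = default_hu_spr_curve(),
                             scheme = default_allocation_scheme(),
                             reference = generate_sobp_reference(),
                             step = 10, dta_mm = 1.0, dose_pct = 3.0,
                             proj = projectile("ion", 12),
                             tissues = builtin_tissues(),
                             k = physics_constants()) {
  table_our <- build_material_table(curve, scheme, step = step,
                                    method = "our", tissues = tissues, k = k)
  table_water <- build_material_table(curve, scheme, step = step,
                                      method = "water", tissues = tissues,
                                      k = k)
  baseline <- wepl_map(phantom, curve, reference)
  methods <- list(our = table_our, water = table_water)
  per_method <- lapply(methods, function(tab) {
    mapped <- wepl_map(phantom, tab, reference)
    g <- gamma_index_1d(mapped, baseline, dta_mm = dta_mm,
                        dose_pct = dose_pct)
    c(delta_metrics(mapped, baseline),
      list(gamma_pass_rate = g$pass_rate, curve = mapped))
  })
  structure(list(methods = per_method, baseline = baseline,
                 rho_n = rho_n_table(table_our, proj = proj,
                                     tissues = tissues),
                 dta_mm = dta_mm, dose_pct = dose_pct),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in names(x$methods)) {
    m <- x$methods[[nm]]
    cat(sprintf(
      "  %-6s delta_peak %+.2f mm, delta_d50 %+.2f mm, gamma pass %.1f%% (%g mm / %g%%)\n",
      nm, m$delta_peak, m$delta_d50, m$gamma_pass_rate, x$dta_mm,
      x$dose_pct))
  }
  lo <- x$rho_n$hu >= -150 & x$rho_n$hu < 10
  hi <- x$rho_n$hu > 600 & x$rho_n$tissue %in% c("bone-mineral", "tooth")
  cat(sprintf("  rho_N: water < our on [-150, 10) HU: %s; water > our above 600 HU (bone/tooth): %s\n",
              all(x$rho_n$rho_n_water[lo] < x$rho_n$rho_n_our[lo]),
              all(x$rho_n$rho_n_water[hi] > x$rho_n$rho_n_our[hi])))
  invisible(x)
}

#' Write the packaged fixtures
#'
#' Writes the default inputs to a directory: the fixture HU-SPR curve
#' (`hu_spr_curve.csv`), the tissue composition table
#' (`tissue_compositions.csv`), the default allocation scheme
#' (`allocation_scheme.json`), the heterogeneous slab phantom
#' (`phantom_heterogeneous.json`) and the default SOBP reference curve
#' (`sobp_reference.csv`).  Output is deterministic: repeated runs produce
#' byte-identical files.
#'
#' @param out_dir destination directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("cannot write fixtures to directory: ", out_dir)
  paths <- c(
    curve = file.path(out_dir, "hu_spr_curve.csv"),
    tissues = file.path(out_dir, "tissue_compositions.csv"),
    scheme = file.path(out_dir, "allocation_scheme.json"),
    phantom = file.path(out_dir, "phantom_heterogeneous.json"),
    sobp = file.path(out_dir, "sobp_reference.csv")
  )
  write_hu_spr_curve(default_hu_spr_curve(), paths[["curve"]])
  write_composition_csv(builtin_tissues(), paths[["tissues"]])
  write_allocation_scheme(default_allocation_scheme(), paths[["scheme"]])
  write_phantom(build_phantom("heterogeneous"), paths[["phantom"]])
  write_depth_dose_csv(generate_sobp_reference(), paths[["sobp"]])
  invisible(paths)
}
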
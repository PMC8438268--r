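#' Physics constants for the stopping-power ratio
#'
#' Constants entering the Bethe-Bloch ratio used by the density solve:
#' electron rest energy, the mean excitation energy of water, the constant
#' subtracted inside the stopping-power logarithm (1/3, corresponding to a
#' fixed carbon velocity of 0.557c), and the reference water mass density.
#'
#' @param mec2 electron rest energy in eV.
#' @param I_w water mean excitation energy in eV.
#' @param velocity_factor constant subtracted from the logarithm; 1/3
#'   matches a carbon residual range of roughly 2-25 cm, over which the
#'   ratio changes by less than 0.5\%.
#' @param rho_water water mass density in g/cm^3.
#' @return List of class `physics_constants`.
#' @export
physics_constants <- function(mec2 = 510998.95, I_w = 78,
                              velocity_factor = 1 / 3, rho_water = 1.0) {
  k <- list(mec2 = mec2, I_w = I_w, velocity_factor = velocity_factor,
            rho_water = rho_water)
  if (any(vapply(k, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all physics constants must be positive scalars")
  if (velocity_factor >= log(mec2 / I_w))
    stop("velocity_factor must be smaller than ln(mec2/I_w)")
  structure(k, class = "physics_constants")
}

#' Nuclear-model constants
#'
#' Constants of the geometric nucleus-nucleus cross-section model: the
#' effective nucleon radius and the molecular weight of water used in the
#' per-mass water reference cross-section.
#'
#' @param r0 effective nucleon radius in fm.
#' @param M_rw molecular weight of water.
#' @return List of class `nuclear_constants`.
#' @export
nuclear_constants <- function(r0 = 1.36, M_rw = 18.015) {
  if (!is.numeric(r0) || r0 <= 0 || !is.numeric(M_rw) || M_rw <= 0)
    stop("'r0' and 'M_rw' must be positive")
  structure(list(r0 = r0, M_rw = M_rw), class = "nuclear_constants")
}
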
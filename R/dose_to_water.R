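#' Dose tally description
#'
#' The scoring-bin context needed to convert dose to medium into dose to
#' water: bin volume, the medium's composition and mass density, and the
#' voxel's water density `rho_w` (the density the varying-density-water
#' assignment would give the same voxel, i.e. SPR times the reference
#' water density).  When `rho_w` is omitted it is computed from the
#' medium's own stopping-power ratio.
#'
#' @param volume_cm3 bin volume in cm^3.
#' @param comp a [tissue_composition()].
#' @param density medium mass density in g/cm^3.
#' @param rho_w voxel water density in g/cm^3, or `NULL` to derive it from
#'   [spr_from_material()].
#' @param k [physics_constants()].
#' @param elements element table.
#' @return Object of class `dose_tally`.
#' @export
dose_tally <- function(volume_cm3, comp, density, rho_w = NULL,
                       k = physics_constants(),
                       elements = element_table()) {
  if (volume_cm3 <= 0) stop("'volume_cm3' must be positive")
  if (density <= 0) stop("'density' must be positive")
  stopifnot(inherits(comp, "tissue_composition"))
  if (is.null(rho_w))
    rho_w <- spr_from_material(comp, density, k, elements) * k$rho_water
  structure(list(volume_cm3 = volume_cm3, comp = comp, density = density,
                 rho_w = rho_w), class = "dose_tally")
}

#' Deposition event list
#'
#' Per-particle energy depositions in a scoring bin: particle charge and
#' mass number, kinetic energy per nucleon, and deposited energy.
#'
#' @param Z,A integer vectors of particle charge and mass numbers.
#' @param E_MeV_u kinetic energies per nucleon in MeV/u.
#' @param edep_MeV deposited energies in MeV.
#' @param bin optional bin indices.
#' @return `data.frame` of class `deposition_events`.
#' @export
deposition_events <- function(Z, A, E_MeV_u, edep_MeV, bin = 1L) {
  if (any(E_MeV_u <= 0) || any(edep_MeV <= 0))
    stop("energies must be positive")
  if (any(Z < 1) || any(A < 1)) stop("Z and A must be >= 1")
  structure(data.frame(Z = as.integer(Z), A = as.integer(A),
                       E_MeV_u = E_MeV_u, edep_MeV = edep_MeV,
                       bin = as.integer(bin)),
            class = c("deposition_events", "data.frame"))
}

#' Read / write an event list as CSV
#'
#' Columns `Z`, `A`, `E_MeV_per_u`, `edep_MeV`, `bin`.
#'
#' @param path file path.
#' @return `read_events_csv`: a [deposition_events()] data frame.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Z", "A", "E_MeV_per_u", "edep_MeV")
  if (!all(need %in% names(df)))
    stop("event CSV lacks required columns: ", path)
  deposition_events(df$Z, df$A, df$E_MeV_per_u, df$edep_MeV,
                    if ("bin" %in% names(df)) df$bin else 1L)
}

#' @rdname read_events_csv
#' @param events a [deposition_events()] data frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(Z = events$Z, A = events$A,
                              E_MeV_per_u = events$E_MeV_u,
                              edep_MeV = events$edep_MeV,
                              bin = events$bin),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# relativistic beta^2 and beta^2*gamma^2 from kinetic energy per nucleon,
# using the atomic mass unit as the nucleon rest energy
.beta2_gamma2 <- function(E_MeV_u, m_u = 931.49410242) {
  if (any(E_MeV_u <= 0)) stop("kinetic energy must be positive")
  g <- 1 + E_MeV_u / m_u
  beta2 <- 1 - 1 / g^2
  if (any(beta2 >= 1)) stop("nonphysical velocity (beta >= 1)")
  list(beta2 = beta2, b2g2 = beta2 * g^2)
}

# energy-dependent Bethe logarithm term: ln(2 mec2 beta^2 gamma^2 / I) - beta^2
.bethe_L <- function(E_MeV_u, I_eV, mec2) {
  bg <- .beta2_gamma2(E_MeV_u)
  arg <- 2 * mec2 * bg$b2g2 / I_eV
  if (any(arg <= 1)) stop("stopping-power logarithm is not positive")
  log(arg) - bg$beta2
}

#' Event-wise mass stopping-power ratio water/medium
#'
#' Ratio of the mass stopping power of water to that of the medium at the
#' event's velocity, from the energy-dependent Bethe form (electron
#' density times `ln(2 mec2 beta^2 gamma^2 / I) - beta^2`).  Unlike the
#' fixed-velocity ratio of [spr_from_material()], this term is evaluated
#' per particle energy as the dose-to-water conversion requires.
#'
#' @param comp medium [tissue_composition()].
#' @param E_MeV_u kinetic energies per nucleon in MeV/u (vectorized).
#' @param k [physics_constants()].
#' @param elements element table.
#' @return Dimensionless ratio `(dE/rho dx)_w / (dE/rho dx)_m`.
#' @export
mass_stopping_ratio_w_over_m <- function(comp, E_MeV_u,
                                         k = physics_constants(),
                                         elements = element_table()) {
  I_m <- if (is_water_composition(comp)) k$I_w
         else mean_excitation_energy(comp, elements)
  za_w <- z_over_a(water_composition(k$I_w), elements)
  za_m <- z_over_a(comp, elements)
  (za_w * .bethe_L(E_MeV_u, k$I_w, k$mec2)) /
    (za_m * .bethe_L(E_MeV_u, I_m, k$mec2))
}

#' Dose-to-water conversion of an event list
#'
#' Converts the energy deposited in a medium into dose to water by
#' weighting every deposition with the water-to-medium stopping-power
#' ratio at the particle's energy:
#' \deqn{D_w = \frac{1}{V\rho_m} \sum_i \frac{\rho_m}{\rho_w}\,
#'   \varepsilon_{m,i}\,
#'   \frac{(dE/dx)_w}{(dE/dx)_m}\Big|_{E_i}}
#' with the tally's voxel water density \eqn{\rho_w} (see [dose_tally()]).
#' When the medium's composition is water the conversion is the identity
#' at any density.
#'
#' @param events a [deposition_events()] data frame.
#' @param tally a [dose_tally()].
#' @param k [physics_constants()].
#' @param elements element table.
#' @return Dose to water in MeV/g (scale by 1.602e-10 for Gy).
#' @seealso [dose_to_medium()]
#' @export
dose_to_water <- function(events, tally, k = physics_constants(),
                          elements = element_table()) {
  stopifnot(inherits(tally, "dose_tally"))
  ratio <- mass_stopping_ratio_w_over_m(tally$comp, events$E_MeV_u,
                                        k, elements)
  sum(events$edep_MeV * ratio) / (tally$volume_cm3 * tally$rho_w)
}

#' @rdname dose_to_water
#' @return `dose_to_medium`: dose to medium in MeV/g.
#' @export
dose_to_medium <- function(events, tally) {
  stopifnot(inherits(tally, "dose_tally"))
  sum(events$edep_MeV) / (tally$volume_cm3 * tally$density)
}
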
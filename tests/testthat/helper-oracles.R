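# Independent oracles used by the tests. These deliberately re-derive the
# quantities with their own (brute force / closed form) code paths and must
# not call the package functions they are used to check.

# exhaustive 1-D gamma: scan every reference sample for every eval point
oracle_gamma_brute <- function(eval_depth, eval_dose, ref_depth, ref_dose,
                               dta_mm, dose_pct) {
  dd_abs <- dose_pct / 100 * max(ref_dose)
  vapply(seq_along(eval_depth), function(i) {
    sqrt(min(((ref_depth - eval_depth[i]) / dta_mm)^2 +
               ((ref_dose - eval_dose[i]) / dd_abs)^2))
  }, numeric(1))
}

# cumulative WEPL by fine-grained midpoint-rule numerical integration
oracle_wepl_numeric <- function(thickness_cm, spr_per_slab, z_cm,
                                n = 200000) {
  zz <- seq(0, sum(thickness_cm), length.out = n + 1)
  mid <- (zz[-1] + zz[-(n + 1)]) / 2
  slab <- findInterval(mid, cumsum(c(0, thickness_cm)),
                       rightmost.closed = TRUE)
  slab <- pmin(slab, length(spr_per_slab))
  cum <- c(0, cumsum(spr_per_slab[slab] * diff(zz)))
  stats::approx(zz, cum, xout = z_cm)$y
}

# random valid composition over a subset of the built-in elements
random_composition <- function(id) {
  el <- ctspr::element_table()
  n <- sample(2:6, 1)
  syms <- sample(el$symbol, n)
  w <- stats::runif(n)
  ctspr::tissue_composition(paste0("random-", id),
                            stats::setNames(w / sum(w), syms))
}

# independent dose-to-water: own beta, own Bethe logarithm, own Z/A sums
oracle_dose_to_water <- function(edep_MeV, E_MeV_u, fractions, V_cm3,
                                 rho_w) {
  el <- ctspr::element_table()
  i <- match(names(fractions), el$symbol)
  wza <- fractions * el$Z[i] / el$A_r[i]
  I_m <- exp(sum(wza * log(el$I[i])) / sum(wza))
  za_m <- sum(wza)
  za_w <- (2 * 1.008 / 18.015) * 1 / 1.008 + (15.999 / 18.015) * 8 / 15.999
  mec2 <- 510998.95
  g <- 1 + E_MeV_u / 931.49410242
  b2 <- 1 - g^-2
  L <- function(I) log(2 * mec2 * b2 * g^2 / I) - b2
  sum(edep_MeV * (za_w * L(78)) / (za_m * L(I_m))) / (V_cm3 * rho_w)
}

# a jagged but valid depth-dose curve for gamma fuzzing
random_curve_pair <- function(n = 60, step = 0.7) {
  depth <- seq(0, by = step, length.out = n)
  ref <- abs(stats::rnorm(n, mean = 1, sd = 0.4)) + 0.05
  ev <- ref * stats::runif(n, 0.8, 1.2) + stats::rnorm(n, sd = 0.05)
  ev <- pmax(ev, 0)
  list(ref = ctspr::depth_dose_curve(depth, ref),
       eval = ctspr::depth_dose_curve(depth + stats::runif(1, -0.3, 0.3) -
                                        min(0, depth[1]), ev))
}
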
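test_that("SOBP reference has the constructed plateau, range and tail", {
  ref <- generate_sobp_reference()          # range 27 cm, width 8 cm
  expect_equal(ref$dose[1], 1.0)            # entrance-normalized
  plateau <- ref$dose[ref$depth_mm >= 190 & ref$depth_mm <= 269.5]
  expect_lt(diff(range(plateau)) / max(plateau), 0.02)
  expect_lt(abs(d50_position(ref) - 270), 0.1)     # one grid step
  tail <- ref$dose[ref$depth_mm > 275 & ref$depth_mm < 350]
  expect_true(all(tail < 0.3 * max(ref$dose)) && all(tail > 0))
  expect_true(all(diff(tail) <= 0))                 # decaying tail
  expect_error(generate_sobp_reference(range_cm = 5, sobp_width_cm = 8),
               "sobp_width_cm")
})

test_that("phantom construction and presets", {
  het <- build_phantom("heterogeneous")
  expect_equal(het$length_cm, 40)
  expect_equal(sum(het$thickness_cm), 40)
  expect_equal(het$thickness_cm[het$hu == 715], 2)    # bone slab
  expect_equal(het$thickness_cm[het$hu == -325], 15)  # lung slab
  hom <- build_phantom("homogeneous", hu = 45)
  expect_equal(hom$thickness_cm, 40)
  expect_equal(assign_tissue(hom$hu), "soft tissue")
  expect_error(phantom_1d(c(20, 19), c(0, 0), 40), "declared length")
  expect_error(phantom_1d(c(20, -1), c(0, 0), 19), "positive")
  path <- tempfile(fileext = ".json")
  write_phantom(het, path)
  back <- read_phantom(path)
  expect_equal(back$thickness_cm, het$thickness_cm)
  expect_equal(back$hu, het$hu)
})

test_that("WEPL mapping: identity, closed-form scaling, slab oracle", {
  ref <- generate_sobp_reference()
  hom <- build_phantom("homogeneous", hu = 500)
  flat1 <- hu_spr_curve(c(-1000, 2000), c(1, 1))
  mapped <- wepl_map(hom, flat1, ref)
  expect_equal(mapped$dose, ref$dose, tolerance = 1e-12)  # SPR 1 identity
  for (s in c(0.8, 1.25)) {
    flats <- hu_spr_curve(c(-1000, 2000), c(s, s))
    d50 <- d50_position(wepl_map(hom, flats, ref))
    expect_lt(abs(d50 - 270 / s), 0.1 + 1e-9)
  }
  # slab-boundary WEPL against a numerical integration oracle
  het <- build_phantom("heterogeneous")
  cv <- default_hu_spr_curve()
  spr <- evaluate_curve(cv, het$hu)
  z <- c(cumsum(het$thickness_cm), 1.3, 8.05, 22.2)
  expect_equal(wepl_at(het, cv, z),
               oracle_wepl_numeric(het$thickness_cm, spr, z),
               tolerance = 1e-3)
  expect_error(wepl_at(het, cv, 41), "outside")
})

test_that("reference dose is clamped beyond the registered depth", {
  ref <- generate_sobp_reference()
  thin <- phantom_1d(30, 0, 30)
  dense <- hu_spr_curve(c(-1000, 2000), c(1.5, 1.5))  # max WEPL 45 cm
  mapped <- wepl_map(thin, dense, ref)
  last_ref <- ref$dose[length(ref$dose)]
  expect_equal(mapped$dose[mapped$depth_mm > 400 / 1.5],
               rep(last_ref, sum(mapped$depth_mm > 400 / 1.5)),
               tolerance = 1e-12)
})

test_that("peak and d50 positions with tie and interpolation rules", {
  z <- seq(0, 10, by = 0.5)
  d <- rep(1, 21); d[9:13] <- 2                    # flat top at 4..6 mm
  cv <- depth_dose_curve(z, d)
  expect_equal(peak_position(cv), 4)               # shallowest tie
  unique_pk <- depth_dose_curve(z, c(rep(1, 10), 3, rep(0.5, 10)))
  expect_equal(peak_position(unique_pk), 5)
  # step falloff from max to 0 between adjacent points: midpoint by interp
  step <- depth_dose_curve(c(0, 1, 2, 3), c(1, 1, 0, 0))
  expect_equal(d50_position(step), 1.5)
  # scaling the curve leaves d50 unchanged (relative threshold)
  ref <- generate_sobp_reference()
  scaled <- depth_dose_curve(ref$depth_mm, ref$dose * 7)
  expect_equal(d50_position(scaled), d50_position(ref), tolerance = 1e-12)
  expect_error(d50_position(depth_dose_curve(z, rep(0, 21))), "all-zero")
  expect_error(d50_position(depth_dose_curve(c(0, 1), c(1, 1))),
               "no distal")
})

test_that("delta metrics are signed eval-minus-ref differences", {
  ref <- generate_sobp_reference()
  m0 <- delta_metrics(ref, ref)
  expect_equal(m0$delta_peak, 0)
  expect_equal(m0$delta_d50, 0)
  # grid-aligned distal shift by 1.0 mm
  shifted <- depth_dose_curve(ref$depth_mm + 1.0, ref$dose)
  m1 <- delta_metrics(shifted, ref)
  expect_equal(m1$delta_peak, 1.0, tolerance = 1e-9)
  expect_equal(m1$delta_d50, 1.0, tolerance = 1e-9)
  # uniform-SPR closed form: delta_d50 ~ d50_ref (1/s - 1)
  hom <- build_phantom("homogeneous", hu = 0)
  s <- 1.25
  mapped <- wepl_map(hom, hu_spr_curve(c(-1000, 2000), c(s, s)), ref)
  m2 <- delta_metrics(mapped, ref)
  expect_equal(m2$delta_d50, d50_position(ref) * (1 / s - 1),
               tolerance = 0.1)
})

test_that("depth-dose CSV round-trips", {
  ref <- generate_sobp_reference(step_mm = 1)
  path <- tempfile(fileext = ".csv")
  write_depth_dose_csv(ref, path)
  back <- read_depth_dose_csv(path)
  expect_equal(back$depth_mm, ref$depth_mm)
  expect_equal(back$dose, ref$dose, tolerance = 1e-12)
})

test_that("gamma: identities, boundary offset, scale invariance", {
  ref <- generate_sobp_reference(step_mm = 0.5)
  g0 <- gamma_index_1d(ref, ref)
  expect_equal(max(g0$gamma), 0)
  expect_equal(g0$pass_rate, 100)
  # uniform +3 percent-of-max offset on a gradient-free curve: the dose
  # term alone sets gamma = 1 everywhere (on sloped curves spatially
  # offset reference points compensate and gamma dips below 1)
  flat <- depth_dose_curve(ref$depth_mm, rep(2, length(ref$depth_mm)))
  offf <- depth_dose_curve(flat$depth_mm, flat$dose + 0.03 * 2)
  gf <- gamma_index_1d(offf, flat, dta_mm = 1, dose_pct = 3)
  expect_true(all(abs(gf$gamma - 1) < 1e-9))
  expect_equal(gf$pass_rate, 100)   # boundary passes
  off <- depth_dose_curve(ref$depth_mm, ref$dose + 0.03 * max(ref$dose))
  g1 <- gamma_index_1d(off, ref, dta_mm = 1, dose_pct = 3)
  expect_true(all(g1$gamma <= 1 + 1e-9) && max(g1$gamma) > 0.9)
  expect_equal(g1$pass_rate, 100)
  # global normalization: common scaling changes nothing
  sc <- 3.7
  g2 <- gamma_index_1d(depth_dose_curve(off$depth_mm, off$dose * sc),
                       depth_dose_curve(ref$depth_mm, ref$dose * sc))
  expect_equal(g2$gamma, g1$gamma, tolerance = 1e-12)
  expect_equal(g2$pass_rate, g1$pass_rate)
})

test_that("low-dose cutoff excludes points from the denominator only", {
  z <- seq(0, 50, by = 1)
  ref <- depth_dose_curve(z, c(rep(1, 26), rep(0.01, 25)))
  ev <- depth_dose_curve(z, c(rep(1, 26), rep(0.5, 25)))  # far off in tail
  g <- gamma_index_1d(ev, ref, dta_mm = 1, dose_pct = 3,
                      low_dose_cutoff_pct = 10)
  expect_equal(sum(g$included), 26)
  expect_equal(g$pass_rate, 100)           # failures all below cutoff
  expect_length(g$gamma, 51)               # gamma still reported everywhere
})

test_that("windowed gamma equals the exhaustive brute-force oracle", {
  set.seed(123)
  for (rep in 1:40) {
    pair <- random_curve_pair()
    g <- gamma_index_1d(pair$eval, pair$ref, dta_mm = 1, dose_pct = 3)
    brute <- oracle_gamma_brute(pair$eval$depth_mm, pair$eval$dose,
                                pair$ref$depth_mm, pair$ref$dose, 1, 3)
    expect_equal(g$gamma, brute, tolerance = 1e-12)
  }
})

test_that("dose-to-water conversion", {
  set.seed(5)
  events <- deposition_events(Z = c(6, 1, 2, 6), A = c(12, 1, 4, 12),
                              E_MeV_u = c(200, 80, 150, 350),
                              edep_MeV = c(1, 0.2, 0.4, 0.7))
  # water at density 1: identity
  tw <- dose_tally(2, water_composition(), 1.0)
  expect_equal(dose_to_water(events, tw), dose_to_medium(events, tw),
               tolerance = 1e-12)
  # varying-density water at any density: still the identity
  tw2 <- dose_tally(2, water_composition(), 1.31)
  expect_equal(dose_to_water(events, tw2), dose_to_medium(events, tw2),
               tolerance = 1e-12)
  # realistic medium against the independent oracle implementation
  bm <- lookup_tissue("bone-mineral")
  tb <- dose_tally(1, bm, 1.47)
  expect_equal(dose_to_water(events, tb),
               oracle_dose_to_water(events$edep_MeV, events$E_MeV_u,
                                    bm$fractions, 1, tb$rho_w),
               tolerance = 1e-10)
  # single published-style event: frozen oracle value
  one <- deposition_events(6, 12, 200, 1)
  expect_equal(dose_to_water(one, tb),
               oracle_dose_to_water(1, 200, bm$fractions, 1, tb$rho_w),
               tolerance = 1e-10)
  expect_error(deposition_events(6, 12, -5, 1), "positive")
  expect_error(dose_tally(0, bm, 1.47), "positive")
  # nonphysical log argument: huge I at low energy
  cold <- deposition_events(1, 1, 1e-4, 0.1)
  expect_error(dose_to_water(cold, tb), "not positive")
})
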
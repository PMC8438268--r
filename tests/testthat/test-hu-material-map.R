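test_that("curve evaluation interpolates, clamps, and hits breakpoints", {
  cv <- hu_spr_curve(c(-100, 0, 100), c(0.9, 1.0, 1.2))
  expect_equal(evaluate_curve(cv, c(-100, 0, 100)), c(0.9, 1.0, 1.2))
  expect_equal(evaluate_curve(cv, 50), (1.0 + 1.2) / 2)
  expect_equal(evaluate_curve(cv, -500), 0.9)  # clamp below
  expect_equal(evaluate_curve(cv, 500), 1.2)   # clamp above
  expect_error(hu_spr_curve(numeric(0), numeric(0)), "empty")
  expect_error(hu_spr_curve(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(hu_spr_curve(c(0, 1), c(1, -1)), "positive")
})

test_that("fixture curve passes through the published anchors", {
  cv <- default_hu_spr_curve()
  a <- validation_anchors()
  expect_equal(evaluate_curve(cv, a$hu), a$spr)
  expect_equal(evaluate_curve(cv, -1000), 0.001)
  expect_equal(evaluate_curve(cv, 2000), 1.827)
  back <- read_hu_spr_curve(system.file("extdata", "hu_spr_curve.csv",
                                        package = "ctspr"))
  expect_equal(back$hu, cv$hu)
  expect_equal(back$spr, cv$spr)
})

test_that("tissue allocation follows the half-open interval scheme", {
  expect_equal(assign_tissue(715), "bone-mineral")
  expect_equal(assign_tissue(-325), "lung")
  expect_equal(assign_tissue(-1000), "air")
  expect_equal(assign_tissue(2000), "tooth")   # top interval closed
  # boundary belongs to the interval it starts
  expect_equal(assign_tissue(120), "muscle")
  expect_equal(assign_tissue(119.999), "soft tissue")
  expect_error(assign_tissue(-1001), "outside")
  expect_error(assign_tissue(2001), "outside")
  # every published representative HU lands in its own tissue's interval
  a <- validation_anchors()
  expect_equal(assign_tissue(a$hu), a$material)
})

test_that("allocation scheme JSON round-trips", {
  sch <- default_allocation_scheme()
  path <- tempfile(fileext = ".json")
  write_allocation_scheme(sch, path)
  back <- read_allocation_scheme(path)
  expect_equal(back$lo, sch$lo)
  expect_equal(back$hi, sch$hi)
  expect_equal(back$tissue, sch$tissue)
  expect_error(hu_allocation_scheme(c(-1000, 0), c(10, 2000),
                                    c("a", "b")), "contiguous")
})

test_that("SPR of water is the density-scaled identity", {
  w <- water_composition()
  expect_equal(spr_from_material(w, 1.0), 1.0, tolerance = 1e-12)
  for (s in c(0.3, 0.95, 1.66))
    expect_equal(spr_from_material(w, s), s, tolerance = 1e-12)
})

test_that("density solve reproduces the published density row", {
  # printed SPR inputs are 2-decimal rounded, propagating ~0.5percent
  a <- validation_anchors()
  printed_rho <- c(0.70, 0.92, 0.98, 1.04, 1.10, 1.16, 1.47, 1.92)
  solved <- mapply(function(m, s) density_from_spr(lookup_tissue(m), s),
                   a$material, a$spr)
  expect_equal(unname(solved), printed_rho, tolerance = 0.015 / 1.0)
  expect_true(all(abs(solved - printed_rho) <= 0.015))
  # and the inverse direction: tooth at its solved density gives spr ~1.66
  expect_equal(spr_from_material(lookup_tissue("tooth"), 1.92), 1.66,
               tolerance = 0.015)
})

test_that("density_from_spr and spr_from_material are exact inverses", {
  set.seed(7)
  for (rep in 1:30) {
    comp <- random_composition(rep + 100)
    for (s in runif(3, 0.1, 2.5)) {
      rho <- density_from_spr(comp, s)
      expect_equal(spr_from_material(comp, rho), s, tolerance = 1e-12)
    }
  }
  # water: both density rules coincide
  for (s in c(0.1, 0.7, 1.0, 1.66, 2.5))
    expect_equal(density_from_spr(water_composition(), s),
                 water_density_from_spr(s), tolerance = 1e-12)
  expect_error(density_from_spr(water_composition(), -1), "positive")
})

test_that("material table has 300 contiguous bins with round-trip SPR", {
  tab <- build_material_table(default_hu_spr_curve())
  expect_s3_class(tab, "material_table")
  expect_equal(nrow(tab), 300)
  expect_equal(tab$lo[1], -1000)
  expect_equal(tab$hi[300], 2000)
  expect_true(all(tab$lo[-1] == tab$hi[-300]))   # contiguous
  expect_equal(tab$hu, tab$lo + 5)               # bin centers
  # each card's density reproduces its SPR through the forward model
  tissues <- builtin_tissues()
  spr_back <- vapply(seq_len(nrow(tab)), function(i)
    spr_from_material(tissues[[tab$tissue[i]]], tab$density[i]),
    numeric(1))
  expect_equal(spr_back, tab$spr, tolerance = 1e-9)
  # bin containing HU 715: bone-mineral at the anchor SPR
  card <- material_card_at(tab, 715)
  expect_equal(card$tissue, "bone-mineral")
  expect_equal(card$spr, 1.31)
  expect_equal(card$density, 1.4622, tolerance = 1e-3)
  expect_error(material_card_at(tab, 3000), "outside")
})

test_that("densities are non-decreasing within single-tissue segments", {
  tab <- build_material_table(default_hu_spr_curve())
  for (tis in unique(tab$tissue)) {
    d <- tab$density[tab$tissue == tis]
    expect_true(all(diff(d) >= -1e-12), info = tis)
  }
})

test_that("varying-density-water table equals SPR everywhere", {
  tabw <- build_material_table(default_hu_spr_curve(), method = "water")
  expect_equal(tabw$density, tabw$spr, tolerance = 1e-12)
  expect_identical(attr(tabw, "method"), "water")
})

test_that("material table CSV and PHITS outputs", {
  tab <- build_material_table(default_hu_spr_curve())
  csv <- tempfile(fileext = ".csv")
  write_material_table(tab, csv)
  back <- read_material_table(csv)
  expect_equal(nrow(back), 300)
  expect_equal(back$density, tab$density, tolerance = 1e-12)
  expect_equal(back$tissue, tab$tissue)
  expect_identical(attr(back, "method"), "our")

  phits <- tempfile(fileext = ".inp")
  write_material_table(tab, phits, format = "phits")
  lines <- readLines(phits)
  expect_equal(lines[1], "[ Material ]")
  expect_length(grep("^M[0-9]+$", lines), 300)
  # the air card carries all its non-zero mass fractions at a ~1e-3 density
  air_hdr <- grep("tissue air", lines)[1]
  expect_match(lines[air_hdr], "density")
  expect_lt(material_card_at(tab, -995)$density, 0.01)
  block <- lines[air_hdr:(air_hdr + 6)]
  for (sym in c("C", "N", "O", "Ar"))
    expect_true(any(grepl(paste0("^  ", sym, " "), block)), info = sym)
  # deterministic output
  phits2 <- tempfile(fileext = ".inp")
  write_material_table(tab, phits2, format = "phits")
  expect_identical(readLines(phits2), lines)
})

test_that("table construction validates its inputs", {
  cv <- default_hu_spr_curve()
  expect_error(build_material_table(cv, step = 7), "multiple")
  expect_error(build_material_table(cv, lo = -2000), "does not cover")
  sch <- hu_allocation_scheme(-1000, 2000, "no-such-tissue")
  expect_error(build_material_table(cv, sch), "absent from the library")
})
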
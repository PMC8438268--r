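#' Depth-dose curve container
#'
#' A dose profile on a uniform depth grid, entrance-normalized by
#' convention (first grid point's dose equals 1 after
#' [normalize_entrance()]).
#'
#' @param depth_mm numeric vector, uniform strictly increasing depth grid
#'   in mm.
#' @param dose numeric vector of non-negative doses.
#' @return Object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depth_mm, dose) {
  depth_mm <- as.numeric(depth_mm); dose <- as.numeric(dose)
  if (!length(depth_mm)) stop("empty curve")
  if (length(depth_mm) != length(dose)) stop("grid/dose lengths differ")
  if (anyNA(depth_mm) || anyNA(dose)) stop("curve contains NA")
  if (any(dose < 0)) stop("doses must be non-negative")
  if (length(depth_mm) > 1) {
    steps <- diff(depth_mm)
    if (any(steps <= 0)) stop("depth grid must be strictly increasing")
    if (diff(range(steps)) > 1e-6 * mean(steps))
      stop("depth grid must be uniform")
  }
  structure(list(depth_mm = depth_mm, dose = dose),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf(
    "<depth_dose_curve> %d points, depth [%g, %g] mm, max dose %.4g\n",
    length(x$depth_mm), min(x$depth_mm), max(x$depth_mm), max(x$dose)))
  invisible(x)
}

#' @rdname depth_dose_curve
#' @param curve a `depth_dose_curve`.
#' @export
normalize_entrance <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (curve$dose[1] <= 0) stop("entrance dose is zero; cannot normalize")
  depth_dose_curve(curve$depth_mm, curve$dose / curve$dose[1])
}

# linear interpolation of a curve at arbitrary depths, clamped at the ends
# (the registered profile keeps a constant dose level beyond its last depth)
.curve_at <- function(curve, depth_mm) {
  stats::approx(curve$depth_mm, curve$dose, xout = depth_mm,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Synthetic spread-out Bragg peak reference curve
#'
#' Deterministic analytic stand-in for the registered water depth-dose
#' profile of a carbon SOBP field: a slowly rising proximal ramp, a flat
#' plateau (the SOBP) spanning `[range_cm - sobp_width_cm, range_cm]`, a
#' sharp logistic distal falloff whose 50\%-of-maximum depth coincides with
#' `range_cm` to within one grid step, and a low exponentially decaying
#' fragment tail.  The curve is entrance-normalized.
#'
#' The distal falloff scale (default 0.1 mm) is deliberately much sharper
#' than a physical SOBP so that the nominal range and the distal d50 agree
#' by construction; it is a fixture for range arithmetic, not a beam model.
#'
#' @param range_cm nominal range (distal d50 depth) in cm.
#' @param sobp_width_cm SOBP plateau width in cm.
#' @param step_mm depth grid step in mm.
#' @param depth_max_cm extent of the registered profile (constant dose
#'   continuation applies beyond it when mapped).
#' @param plateau plateau-to-entrance dose ratio.
#' @param falloff_mm logistic distal falloff scale in mm.
#' @param tail_fraction fragment-tail dose just distal of the falloff, as a
#'   fraction of the plateau dose.
#' @param tail_decay_cm exponential decay length of the fragment tail.
#' @return A [depth_dose_curve()].
#' @export
generate_sobp_reference <- function(range_cm = 27, sobp_width_cm = 8,
                                    step_mm = 0.1, depth_max_cm = 40,
                                    plateau = 2.5, falloff_mm = 0.1,
                                    tail_fraction = 0.08,
                                    tail_decay_cm = 8) {
  if (sobp_width_cm <= 0 || sobp_width_cm >= range_cm)
    stop("need 0 < sobp_width_cm < range_cm")
  if (range_cm > depth_max_cm) stop("range exceeds the registered depth")
  z <- seq(0, depth_max_cm * 10, by = step_mm)           # mm
  r <- range_cm * 10; w <- sobp_width_cm * 10
  ramp <- ifelse(z <= r - w, 1 + (plateau - 1) * (z / (r - w))^3, plateau)
  fall <- 1 / (1 + exp((z - r) / falloff_mm))
  tail <- tail_fraction * plateau * (1 - fall) *
    exp(-pmax(z - r, 0) / (tail_decay_cm * 10))
  normalize_entrance(depth_dose_curve(z, ramp * fall + tail))
}

#' 1-D layered phantom
#'
#' Ordered slabs of (thickness, CT number) along the beam axis.  The slab
#' thicknesses must fill the declared phantom length exactly.
#'
#' @param thickness_cm numeric vector of slab thicknesses in cm.
#' @param hu numeric vector of slab CT numbers.
#' @param length_cm declared phantom depth in cm.
#' @return Object of class `phantom_1d`.
#' @export
phantom_1d <- function(thickness_cm, hu, length_cm = sum(thickness_cm)) {
  thickness_cm <- as.numeric(thickness_cm); hu <- as.numeric(hu)
  if (length(thickness_cm) != length(hu)) stop("slab vectors differ in length")
  if (any(thickness_cm <= 0)) stop("slab thicknesses must be positive")
  if (abs(sum(thickness_cm) - length_cm) > 1e-9)
    stop(sprintf("slabs sum to %g cm but the declared length is %g cm",
                 sum(thickness_cm), length_cm))
  structure(list(thickness_cm = thickness_cm, hu = hu,
                 length_cm = length_cm), class = "phantom_1d")
}

#' @export
print.phantom_1d <- function(x, ...) {
  cat(sprintf("<phantom_1d> %d slab(s), %g cm\n", length(x$hu), x$length_cm))
  print(data.frame(thickness_cm = x$thickness_cm, hu = x$hu))
  invisible(x)
}

#' Phantom presets and construction
#'
#' `build_phantom` accepts a preset name (`"homogeneous"`,
#' `"heterogeneous"`) or a `data.frame`/list with `thickness_cm` and `hu`.
#' The homogeneous preset is a 40 cm box of a single CT number.  The
#' heterogeneous preset inserts a 2 cm bone-mineral slab (HU 715) and a
#' 15 cm lung slab (HU -325) into a 40 cm water phantom, with default
#' positions water 0-5 cm, bone 5-7 cm, water 7-10 cm, lung 10-25 cm,
#' water 25-40 cm (slab positions are configurable by passing an explicit
#' spec; the published layout is schematic only).
#'
#' @param spec preset name or slab specification.
#' @param hu CT number for the homogeneous preset.
#' @param length_cm phantom depth in cm.
#' @return A [phantom_1d()].
#' @export
build_phantom <- function(spec = c("homogeneous", "heterogeneous"),
                          hu = 0, length_cm = 40) {
  if (is.character(spec)) {
    spec <- match.arg(spec)
    if (spec == "homogeneous")
      return(phantom_1d(length_cm, hu, length_cm))
    return(phantom_1d(c(5, 2, 3, 15, 15), c(0, 715, 0, -325, 0), 40))
  }
  spec <- as.data.frame(spec)
  if (!all(c("thickness_cm", "hu") %in% names(spec)))
    stop("phantom spec needs fields 'thickness_cm' and 'hu'")
  phantom_1d(spec$thickness_cm, spec$hu, length_cm)
}

#' Read / write a phantom spec as JSON
#'
#' JSON array of objects `{"thickness_cm": ..., "hu": ...}`.
#'
#' @param path file path.
#' @return `read_phantom`: a [phantom_1d()].
#' @export
read_phantom <- function(path) {
  df <- jsonlite::fromJSON(path)
  build_phantom(df, length_cm = sum(df$thickness_cm))
}

#' @rdname read_phantom
#' @param phantom a [phantom_1d()].
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_1d"))
  jsonlite::write_json(data.frame(thickness_cm = phantom$thickness_cm,
                                  hu = phantom$hu),
                       path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Water-equivalent path length inside a phantom
#'
#' `WEPL(z) = integral_0^z SPR(hu(z')) dz'`, evaluated exactly from the
#' piecewise-constant slab SPRs.
#'
#' @param phantom a [phantom_1d()].
#' @param lookup SPR source, see [spr_at_hu()] (binned material table or
#'   continuous calibration curve).
#' @param z_cm depths in cm (vectorized).
#' @return WEPL in cm.
#' @export
wepl_at <- function(phantom, lookup, z_cm) {
  stopifnot(inherits(phantom, "phantom_1d"))
  if (any(z_cm < 0) || any(z_cm > phantom$length_cm + 1e-9))
    stop("depth outside the phantom")
  spr <- spr_at_hu(lookup, phantom$hu)
  bounds <- cumsum(c(0, phantom$thickness_cm))     # slab boundaries
  wcum <- cumsum(c(0, phantom$thickness_cm * spr)) # WEPL at boundaries
  idx <- pmin(findInterval(z_cm, bounds, rightmost.closed = TRUE),
              length(spr))
  wcum[idx] + (z_cm - bounds[idx]) * spr[idx]
}

#' Map a reference water curve through a phantom by range scaling
#'
#' Emulates the pencil-beam range-scaling mechanism in one dimension: the
#' dose at geometric depth `z` is the registered water dose at the
#' water-equivalent depth, `dose(z) = reference(WEPL(z))`.  Beyond the
#' registered profile's last depth the reference dose level is kept
#' constant (clamping).
#'
#' @param phantom a [phantom_1d()].
#' @param lookup SPR source, see [spr_at_hu()].
#' @param reference a [depth_dose_curve()] in water.
#' @param step_mm output grid step; defaults to the reference grid step.
#' @return A [depth_dose_curve()] over the phantom depth.
#' @export
wepl_map <- function(phantom, lookup, reference, step_mm = NULL) {
  stopifnot(inherits(reference, "depth_dose_curve"))
  if (is.null(step_mm))
    step_mm <- if (length(reference$depth_mm) > 1)
      reference$depth_mm[2] - reference$depth_mm[1] else 0.1
  z <- seq(0, phantom$length_cm * 10, by = step_mm)      # mm
  wepl_mm <- wepl_at(phantom, lookup, z / 10) * 10
  depth_dose_curve(z, .curve_at(reference, wepl_mm))
}

#' Peak position of a depth-dose curve
#'
#' Depth of the global dose maximum; ties are broken by the shallowest
#' depth (SOBP plateaus are flat by construction).
#'
#' @param curve a [depth_dose_curve()].
#' @return Depth in mm.
#' @export
peak_position <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (max(curve$dose) <= 0) stop("all-zero curve has no peak")
  curve$depth_mm[which.max(curve$dose)]
}

#' Distal 50\%-of-maximum position
#'
#' Depth at which the dose falls to 50\% of the curve maximum on the
#' distal side (the last downward crossing), linearly interpolated between
#' grid points.
#'
#' @param curve a [depth_dose_curve()].
#' @return Depth in mm.
#' @export
d50_position <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  m <- max(curve$dose)
  if (m <= 0) stop("all-zero curve has no d50")
  half <- m / 2
  d <- curve$dose; z <- curve$depth_mm
  n <- length(d)
  cross <- which(d[-n] >= half & d[-1] < half)
  if (!length(cross)) stop("curve has no distal 50% falloff")
  i <- cross[length(cross)]
  z[i] + (z[i + 1] - z[i]) * (d[i] - half) / (d[i] - d[i + 1])
}

#' Read / write a depth-dose curve as CSV
#'
#' Two-column CSV with header `depth_mm,dose`.
#'
#' @param path file path.
#' @return `read_depth_dose_csv`: a [depth_dose_curve()].
#' @export
read_depth_dose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("depth_mm", "dose") %in% names(df)))
    stop("depth-dose CSV must have columns 'depth_mm' and 'dose': ", path)
  depth_dose_curve(df$depth_mm, df$dose)
}

#' @rdname read_depth_dose_csv
#' @param curve a [depth_dose_curve()].
#' @export
write_depth_dose_csv <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  utils::write.csv(data.frame(depth_mm = curve$depth_mm, dose = curve$dose),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Range-difference metrics between two curves
#'
#' Signed differences (evaluated minus reference) of the peak position and
#' of the distal 50\%-of-maximum position.
#'
#' @param eval,ref [depth_dose_curve()] objects.
#' @return List with `delta_peak` and `delta_d50` (mm).
#' @export
delta_metrics <- function(eval, ref) {
  list(delta_peak = peak_position(eval) - peak_position(ref),
       delta_d50 = d50_position(eval) - d50_position(ref))
}
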
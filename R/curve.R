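#' HU-SPR calibration curve
#'
#' Piecewise-linear conversion from CT number (Hounsfield units) to the
#' stopping-power ratio to water, as registered in a treatment planning
#' system.  Breakpoints must be strictly increasing in HU with positive SPR.
#'
#' @param hu numeric vector of CT numbers (strictly increasing).
#' @param spr numeric vector of stopping-power ratios (positive).
#' @return Object of class `hu_spr_curve`.
#' @seealso [evaluate_curve()], [default_hu_spr_curve()]
#' @export
hu_spr_curve <- function(hu, spr) {
  hu <- as.numeric(hu); spr <- as.numeric(spr)
  if (length(hu) == 0L) stop("empty curve")
  if (length(hu) != length(spr)) stop("'hu' and 'spr' lengths differ")
  if (anyNA(hu) || anyNA(spr)) stop("curve contains NA")
  if (is.unsorted(hu, strictly = TRUE)) stop("'hu' must be strictly increasing")
  if (any(spr <= 0)) stop("'spr' must be positive at every breakpoint")
  structure(list(hu = hu, spr = spr), class = "hu_spr_curve")
}

#' @export
print.hu_spr_curve <- function(x, ...) {
  cat(sprintf("<hu_spr_curve> %d breakpoints, HU [%g, %g], SPR [%g, %g]\n",
              length(x$hu), min(x$hu), max(x$hu), min(x$spr), max(x$spr)))
  invisible(x)
}

#' Evaluate an HU-SPR curve
#'
#' Linear interpolation between bracketing breakpoints; outside the
#' breakpoint range the end value is returned (clamping, no linear
#' extrapolation).  Evaluation at a breakpoint returns its SPR exactly.
#'
#' @param curve an [hu_spr_curve()].
#' @param hu numeric vector of CT numbers.
#' @return Numeric vector of SPR values.
#' @export
evaluate_curve <- function(curve, hu) {
  stopifnot(inherits(curve, "hu_spr_curve"))
  if (length(curve$hu) == 1L) return(rep(curve$spr, length(hu)))
  stats::approx(curve$hu, curve$spr, xout = hu, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Packaged fixture HU-SPR curve
#'
#' A stand-in calibration curve built from the eight published anchor
#' points (HU, SPR) of the validation materials, extended to the full
#' CT-number domain with an air point at (-1000, 0.001) and a linear
#' continuation of the last printed segment to (2000, 1.827).  Real TPS
#' curves are scanner-specific; load one with [read_hu_spr_curve()] for
#' production use.
#'
#' @return An [hu_spr_curve()].
#' @export
default_hu_spr_curve <- function() {
  a <- validation_anchors()
  hu_spr_curve(c(-1000, a$hu, 2000), c(0.001, a$spr, 1.827))
}

#' Published validation anchors
#'
#' The eight representative materials used for validation: the CT number
#' chosen inside each material's allocation interval and the SPR obtained
#' from the TPS calibration curve at that CT number.  These (HU, SPR) pairs
#' are the only tabulated points of the calibration curve and anchor the
#' packaged fixture curve.
#'
#' @return `data.frame` with columns `material`, `hu`, `spr`.
#' @export
validation_anchors <- function() {
  data.frame(
    material = c("lung", "fat", "adipose", "soft tissue", "muscle",
                 "bone-scapula", "bone-mineral", "tooth"),
    hu  = c(-325, -105, -5, 45, 175, 265, 715, 1585),
    spr = c(0.70, 0.95, 1.01, 1.04, 1.10, 1.13, 1.31, 1.66),
    stringsAsFactors = FALSE
  )
}

#' Read / write an HU-SPR curve as CSV
#'
#' Two-column CSV with header `hu,spr`.
#'
#' @param path file path.
#' @return `read_hu_spr_curve`: an [hu_spr_curve()].
#' @export
read_hu_spr_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hu", "spr") %in% names(df)))
    stop("curve CSV must have columns 'hu' and 'spr': ", path)
  hu_spr_curve(df$hu, df$spr)
}

#' @rdname read_hu_spr_curve
#' @param curve an [hu_spr_curve()].
#' @export
write_hu_spr_curve <- function(curve, path) {
  stopifnot(inherits(curve, "hu_spr_curve"))
  utils::write.csv(data.frame(hu = curve$hu, spr = curve$spr), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
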
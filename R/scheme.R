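#' HU allocation scheme
#'
#' Ordered half-open CT-number intervals `[lo, hi)` mapping to tissue
#' names.  The intervals must be contiguous and exactly partition the CT
#' domain (default [-1000, 2000]); the top interval is closed at the upper
#' domain edge.
#'
#' @param lo,hi numeric vectors of interval bounds.
#' @param tissue character vector of tissue names.
#' @param domain length-2 numeric, the CT-number domain to partition.
#' @return Object of class `hu_allocation_scheme` (a `data.frame` with
#'   columns `lo`, `hi`, `tissue`).
#' @export
hu_allocation_scheme <- function(lo, hi, tissue, domain = c(-1000, 2000)) {
  df <- data.frame(lo = as.numeric(lo), hi = as.numeric(hi),
                   tissue = as.character(tissue), stringsAsFactors = FALSE)
  df <- df[order(df$lo), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$hi <= df$lo)) stop("every interval needs hi > lo")
  if (df$lo[1] != domain[1] || df$hi[nrow(df)] != domain[2])
    stop(sprintf("intervals must span [%g, %g]", domain[1], domain[2]))
  if (nrow(df) > 1 && any(abs(df$lo[-1] - df$hi[-nrow(df)]) > 1e-9))
    stop("intervals must be contiguous and non-overlapping")
  structure(df, class = c("hu_allocation_scheme", "data.frame"),
            domain = domain)
}

#' Default allocation scheme
#'
#' The packaged CT-number to tissue allocation.  Interval boundaries are
#' chosen so that each validation material's representative CT number falls
#' in its own tissue's interval and the fat + adipose region spans
#' -150..10 HU; they are user-overridable via [hu_allocation_scheme()] or
#' [read_allocation_scheme()].
#'
#' @return An [hu_allocation_scheme()].
#' @export
default_allocation_scheme <- function() {
  hu_allocation_scheme(
    lo = c(-1000, -950, -150, -50, 10, 120, 220, 450, 1100),
    hi = c(-950, -150, -50, 10, 120, 220, 450, 1100, 2000),
    tissue = c("air", "lung", "fat", "adipose", "soft tissue",
               "muscle", "bone-scapula", "bone-mineral", "tooth")
  )
}

#' Assign a tissue to a CT number
#'
#' Looks up the half-open interval `[lo, hi)` containing each CT number;
#' the top interval is closed at the domain's upper edge.  CT numbers
#' outside the domain raise an error (callers may pre-clamp).
#'
#' @param hu numeric vector of CT numbers.
#' @param scheme an [hu_allocation_scheme()].
#' @return Character vector of tissue names.
#' @export
#' @examples
#' assign_tissue(715)   # "bone-mineral"
#' assign_tissue(-325)  # "lung"
assign_tissue <- function(hu, scheme = default_allocation_scheme()) {
  stopifnot(inherits(scheme, "hu_allocation_scheme"))
  domain <- attr(scheme, "domain")
  hu <- as.numeric(hu)
  if (anyNA(hu) || any(hu < domain[1]) || any(hu > domain[2]))
    stop(sprintf("CT number outside [%g, %g]", domain[1], domain[2]))
  # half-open [lo, hi): a breakpoint belongs to the interval it starts
  idx <- findInterval(hu, scheme$lo, rightmost.closed = FALSE)
  scheme$tissue[idx]
}

#' Read / write an allocation scheme as JSON
#'
#' JSON array of objects `{"lo": ..., "hi": ..., "tissue": ...}`.
#'
#' @param path file path.
#' @return `read_allocation_scheme`: an [hu_allocation_scheme()].
#' @export
read_allocation_scheme <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!all(c("lo", "hi", "tissue") %in% names(df)))
    stop("scheme JSON must have fields lo, hi, tissue: ", path)
  hu_allocation_scheme(df$lo, df$hi, df$tissue,
                       domain = c(min(df$lo), max(df$hi)))
}

#' @rdname read_allocation_scheme
#' @param scheme an [hu_allocation_scheme()].
#' @export
write_allocation_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "hu_allocation_scheme"))
  jsonlite::write_json(as.data.frame(scheme), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
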
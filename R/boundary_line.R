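#' Linear boundary line between two adjacent FHP levels
#'
#' A classification line `0 = K + L1 * X + L2 * Y` in the plane spanned by one
#' radiographic parameter (X) and the FNTA (Y, degrees), valid over the
#' parameter range `[x_min, x_max]`. Solving for the FNTA gives
#' `Y = -(K + L1 * X) / L2`, so `l2` must be nonzero; by convention `l2 < 0`
#' so that points with FNTA above the line get a positive side consistently.
#'
#' An optional effective range `[eff_x_min, eff_x_max]`, contained in the full
#' range, restricts where the line is swept when deciding whether an FNTA is
#' ambiguous (useful when the observed data span less than the plotted axis).
#'
#' @param k,l1,l2 Line constants K, L1, L2; `l2` must be nonzero.
#' @param x_min,x_max Parameter-axis range endpoints, `x_min < x_max`.
#' @param separates Integer vector of the two adjacent levels the line
#'   separates, one of `c(0, 1)`, `c(1, 2)`, `c(2, 3)`.
#' @param eff_x_min,eff_x_max Optional effective-range override for ambiguity
#'   determination; must lie within `[x_min, x_max]`.
#' @return An object of class `"fhp_boundary"`.
#' @seealso [boundary_fnta_at()], [boundary_fnta_range()], [fit_boundary()]
#' @export
#' @examples
#' bl <- boundary_line(4.7059, -0.0041, -0.4309, -5, 50, separates = c(0, 1))
#' boundary_fnta_range(bl)
boundary_line <- function(k, l1, l2, x_min, x_max, separates,
                          eff_x_min = NULL, eff_x_max = NULL) {
  for (v in list(k = k, l1 = l1, l2 = l2, x_min = x_min, x_max = x_max)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("line constants and range endpoints must be finite scalars",
           call. = FALSE)
    }
  }
  if (l2 == 0) stop("`l2` must be nonzero", call. = FALSE)
  if (x_min >= x_max) stop("`x_min` must be < `x_max`", call. = FALSE)
  separates <- as.integer(separates)
  ok <- length(separates) == 2L && separates[2L] == separates[1L] + 1L &&
    separates[1L] %in% 0:2
  if (!ok) {
    stop("`separates` must be adjacent levels (0,1), (1,2) or (2,3)",
         call. = FALSE)
  }
  if (!is.null(eff_x_min) || !is.null(eff_x_max)) {
    eff_x_min <- eff_x_min %||% x_min
    eff_x_max <- eff_x_max %||% x_max
    if (eff_x_min < x_min || eff_x_max > x_max || eff_x_min >= eff_x_max) {
      stop("effective range must be an interval inside [x_min, x_max]",
           call. = FALSE)
    }
  }
  structure(
    list(k = k, l1 = l1, l2 = l2, x_min = x_min, x_max = x_max,
         eff_x_min = eff_x_min, eff_x_max = eff_x_max,
         separates = separates),
    class = "fhp_boundary"
  )
}

#' Boundary FNTA at a given parameter value
#'
#' Evaluates `Y = -(K + L1 * X) / L2`, the FNTA at which the line sits for
#' parameter value `x`.
#'
#' @param line An [boundary_line()] object.
#' @param x Numeric vector of parameter values; each must lie within the
#'   line's `[x_min, x_max]`.
#' @return Numeric vector of boundary FNTA values in degrees.
#' @export
boundary_fnta_at <- function(line, x) {
  stopifnot(inherits(line, "fhp_boundary"))
  if (!is.numeric(x) || anyNA(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(x < line$x_min | x > line$x_max)) {
    stop(sprintf("`x` outside line range [%g, %g]", line$x_min, line$x_max),
         call. = FALSE)
  }
  -(line$k + line$l1 * x) / line$l2
}

#' Range of boundary FNTA values over a line's effective parameter range
#'
#' The line is affine in `x`, so its FNTA extremes over the effective range
#' are attained at the endpoints. An FNTA strictly inside `(min, max)` is
#' ambiguous with respect to this boundary: some parameter values would put
#' the participant above the line, others below.
#'
#' @inheritParams boundary_fnta_at
#' @return Numeric `c(min, max)` of the boundary FNTA, degrees.
#' @export
boundary_fnta_range <- function(line) {
  stopifnot(inherits(line, "fhp_boundary"))
  lo <- line$eff_x_min %||% line$x_min
  hi <- line$eff_x_max %||% line$x_max
  ends <- -(line$k + line$l1 * c(lo, hi)) / line$l2
  c(min(ends), max(ends))
}

#' @export
print.fhp_boundary <- function(x, ...) {
  rng <- boundary_fnta_range(x)
  cat(sprintf(
    "FHP boundary line %d|%d: 0 = %.4f + %.4f*X + %.4f*Y, X in [%g, %g]\n",
    x$separates[1L], x$separates[2L], x$k, x$l1, x$l2, x$x_min, x$x_max))
  cat(sprintf("  boundary FNTA range: [%.2f, %.2f] deg\n", rng[1L], rng[2L]))
  invisible(x)
}
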
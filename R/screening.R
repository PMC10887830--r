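#' Classify FHP level from the forward neck tilt angle
#'
#' Threshold screening: level 0 (Normal) for `0 <= fnta < 12`, level 1 for
#' `12 <= fnta < 25`, level 2 for `25 <= fnta < 40` and level 3 (radiology
#' requested) for `fnta >= 40`. Intervals are half-open with the lower bound
#' inclusive, so an FNTA exactly at a threshold belongs to the higher level.
#'
#' @param fnta Numeric vector of forward neck tilt angles in degrees; must be
#'   finite and nonnegative.
#' @param thresholds Strictly increasing vector of three cutoffs in degrees.
#'   Defaults to the published 12/25/40.
#' @return Integer vector of FHP levels in `0:3`.
#' @export
#' @examples
#' classify_fnta(c(0, 11, 12, 25, 62))
classify_fnta <- function(fnta, thresholds = .fhp_default_thresholds) {
  if (!is.numeric(fnta) || anyNA(fnta) || any(!is.finite(fnta))) {
    stop("`fnta` must be finite numeric", call. = FALSE)
  }
  if (any(fnta < 0)) {
    stop("`fnta` must be >= 0 (got ", min(fnta), ")", call. = FALSE)
  }
  .check_thresholds(thresholds)
  findInterval(fnta, thresholds)
}

.check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 3L ||
      anyNA(thresholds) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be three strictly increasing cutoffs",
         call. = FALSE)
  }
  invisible(thresholds)
}

# internal: FNTA interval [lo, hi) of one level given the thresholds
.level_interval <- function(level, thresholds = .fhp_default_thresholds) {
  edges <- c(0, thresholds, Inf)
  c(edges[level + 1L], edges[level + 2L])
}
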
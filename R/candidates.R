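#' Candidate FHP levels from one diagnostic model given only the FNTA
#'
#' At diagnosis time the radiographic parameter is unknown, so each boundary
#' line of the model is reduced to its FNTA interval over the effective
#' parameter range ([boundary_fnta_range()]). Relative to one boundary the
#' FNTA is *below* when `fnta <= min`, *above* when `fnta >= max`, and
#' *ambiguous* strictly inside the interval (the horizontal FNTA line crosses
#' the boundary within its range). A level `l` remains a candidate when every
#' boundary under it is above-or-ambiguous and every boundary over it is
#' below-or-ambiguous; with ordered boundaries this yields a nonempty
#' contiguous run, in practice one level or two adjacent ones.
#'
#' An FNTA exactly equal to an interval endpoint is unambiguous: at the
#' minimum it is below the boundary (lower level), at the maximum above it.
#'
#' @param model An `"fhp_model"`.
#' @param fnta Scalar FNTA in degrees, `>= 0`.
#' @return Integer vector of candidate levels (increasing, contiguous).
#' @export
#' @examples
#' bank <- default_model_bank()
#' candidate_levels(bank$models$CSA, 13) # unambiguous level 1
#' candidate_levels(bank$models$CCA, 11) # ambiguous between 0 and 1
candidate_levels <- function(model, fnta) {
  stopifnot(inherits(model, "fhp_model"))
  if (!is.numeric(fnta) || length(fnta) != 1L || !is.finite(fnta)) {
    stop("`fnta` must be a finite scalar", call. = FALSE)
  }
  if (fnta < 0) stop("`fnta` must be >= 0", call. = FALSE)
  # state per boundary: -1 below, +1 above, 0 ambiguous
  state <- vapply(model$lines, function(ln) {
    rng <- boundary_fnta_range(ln)
    if (fnta <= rng[1L]) -1L else if (fnta >= rng[2L]) 1L else 0L
  }, integer(1))
  keep <- vapply(0:3, function(l) {
    under <- seq_len(l)            # boundaries (b-1, b) with b <= l
    over <- setdiff(1:3, under)    # boundaries with b > l
    all(state[under] >= 0L) && all(state[over] <= 0L)
  }, logical(1))
  out <- (0:3)[keep]
  if (length(out) == 0L || any(diff(out) != 1L)) {
    stop("internal error: candidate set not a contiguous nonempty run for ",
         model$parameter, " at fnta = ", fnta, call. = FALSE)
  }
  out
}

#' Majority-vote FHP diagnosis across the eight diagnostic models
#'
#' Each model contributes one vote to every level in its candidate set; the
#' diagnosis is the level with the most votes. Ties (which do not occur on the
#' published evaluation data) are broken toward the higher level —
#' conservative with respect to radiographic referral — and flagged.
#'
#' @param bank An `"fhp_model_bank"` with all eight models.
#' @param fnta Scalar FNTA in degrees, `>= 0`.
#' @return A list of class `"fhp_diagnosis"` with elements `fnta`,
#'   `per_model_candidates` (named list of integer vectors),
#'   `vote_counts` (named numeric, levels `"0"`..`"3"`), `pc_level`
#'   (threshold classification), `final_level` (voted diagnosis) and
#'   `tie_flag`.
#' @export
#' @examples
#' vote_diagnosis(default_model_bank(), 25)
vote_diagnosis <- function(bank, fnta) {
  stopifnot(inherits(bank, "fhp_model_bank"))
  if (length(bank$models) != 8L) {
    stop("bank must contain the eight diagnostic models", call. = FALSE)
  }
  cands <- lapply(bank$models, candidate_levels, fnta = fnta)
  counts <- vapply(0:3, function(l) {
    sum(vapply(cands, function(cs) l %in% cs, logical(1)))
  }, numeric(1))
  names(counts) <- as.character(0:3)
  top <- which(counts == max(counts))
  structure(
    list(fnta = fnta,
         per_model_candidates = cands,
         vote_counts = counts,
         pc_level = classify_fnta(fnta, bank$thresholds),
         final_level = as.integer(max(top) - 1L),
         tie_flag = length(top) > 1L),
    class = "fhp_diagnosis"
  )
}

#' @export
print.fhp_diagnosis <- function(x, ...) {
  cat(sprintf("FNTA %.1f deg: screened level %d, voted diagnosis %d%s\n",
              x$fnta, x$pc_level, x$final_level,
              if (x$tie_flag) " (tie, broken upward)" else ""))
  cat("  votes:", paste(sprintf("%s=%d", fhp_level_labels(), x$vote_counts),
                        collapse = ", "), "\n")
  cells <- vapply(x$per_model_candidates, paste, "", collapse = ".")
  cat("  candidates:", paste(sprintf("%s:%s", names(cells), cells),
                             collapse = "  "), "\n")
  invisible(x)
}
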
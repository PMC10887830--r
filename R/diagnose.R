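#' Diagnose a set of participants from their FNTA values only
#'
#' Runs [vote_diagnosis()] for each FNTA and assembles the result sheet: one
#' row per participant with the per-model candidate cells (two-level sets
#' printed in the `"0.1"` / `"1.2"` dotted notation), the four vote counts
#' (`N`, `L1`, `L2`, `L3`), the threshold classification (`PC`) and the voted
#' diagnosis (`D`).
#'
#' @param fnta Numeric vector of FNTA values, or a cohort data frame with an
#'   `fnta` column (and optionally `participant_id`).
#' @param bank An `"fhp_model_bank"`; defaults to the packaged published one.
#' @param ids Optional participant labels.
#' @return Data frame of class `"fhp_sheet"` with columns `participant`,
#'   `fnta`, one character column per parameter, `N`, `L1`, `L2`, `L3`, `PC`,
#'   `D`, `tie`.
#' @export
#' @examples
#' diagnose_cohort(c(4, 11, 25, 62))
diagnose_cohort <- function(fnta, bank = default_model_bank(), ids = NULL) {
  if (is.data.frame(fnta)) {
    ids <- ids %||% fnta$participant_id
    fnta <- fnta$fnta
  }
  if (!is.numeric(fnta) || length(fnta) == 0L) {
    stop("`fnta` must be a nonempty numeric vector", call. = FALSE)
  }
  ids <- ids %||% as.character(seq_along(fnta))
  rows <- lapply(seq_along(fnta), function(i) {
    dg <- vote_diagnosis(bank, fnta[i])
    cells <- vapply(dg$per_model_candidates, paste, "", collapse = ".")
    out <- data.frame(participant = ids[i], fnta = fnta[i],
                      stringsAsFactors = FALSE)
    for (p in fhp_parameters()) out[[p]] <- cells[[p]]
    out$N <- dg$vote_counts[["0"]]
    out$L1 <- dg$vote_counts[["1"]]
    out$L2 <- dg$vote_counts[["2"]]
    out$L3 <- dg$vote_counts[["3"]]
    out$PC <- dg$pc_level
    out$D <- dg$final_level
    out$tie <- dg$tie_flag
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fhp_sheet", class(out))
  out
}

#' Write / read a diagnosis sheet
#'
#' Comma-delimited text mirroring the result-sheet layout (participant, FNTA,
#' eight candidate cells in dotted notation, vote counts, PC, D), with
#' `#`-prefixed provenance comments.
#'
#' @param sheet Diagnosis sheet from [diagnose_cohort()].
#' @param path File path.
#' @param provenance Optional named character vector of provenance fields.
#' @return `path` (write) or the sheet data frame (read).
#' @export
write_diagnosis_sheet <- function(sheet, path, provenance = NULL) {
  meta <- c(package = paste0("fhpdiag ",
                             as.character(utils::packageVersion("fhpdiag"))),
            provenance)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con, sep = "\n")
  utils::write.table(sheet, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_diagnosis_sheet
#' @export
read_diagnosis_sheet <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (p in intersect(c("participant", fhp_parameters()), names(out))) {
    out[[p]] <- as.character(out[[p]])
  }
  need <- c("fnta", "PC", "D")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("diagnosis sheet lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("fhp_sheet", class(out))
  out
}

#' The packaged 43-participant evaluation sheet
#'
#' The published evaluation cohort: 43 participants' FNTA values together
#' with the originally printed candidate cells, vote counts, threshold
#' classification (PC) and voted diagnosis (D). The FNTA, PC and D columns
#' are the authoritative fixture; a handful of printed candidate cells sit on
#' rounded boundary endpoints and can differ from exact-arithmetic
#' recomputation without changing any diagnosis (see the package vignette).
#'
#' @return Data frame with the sheet columns.
#' @export
#' @examples
#' sheet <- packaged_evaluation_sheet()
#' nrow(sheet)
packaged_evaluation_sheet <- function() {
  path <- system.file("extdata", "evaluation_sheet.csv", package = "fhpdiag",
                      mustWork = TRUE)
  read_diagnosis_sheet(path)
}
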
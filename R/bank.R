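#' Diagnostic model for one radiographic parameter
#'
#' Bundles the three boundary lines of one parameter's scatter-plot model: the
#' blue line separating Normal from Level 1, the pink line separating Levels 1
#' and 2, and the red line separating Levels 2 and 3. The lines must be
#' ordered: at the midpoint of the common parameter range the blue boundary
#' FNTA lies below the pink, which lies below the red.
#'
#' @param parameter One of [fhp_parameters()].
#' @param blue,pink,red [boundary_line()] objects separating (0,1), (1,2) and
#'   (2,3) respectively.
#' @return An object of class `"fhp_model"`.
#' @export
diagnostic_model <- function(parameter, blue, pink, red) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% fhp_parameters()) {
    stop("`parameter` must be one of ", paste(fhp_parameters(), collapse = ", "),
         call. = FALSE)
  }
  lines <- list(blue = blue, pink = pink, red = red)
  want <- list(c(0L, 1L), c(1L, 2L), c(2L, 3L))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!inherits(ln, "fhp_boundary")) {
      stop("`", names(lines)[i], "` must be a boundary_line", call. = FALSE)
    }
    if (!identical(ln$separates, want[[i]])) {
      stop("`", names(lines)[i], "` must separate levels ",
           paste(want[[i]], collapse = " and "), call. = FALSE)
    }
  }
  xmid <- mean(c(max(vapply(lines, `[[`, 0, "x_min")),
                 min(vapply(lines, `[[`, 0, "x_max"))))
  ys <- vapply(lines, boundary_fnta_at, 0, x = xmid)
  if (is.unsorted(ys, strictly = TRUE)) {
    stop(sprintf(
      "boundary ordering violated for %s: blue/pink/red FNTA at x = %.3g are %s",
      parameter, xmid, paste(sprintf("%.2f", ys), collapse = " / ")),
      call. = FALSE)
  }
  structure(list(parameter = parameter, lines = lines), class = "fhp_model")
}

#' Bank of the eight diagnostic models plus screening thresholds
#'
#' @param models Named list of eight [diagnostic_model()] objects, one per
#'   parameter in [fhp_parameters()].
#' @param thresholds Screening cutoffs, see [classify_fnta()].
#' @return An object of class `"fhp_model_bank"`.
#' @export
model_bank <- function(models, thresholds = .fhp_default_thresholds) {
  .check_thresholds(thresholds)
  if (!is.list(models) || !setequal(names(models), fhp_parameters()) ||
      length(models) != 8L) {
    stop("`models` must be a named list with exactly one model per parameter: ",
         paste(fhp_parameters(), collapse = ", "), call. = FALSE)
  }
  models <- models[fhp_parameters()]
  for (p in fhp_parameters()) {
    m <- models[[p]]
    if (!inherits(m, "fhp_model") || m$parameter != p) {
      stop("`models$", p, "` must be a diagnostic_model for ", p,
           call. = FALSE)
    }
  }
  structure(list(thresholds = as.numeric(thresholds), models = models),
            class = "fhp_model_bank")
}

#' @export
print.fhp_model_bank <- function(x, ...) {
  cat("FHP diagnostic model bank (8 models)\n")
  cat("  screening thresholds:", paste(x$thresholds, collapse = " / "),
      "deg\n")
  for (p in names(x$models)) {
    rng <- vapply(x$models[[p]]$lines, boundary_fnta_range, numeric(2))
    cat(sprintf(
      "  %-5s boundary FNTA  0|1: [%5.1f, %5.1f]  1|2: [%5.1f, %5.1f]  2|3: [%5.1f, %5.1f]\n",
      p, rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

.bank_line_fields <- c("K", "L1", "L2", "LE", "RE")

#' Load a diagnostic-model constants bank from JSON
#'
#' The bank file has the schema
#' `{"thresholds": [12, 25, 40], "models": {"CSA": {"blue": {"K": ..., "L1":
#' ..., "L2": ..., "LE": ..., "RE": ..., "eff_LE": ..., "eff_RE": ...},
#' "pink": {...}, "red": {...}}, ...}}` with `eff_LE`/`eff_RE` optional. All
#' eight parameters and all three lines are required; a missing field is a
#' schema error naming its path.
#'
#' @param path Path to the JSON file; defaults to the packaged published bank.
#' @return An `"fhp_model_bank"`.
#' @export
#' @examples
#' bank <- default_model_bank()
#' bank$models$CSA$lines$blue$k
load_model_bank <- function(path = fhpdiag_bank_file()) {
  if (!file.exists(path)) stop("bank file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(raw$thresholds)) stop("bank schema error: missing `thresholds`",
                                    call. = FALSE)
  if (is.null(raw$models)) stop("bank schema error: missing `models`",
                                call. = FALSE)
  missing_models <- setdiff(fhp_parameters(), names(raw$models))
  if (length(missing_models)) {
    stop("bank schema error: missing models: ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  sep <- list(blue = c(0L, 1L), pink = c(1L, 2L), red = c(2L, 3L))
  models <- lapply(fhp_parameters(), function(p) {
    entry <- raw$models[[p]]
    lines <- lapply(names(sep), function(colr) {
      ln <- entry[[colr]]
      if (is.null(ln)) {
        stop("bank schema error: missing models$", p, "$", colr, call. = FALSE)
      }
      miss <- setdiff(.bank_line_fields, names(ln))
      if (length(miss)) {
        stop("bank schema error: missing models$", p, "$", colr, "$",
             miss[1L], call. = FALSE)
      }
      num <- function(v) if (is.null(v)) NULL else as.numeric(v)
      boundary_line(num(ln$K), num(ln$L1), num(ln$L2), num(ln$LE), num(ln$RE),
                    separates = sep[[colr]],
                    eff_x_min = num(ln$eff_LE), eff_x_max = num(ln$eff_RE))
    })
    names(lines) <- names(sep)
    diagnostic_model(p, lines$blue, lines$pink, lines$red)
  })
  names(models) <- fhp_parameters()
  model_bank(models, thresholds = as.numeric(raw$thresholds))
}

#' Write a model bank to JSON
#'
#' Constants are serialized at full double precision so that a save/load
#' round trip reproduces the bank bit-exactly.
#'
#' @param bank An `"fhp_model_bank"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_bank <- function(bank, path) {
  stopifnot(inherits(bank, "fhp_model_bank"))
  to_entry <- function(ln) {
    out <- list(K = ln$k, L1 = ln$l1, L2 = ln$l2, LE = ln$x_min, RE = ln$x_max)
    if (!is.null(ln$eff_x_min)) out$eff_LE <- ln$eff_x_min
    if (!is.null(ln$eff_x_max)) out$eff_RE <- ln$eff_x_max
    out
  }
  payload <- list(
    thresholds = bank$thresholds,
    models = lapply(bank$models, function(m) lapply(m$lines, to_entry))
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Path to the packaged published constants bank
#' @return File path of the JSON bank installed with the package.
#' @export
fhpdiag_bank_file <- function() {
  system.file("extdata", "model_bank.json", package = "fhpdiag",
              mustWork = TRUE)
}

#' The packaged published model bank
#'
#' Constants of the eight published diagnostic models (three lines each, with
#' their parameter-axis ranges) and the 12/25/40 screening thresholds.
#'
#' @return An `"fhp_model_bank"`.
#' @export
default_model_bank <- function() {
  load_model_bank(fhpdiag_bank_file())
}
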
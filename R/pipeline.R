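.fhp_error <- function(category, msg) {
  stop(structure(class = c(paste0("fhp_", category, "_error"), "error",
                           "condition"),
                 list(message = paste0("[", category, "] ", msg),
                      call = NULL)))
}

#' Run one stage of the FHP diagnostic pipeline
#'
#' Dispatches the pipeline stages, writing artifacts to disk with provenance
#' comments (command, package version, seed, bank digest):
#'
#' * `simulate` — generate a synthetic cohort from a cohort spec and write it
#'   as CSV.
#' * `fit` — fit the eight-model bank from a labelled cohort CSV and write it
#'   as a JSON constants bank.
#' * `diagnose` — run the FNTA-only voted diagnosis on a cohort CSV against a
#'   constants bank and write the result sheet.
#' * `evaluate` — read a diagnosis sheet and write agreement/confusion
#'   report as a delimited table plus a human-readable summary.
#' * `report` — render the confusion chart and the eight model figures to a
#'   PDF.
#'
#' Errors are raised as classed conditions (`fhp_config_error`,
#' `fhp_data_error`, `fhp_numerical_error`) so the command-line wrapper can
#' categorize its exit messages.
#'
#' @param command One of `"simulate"`, `"fit"`, `"diagnose"`, `"evaluate"`,
#'   `"report"`.
#' @param input Input path (cohort CSV or diagnosis sheet, by command).
#' @param output Output path; for `evaluate` the summary is written alongside
#'   with extension `.txt`.
#' @param bank_path Constants-bank JSON; default is the packaged bank.
#' @param seed Integer seed for `simulate`.
#' @param train_fraction Training proportion recorded for `fit` workflows
#'   (the split itself is done with [split_cohort()] by the caller or via
#'   `split = TRUE`).
#' @param split For `fit`: split the cohort first and fit on the training
#'   part only.
#' @param n_per_level Per-level counts for `simulate`.
#' @param verbose Emit progress messages.
#' @return The main artifact of the stage, invisibly (cohort, bank, sheet or
#'   evaluation object).
#' @export
#' @examples
#' out <- tempfile(fileext = ".csv")
#' run_pipeline("simulate", output = out, seed = 3)
#' nrow(read_cohort(out))
run_pipeline <- function(command = c("simulate", "fit", "diagnose",
                                     "evaluate", "report"),
                         input = NULL, output = NULL,
                         bank_path = fhpdiag_bank_file(), seed = 1L,
                         train_fraction = 0.70, split = FALSE,
                         n_per_level = c(38L, 55L, 36L, 16L),
                         verbose = FALSE) {
  command <- match.arg(command)
  say <- function(...) if (verbose) message(...)
  need_input <- function() {
    if (is.null(input)) .fhp_error("config", "`input` is required")
    if (!file.exists(input)) {
      .fhp_error("config", paste0("input file not found: ", input))
    }
  }
  if (is.null(output)) .fhp_error("config", "`output` is required")
  if (train_fraction <= 0 || train_fraction >= 1) {
    .fhp_error("config", "`train_fraction` must be in (0, 1)")
  }

  if (command == "simulate") {
    spec <- default_cohort_spec(n = n_per_level, seed = seed)
    cohort <- generate_cohort(spec)
    write_cohort(cohort, output, provenance = c(command = "simulate"))
    say("simulate: wrote ", nrow(cohort), " participants to ", output)
    return(invisible(cohort))
  }

  need_input()
  if (command == "fit") {
    cohort <- tryCatch(read_cohort(input),
                       error = function(e) .fhp_error("data",
                                                      conditionMessage(e)))
    if (split) {
      cohort <- split_cohort(cohort, train_fraction, seed = seed)$train
    }
    bank <- tryCatch(fit_model_bank(cohort),
                     error = function(e) .fhp_error("numerical",
                                                    conditionMessage(e)))
    write_model_bank(bank, output)
    say("fit: wrote constants bank to ", output)
    return(invisible(bank))
  }

  bank <- tryCatch(load_model_bank(bank_path),
                   error = function(e) .fhp_error("config",
                                                  conditionMessage(e)))
  digest <- unname(tools::md5sum(bank_path))

  if (command == "diagnose") {
    cohort <- tryCatch(read_cohort(input),
                       error = function(e) .fhp_error("data",
                                                      conditionMessage(e)))
    sheet <- diagnose_cohort(cohort, bank = bank)
    write_diagnosis_sheet(sheet, output,
                          provenance = c(command = "diagnose",
                                         seed = as.character(seed),
                                         bank_digest = digest))
    say("diagnose: wrote ", nrow(sheet), "-row sheet to ", output)
    return(invisible(sheet))
  }

  if (command == "evaluate") {
    sheet <- tryCatch(read_diagnosis_sheet(input),
                      error = function(e) .fhp_error("data",
                                                     conditionMessage(e)))
    report <- confusion_report(sheet$PC, sheet$D, ids = sheet$participant)
    write_evaluation(report, output,
                     provenance = c(command = "evaluate",
                                    bank_digest = digest))
    say(sprintf("evaluate: agreement %.2f%% over %d participants",
                report$agreement_ratio, report$n))
    return(invisible(report))
  }

  # report: figures
  sheet <- tryCatch(read_diagnosis_sheet(input),
                    error = function(e) .fhp_error("data",
                                                   conditionMessage(e)))
  report <- confusion_report(sheet$PC, sheet$D, ids = sheet$participant)
  grDevices::pdf(output, width = 7, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off())
  plot_confusion(report)
  for (p in fhp_parameters()) plot_diagnostic_model(bank$models[[p]])
  say("report: wrote figures to ", output)
  invisible(report)
}

#' Write an evaluation report to disk
#'
#' Writes the confusion counts with their marginal rates as a delimited table
#' and a human-readable summary file (same path, `.txt` extension).
#'
#' @param report An `"fhp_evaluation"`.
#' @param path Output CSV path.
#' @param provenance Optional named character vector of provenance fields.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "fhp_evaluation"))
  meta <- c(package = paste0("fhpdiag ",
                             as.character(utils::packageVersion("fhpdiag"))),
            n = as.character(report$n),
            agreement_ratio = sprintf("%.2f", report$agreement_ratio),
            provenance)
  tab <- as.data.frame(report$confusion)
  tab <- data.frame(pc = tab$PC, d = tab$D, count = tab$Freq)
  con <- file(path, open = "wb")
  writeLines(sprintf("# %s: %s", names(meta), meta), con, sep = "\n")
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  close(con)
  txt <- paste0(tools::file_path_sans_ext(path), ".txt")
  sink(txt)
  print(report)
  sink()
  invisible(path)
}

#' Plot one diagnostic model's three boundary lines
#'
#' Scatter-plot layout with the radiographic parameter on the horizontal axis
#' and the FNTA on the vertical axis; the blue, pink and red lines separate
#' adjacent levels. Cohort points, when given, are colored by level.
#'
#' @param model An `"fhp_model"`.
#' @param cohort Optional cohort data frame to overlay.
#' @return The model, invisibly.
#' @export
plot_diagnostic_model <- function(model, cohort = NULL) {
  stopifnot(inherits(model, "fhp_model"))
  xs <- seq(model$lines$blue$x_min, model$lines$blue$x_max, length.out = 50)
  ys <- vapply(model$lines, function(ln) {
    boundary_fnta_at(ln, pmin(pmax(xs, ln$x_min), ln$x_max))
  }, numeric(length(xs)))
  cols <- c(blue = "#1f77b4", pink = "#e377c2", red = "#d62728")
  ylim <- range(0, ys, if (!is.null(cohort)) cohort$fnta)
  plot(NA, xlim = range(xs), ylim = ylim, xlab = model$parameter,
       ylab = "FNTA (deg)",
       main = paste("Diagnostic model:", model$parameter))
  if (!is.null(cohort)) {
    lev <- if ("known_level" %in% names(cohort)) cohort$known_level
           else classify_fnta(cohort$fnta)
    pt_cols <- c("skyblue3", "blue4", "deeppink3", "red3")[lev + 1L]
    graphics::points(cohort[[model$parameter]], cohort$fnta, col = pt_cols,
                     pch = c(1, 6, 2, 4)[lev + 1L])
  }
  for (i in seq_along(model$lines)) {
    graphics::lines(xs, ys[, i], col = cols[[names(model$lines)[i]]],
                    lwd = 2)
  }
  invisible(model)
}

#' Plot a confusion chart with marginal rates
#'
#' Grid of confusion counts (rows = screened level, columns = voted
#' diagnosis) with per-row TPR/FNR and per-column PPV/FDR margins.
#'
#' @param report An `"fhp_evaluation"`.
#' @return The report, invisibly.
#' @export
plot_confusion <- function(report) {
  stopifnot(inherits(report, "fhp_evaluation"))
  op <- graphics::par(mar = c(5, 5, 4, 1))
  on.exit(graphics::par(op))
  plot(NA, xlim = c(0.5, 5.5), ylim = c(5.5, 0.5), axes = FALSE,
       xlab = "Voted diagnosis (D)", ylab = "Screened level (PC)",
       main = sprintf("Agreement %.2f%% (n = %d)", report$agreement_ratio,
                      report$n))
  labs <- fhp_level_labels()
  graphics::axis(1, at = 1:4, labels = labs, tick = FALSE)
  graphics::axis(2, at = 1:4, labels = labs, tick = FALSE, las = 2)
  for (i in 1:4) {
    for (j in 1:4) {
      cnt <- report$confusion[i, j]
      bg <- if (i == j && cnt > 0) "#cfe8cf" else if (cnt > 0) "#f4c7c3"
            else "white"
      graphics::rect(j - 0.5, i - 0.5, j + 0.5, i + 0.5, col = bg)
      graphics::text(j, i, cnt)
    }
    graphics::rect(4.5, i - 0.5, 5.5, i + 0.5, col = "grey95")
    graphics::text(5, i, if (is.na(report$tpr[i])) "-" else
      sprintf("TPR %.0f%%\nFNR %.0f%%", report$tpr[i], report$fnr[i]),
      cex = 0.7)
  }
  for (j in 1:4) {
    graphics::rect(j - 0.5, 4.5, j + 0.5, 5.5, col = "grey95")
    graphics::text(j, 5, if (is.na(report$ppv[j])) "-" else
      sprintf("PPV %.0f%%\nFDR %.0f%%", report$ppv[j], report$fdr[j]),
      cex = 0.7)
  }
  invisible(report)
}
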
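#' Agreement ratio between screening classification and voted diagnosis
#'
#' Percentage of participants whose voted diagnosis equals their FNTA
#' threshold classification, reported to two decimals.
#'
#' @param pc,d Equal-length integer vectors of FHP levels (0-3).
#' @return Percent agreement, rounded to two decimals.
#' @export
#' @examples
#' agreement_ratio(c(0, 1), c(1, 1))
agreement_ratio <- function(pc, d) {
  if (length(pc) != length(d)) {
    stop("`pc` and `d` must have equal length", call. = FALSE)
  }
  if (length(pc) == 0L) stop("empty input", call. = FALSE)
  round(100 * mean(pc == d), 2)
}

#' Confusion report of screening classification versus voted diagnosis
#'
#' Builds the 4x4 confusion matrix (rows = threshold classification PC,
#' columns = voted diagnosis D) with its per-row true-positive and
#' false-negative rates and per-column positive predictive values and false
#' discovery rates. Rates of empty rows/columns are reported as `NA`, never
#' as zero.
#'
#' @param pc,d Equal-length nonempty integer vectors of levels in 0-3.
#' @param ids Optional participant labels used in the disagreement list.
#' @return A list of class `"fhp_evaluation"` with `n`, `agreement_ratio`,
#'   `confusion` (4x4 matrix), `tpr`, `fnr`, `ppv`, `fdr` (per-level
#'   percentages, `NA` when undefined) and `disagreements` (data frame of
#'   `participant`, `pc`, `d`).
#' @export
#' @examples
#' sheet <- packaged_evaluation_sheet()
#' confusion_report(sheet$PC, sheet$D, ids = sheet$participant)
confusion_report <- function(pc, d, ids = NULL) {
  if (length(pc) != length(d) || length(pc) == 0L) {
    stop("`pc` and `d` must be nonempty and of equal length", call. = FALSE)
  }
  if (!all(pc %in% 0:3) || !all(d %in% 0:3)) {
    stop("levels must lie in 0-3", call. = FALSE)
  }
  ids <- ids %||% as.character(seq_along(pc))
  lv <- factor(0:3, levels = 0:3)
  confusion <- table(PC = factor(pc, levels = 0:3),
                     D = factor(d, levels = 0:3))
  confusion <- unclass(confusion)
  row_n <- rowSums(confusion)
  col_n <- colSums(confusion)
  diagc <- diag(confusion)
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  mism <- which(pc != d)
  structure(
    list(n = length(pc),
         agreement_ratio = agreement_ratio(pc, d),
         confusion = confusion,
         tpr = rate(diagc, row_n),
         fnr = rate(row_n - diagc, row_n),
         ppv = rate(diagc, col_n),
         fdr = rate(col_n - diagc, col_n),
         disagreements = data.frame(participant = ids[mism],
                                    pc = pc[mism], d = d[mism],
                                    stringsAsFactors = FALSE)),
    class = "fhp_evaluation"
  )
}

#' @export
print.fhp_evaluation <- function(x, ...) {
  cat(sprintf("FHP diagnosis evaluation: n = %d, agreement = %.2f%%\n",
              x$n, x$agreement_ratio))
  cat("confusion matrix (rows = screened PC, cols = voted D):\n")
  print(x$confusion)
  fmt <- function(v) paste(ifelse(is.na(v), "  -  ", sprintf("%5.1f", v)),
                           collapse = " ")
  cat("TPR% per level:", fmt(x$tpr), "\n")
  cat("FNR% per level:", fmt(x$fnr), "\n")
  cat("PPV% per level:", fmt(x$ppv), "\n")
  cat("FDR% per level:", fmt(x$fdr), "\n")
  if (nrow(x$disagreements)) {
    cat("disagreements:\n")
    print(x$disagreements, row.names = FALSE)
  }
  invisible(x)
}

#' Normality and correlation table for a cohort
#'
#' For each radiographic parameter: Shapiro-Wilk normality p-value of the
#' parameter, and Spearman and Pearson correlation coefficients with
#' two-sided p-values against the FNTA and against the FHP level treated as
#' an integer score 0-3 (ordinal hypothesis). Spearman uses average ranks for
#' ties with the t-approximation for p; set `p_method = "permutation"` for a
#' Monte-Carlo permutation p (useful at small n where the approximation is
#' rough).
#'
#' @param cohort Cohort data frame with `fnta`, the eight parameters and
#'   `known_level` (or levels computable by [classify_fnta()]).
#' @param p_method `"asymptotic"` (default) or `"permutation"` for the
#'   correlation p-values.
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return Data frame with one row per parameter: `parameter`, `normality_p`,
#'   `spearman_rho_fnta`, `spearman_p_fnta`, `pearson_r_fnta`,
#'   `pearson_p_fnta`, and the same four statistics against the level.
#'   Constant parameters yield `NA` correlations with a warning.
#' @export
correlation_table <- function(cohort, p_method = c("asymptotic", "permutation"),
                              n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) < 4L) stop("need at least 4 records", call. = FALSE)
  lev <- if ("known_level" %in% names(cohort) &&
             !all(is.na(cohort$known_level))) {
    cohort$known_level
  } else {
    classify_fnta(cohort$fnta)
  }
  cor_pair <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(NA_real_, NA_real_))
    }
    est <- stats::cor(x, y, method = method)
    if (p_method == "asymptotic") {
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = method, exact = FALSE))
      c(est, ct$p.value)
    } else {
      obs <- abs(est)
      hits <- withr::with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          abs(stats::cor(x, sample(y), method = method)) >= obs - 1e-12
        }, logical(1)))
      })
      c(est, (hits + 1) / (n_perm + 1))
    }
  }
  rows <- lapply(fhp_parameters(), function(p) {
    v <- cohort[[p]]
    if (stats::sd(v) == 0) {
      warning("constant parameter ", p, ": correlations undefined",
              call. = FALSE)
    }
    sw <- if (stats::sd(v) > 0 && nrow(cohort) >= 3 && nrow(cohort) <= 5000) {
      stats::shapiro.test(v)$p.value
    } else {
      NA_real_
    }
    sf <- cor_pair(v, cohort$fnta, "spearman")
    pf <- cor_pair(v, cohort$fnta, "pearson")
    sl <- cor_pair(v, lev, "spearman")
    pl <- cor_pair(v, lev, "pearson")
    data.frame(parameter = p, normality_p = sw,
               spearman_rho_fnta = sf[1], spearman_p_fnta = sf[2],
               pearson_r_fnta = pf[1], pearson_p_fnta = pf[2],
               spearman_rho_level = sl[1], spearman_p_level = sl[2],
               pearson_r_level = pl[1], pearson_p_level = pl[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-level means and standard deviations
#'
#' Sample mean and SD (n - 1 denominator) of the FNTA and each radiographic
#' parameter, per FHP level. Levels come from `known_level` or, when absent,
#' from threshold screening. Empty levels are reported with `n = 0` and `NA`
#' moments; a single-record level has a mean but an `NA` SD.
#'
#' @param cohort Cohort data frame.
#' @return Data frame in long form: `level`, `n`, `variable`, `mean`, `sd`.
#' @export
level_summary <- function(cohort) {
  cohort <- as.data.frame(cohort)
  lev <- if ("known_level" %in% names(cohort) &&
             !all(is.na(cohort$known_level))) {
    cohort$known_level
  } else {
    classify_fnta(cohort$fnta)
  }
  vars <- intersect(c("age", "fnta", fhp_parameters()), names(cohort))
  rows <- lapply(0:3, function(l) {
    sub <- cohort[lev == l, , drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      x <- sub[[v]]
      data.frame(level = l, n = nrow(sub), variable = v,
                 mean = if (nrow(sub) >= 1L) mean(x) else NA_real_,
                 sd = if (nrow(sub) >= 2L) stats::sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
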
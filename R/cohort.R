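#' Per-level distribution of FNTA and radiographic parameters
#'
#' Normal means and SDs of the FNTA and of each of the eight radiographic
#' parameters for one FHP level, plus the number of participants to simulate
#' at that level.
#'
#' @param level FHP level, 0-3.
#' @param fnta_mean,fnta_sd FNTA mean and SD, degrees; `fnta_sd >= 0`.
#' @param param_means,param_sds Named numeric vectors over exactly
#'   [fhp_parameters()]; SDs nonnegative. Degrees except CSA (mm).
#' @param n Number of participants at this level, `>= 0`.
#' @return An object of class `"fhp_level_dist"`.
#' @export
level_distribution <- function(level, fnta_mean, fnta_sd, param_means,
                               param_sds, n) {
  level <- as.integer(level)
  if (!level %in% 0:3) stop("`level` must be 0-3", call. = FALSE)
  if (!is.numeric(fnta_sd) || fnta_sd < 0) {
    stop("`fnta_sd` must be >= 0", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be >= 0", call. = FALSE)
  if (!setequal(names(param_means), fhp_parameters()) ||
      !setequal(names(param_sds), fhp_parameters())) {
    stop("`param_means`/`param_sds` must be named over exactly: ",
         paste(fhp_parameters(), collapse = ", "), call. = FALSE)
  }
  if (any(param_sds < 0)) stop("`param_sds` must all be >= 0", call. = FALSE)
  structure(
    list(level = level, fnta_mean = fnta_mean, fnta_sd = fnta_sd,
         param_means = param_means[fhp_parameters()],
         param_sds = param_sds[fhp_parameters()], n = n),
    class = "fhp_level_dist"
  )
}

#' Specification of a synthetic cohort
#'
#' @param levels List of four [level_distribution()] objects, one per level
#'   0-3, each level exactly once.
#' @param truncate_fnta_to_level_range If `TRUE` (default), each level's FNTA
#'   is drawn from its normal truncated to the level's screening interval, so
#'   `known_level` is consistent with [classify_fnta()]. If `FALSE`, plain
#'   normals are drawn.
#' @param correlation_fnta_param Optional named vector in `[-1, 1]` (names
#'   from [fhp_parameters()]) giving the within-level correlation between the
#'   FNTA and each parameter, imposed via a bivariate-normal construction on
#'   the underlying Gaussian scores. Missing entries default to 0, matching
#'   the near-zero correlations observed in practice.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @param thresholds Screening cutoffs defining the level intervals used for
#'   truncation.
#' @return An object of class `"fhp_cohort_spec"`.
#' @export
cohort_spec <- function(levels, truncate_fnta_to_level_range = TRUE,
                        correlation_fnta_param = NULL, seed = 1L,
                        thresholds = .fhp_default_thresholds) {
  if (!is.list(levels) ||
      !all(vapply(levels, inherits, logical(1), "fhp_level_dist"))) {
    stop("`levels` must be a list of level_distribution objects",
         call. = FALSE)
  }
  lvls <- vapply(levels, `[[`, integer(1), "level")
  if (!setequal(lvls, 0:3) || length(lvls) != 4L) {
    stop("`levels` must contain levels 0-3 exactly once each", call. = FALSE)
  }
  levels <- levels[order(lvls)]
  if (!is.null(correlation_fnta_param)) {
    bad <- setdiff(names(correlation_fnta_param), fhp_parameters())
    if (length(bad) || is.null(names(correlation_fnta_param))) {
      stop("correlation names must come from fhp_parameters()", call. = FALSE)
    }
    if (any(abs(correlation_fnta_param) > 1)) {
      stop("`correlation_fnta_param` values must lie in [-1, 1]",
           call. = FALSE)
    }
  }
  .check_thresholds(thresholds)
  structure(
    list(levels = levels,
         truncate_fnta_to_level_range = isTRUE(truncate_fnta_to_level_range),
         correlation_fnta_param = correlation_fnta_param,
         seed = as.integer(seed),
         thresholds = as.numeric(thresholds)),
    class = "fhp_cohort_spec"
  )
}

#' Read a cohort specification from a YAML file
#'
#' The file holds `truncate_fnta_to_level_range`, optional `correlation`,
#' optional `seed`, and a `levels` map keyed by level with `n`, `fnta:
#' {mean, sd}` and `params: {<name>: {mean, sd}}` entries. The packaged
#' default file carries the study population's per-level means and SDs.
#'
#' @param path YAML file; defaults to the packaged spec.
#' @param n Optional length-4 override of the per-level counts (levels 0-3).
#' @param seed Optional seed override.
#' @return An `"fhp_cohort_spec"`.
#' @export
read_cohort_spec <- function(path = fhpdiag_cohort_spec_file(), n = NULL,
                             seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$levels)) stop("cohort spec: missing `levels`", call. = FALSE)
  lv_names <- names(raw$levels)
  levels <- lapply(seq_along(raw$levels), function(i) {
    e <- raw$levels[[i]]
    level_distribution(
      level = as.integer(lv_names[i]),
      fnta_mean = e$fnta$mean, fnta_sd = e$fnta$sd,
      param_means = vapply(e$params, `[[`, 0, "mean"),
      param_sds = vapply(e$params, `[[`, 0, "sd"),
      n = if (!is.null(n)) n[i] else e$n
    )
  })
  corr <- raw$correlation
  if (!is.null(corr)) corr <- unlist(corr)
  cohort_spec(
    levels,
    truncate_fnta_to_level_range = raw$truncate_fnta_to_level_range %||% TRUE,
    correlation_fnta_param = corr,
    seed = seed %||% raw$seed %||% 1L
  )
}

#' Path to the packaged cohort specification
#' @return File path of the YAML spec installed with the package.
#' @export
fhpdiag_cohort_spec_file <- function() {
  system.file("extdata", "cohort_spec.yaml", package = "fhpdiag",
              mustWork = TRUE)
}

#' The default synthetic-cohort specification
#'
#' Per-level FNTA and parameter means/SDs of the study population, with
#' default per-level counts `c(38, 55, 36, 16)` (total 145). The published
#' tables do not report per-level counts, so this allocation is a documented,
#' configurable placeholder chosen to sum to the study's 145 participants
#' with most mass at levels 0-1.
#'
#' @param n Length-4 integer vector of participants per level 0-3.
#' @param seed Integer seed.
#' @return An `"fhp_cohort_spec"`.
#' @export
default_cohort_spec <- function(n = c(38L, 55L, 36L, 16L), seed = 1L) {
  stopifnot(length(n) == 4L)
  read_cohort_spec(fhpdiag_cohort_spec_file(), n = n, seed = seed)
}

# inverse-CDF draw from N(0,1) truncated to [a, b] on the standard scale
.rtruncnorm_std <- function(n, a, b) {
  lo <- stats::pnorm(a)
  hi <- stats::pnorm(b)
  stats::qnorm(stats::runif(n, lo, hi))
}

#' Generate a seeded synthetic cohort
#'
#' Draws, per level, the FNTA from the level's normal distribution (truncated
#' to the level's screening interval when the spec says so) and each
#' radiographic parameter from its level normal. A per-parameter correlation
#' with the FNTA, when requested, is imposed through a shared standard-normal
#' score: `param = mu + sigma * (r * z_fnta + sqrt(1 - r^2) * z)`. The whole
#' cohort comes from a single seeded PRNG stream, so identical spec (seed
#' included) gives an identical cohort; the caller's RNG state is left
#' untouched.
#'
#' @param spec An [cohort_spec()].
#' @return Data frame with columns `participant_id`, `fnta`, the eight
#'   parameters, and `known_level` (the generating level); attribute `seed`
#'   records the seed used.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' table(cohort$known_level)
generate_cohort <- function(spec) {
  if (!inherits(spec, "fhp_cohort_spec")) {
    stop("`spec` must be an fhp_cohort_spec", call. = FALSE)
  }
  pars <- fhp_parameters()
  rho <- stats::setNames(numeric(8), pars)
  if (!is.null(spec$correlation_fnta_param)) {
    rho[names(spec$correlation_fnta_param)] <- spec$correlation_fnta_param
  }
  blocks <- withr::with_seed(spec$seed, lapply(spec$levels, function(ld) {
    n <- ld$n
    if (n == 0L) return(NULL)
    if (spec$truncate_fnta_to_level_range && ld$fnta_sd > 0) {
      iv <- .level_interval(ld$level, spec$thresholds)
      z1 <- .rtruncnorm_std(n, (iv[1L] - ld$fnta_mean) / ld$fnta_sd,
                            (iv[2L] - ld$fnta_mean) / ld$fnta_sd)
    } else {
      z1 <- stats::rnorm(n)
    }
    fnta <- ld$fnta_mean + ld$fnta_sd * z1
    vals <- vapply(pars, function(p) {
      r <- rho[[p]]
      z2 <- stats::rnorm(n)
      ld$param_means[[p]] + ld$param_sds[[p]] * (r * z1 + sqrt(1 - r^2) * z2)
    }, numeric(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, pars))
    cbind(data.frame(fnta = fnta), as.data.frame(vals),
          known_level = ld$level)
  }))
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L) {
    out <- data.frame(participant_id = character(), fnta = numeric())
    for (p in pars) out[[p]] <- numeric()
    out$known_level <- integer()
  } else {
    out <- do.call(rbind, blocks)
    out <- cbind(participant_id = sprintf("P%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
  }
  attr(out, "seed") <- spec$seed
  out
}

#' Split a cohort into training and evaluation subsets
#'
#' The evaluation set receives `floor((1 - train_fraction) * n)` participants
#' and the training set the remainder. With `stratify = TRUE` the evaluation
#' allocation is proportional across FHP levels (largest-remainder rounding),
#' reflecting a split balanced by level; levels come from `known_level` or,
#' if absent, from threshold screening of the FNTA.
#'
#' @param records Cohort data frame.
#' @param train_fraction Proportion in `(0, 1)` assigned to training
#'   (default 0.70).
#' @param stratify Balance the split across FHP levels (default `TRUE`).
#' @param seed Integer seed for the random allocation.
#' @return List with data frames `train` and `eval`; a disjoint, exhaustive
#'   partition of `records`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' sp <- split_cohort(cohort, 0.70, seed = 7)
#' c(nrow(sp$train), nrow(sp$eval))
split_cohort <- function(records, train_fraction = 0.70, stratify = TRUE,
                         seed = 1L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) stop("cannot split an empty cohort", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_eval <- floor((1 - train_fraction) * n)
  lev <- if ("known_level" %in% names(records) &&
             !all(is.na(records$known_level))) {
    records$known_level
  } else {
    classify_fnta(records$fnta)
  }
  eval_idx <- withr::with_seed(seed, {
    if (!stratify || n_eval == 0L) {
      sort(sample.int(n, n_eval))
    } else {
      counts <- table(factor(lev, levels = sort(unique(lev))))
      quota <- n_eval * as.numeric(counts) / n
      take <- floor(quota)
      rem <- n_eval - sum(take)
      if (rem > 0) {
        extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      idx <- unlist(lapply(seq_along(counts), function(i) {
        pool <- which(lev == as.numeric(names(counts))[i])
        if (take[i] == 0L) integer() else sample(pool, take[i])
      }))
      sort(idx)
    }
  })
  list(train = records[setdiff(seq_len(n), eval_idx), , drop = FALSE],
       eval = records[eval_idx, , drop = FALSE])
}

#' Write / read a cohort table
#'
#' Comma-delimited UTF-8 text with header
#' `participant_id,fnta,CSA,...,TK,known_level`; `known_level` is empty when
#' unknown. `write_cohort()` prepends `#`-prefixed provenance comments
#' (package version, seed when available); `read_cohort()` skips them.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @param provenance Optional named character vector of extra provenance
#'   fields to embed.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path, provenance = NULL) {
  meta <- c(package = paste0("fhpdiag ", as.character(utils::packageVersion("fhpdiag"))),
            seed = if (!is.null(attr(cohort, "seed")))
              as.character(attr(cohort, "seed")) else NULL,
            provenance)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con, sep = "\n")
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "", eol = "\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", na.strings = c("", "NA"))
  need <- c("participant_id", "fnta", fhp_parameters())
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}
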
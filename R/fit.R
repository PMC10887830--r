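#' Fit a linear boundary between two adjacent FHP level groups
#'
#' Two-class Fisher linear discriminant with equal priors and pooled
#' within-group covariance in the (parameter, FNTA) plane. The boundary is the
#' locus of equal discriminant scores,
#' `w' z = w' (m_low + m_high) / 2` with `w = S^-1 (m_high - m_low)`,
#' rewritten as `0 = K + L1 * X + L2 * Y` and sign-normalized so `L2 < 0`
#' (the higher level then lies on the positive-FNTA side). The parameter-axis
#' range is set to the observed range of the pooled points.
#'
#' @param points_low,points_high Two-column matrices or data frames
#'   (`x` = parameter, `fnta`), at least two rows each; `points_low` is the
#'   lower of the two adjacent levels.
#' @param separates Integer pair of the adjacent levels the boundary
#'   separates.
#' @return A [boundary_line()].
#' @export
#' @examples
#' lo <- cbind(x = rnorm(50), fnta = rnorm(50, 8, 2))
#' hi <- cbind(x = rnorm(50), fnta = rnorm(50, 17, 2))
#' fit_boundary(lo, hi, separates = c(0, 1))
fit_boundary <- function(points_low, points_high, separates = c(0L, 1L)) {
  as_mat <- function(p, nm) {
    p <- as.matrix(as.data.frame(p))
    if (ncol(p) != 2L || !is.numeric(p) || anyNA(p)) {
      stop("`", nm, "` must be a numeric two-column (x, fnta) table",
           call. = FALSE)
    }
    if (nrow(p) < 2L) {
      stop("`", nm, "` needs at least 2 points", call. = FALSE)
    }
    unname(p)
  }
  lo <- as_mat(points_low, "points_low")
  hi <- as_mat(points_high, "points_high")
  m_lo <- colMeans(lo)
  m_hi <- colMeans(hi)
  n_lo <- nrow(lo)
  n_hi <- nrow(hi)
  pooled <- ((n_lo - 1) * stats::cov(lo) + (n_hi - 1) * stats::cov(hi)) /
    (n_lo + n_hi - 2)
  w <- tryCatch(solve(pooled, m_hi - m_lo), error = function(e) {
    stop("degenerate fit: pooled within-group covariance is singular (",
         conditionMessage(e), ")", call. = FALSE)
  })
  if (!all(is.finite(w))) {
    stop("degenerate fit: nonfinite discriminant direction", call. = FALSE)
  }
  k <- -sum(w * (m_lo + m_hi) / 2)
  l1 <- w[1L]
  l2 <- w[2L]
  if (l2 == 0) {
    stop("degenerate fit: boundary is vertical in the FNTA axis",
         call. = FALSE)
  }
  if (l2 > 0) {
    k <- -k; l1 <- -l1; l2 <- -l2
  }
  xs <- c(lo[, 1L], hi[, 1L])
  boundary_line(k, l1, l2, min(xs), max(xs), separates = separates)
}

#' Fit one parameter's diagnostic model from a labelled cohort
#'
#' Fits the three boundaries on adjacent level pairs (0 vs 1, 1 vs 2, 2 vs 3)
#' in the (parameter, FNTA) plane using [fit_boundary()]. All three lines
#' share the parameter range observed over the whole training cohort. The
#' blue < pink < red ordering is enforced; a violation raises an error rather
#' than silently reordering.
#'
#' @param train Cohort data frame (see [generate_cohort()]) with columns
#'   `fnta`, the parameter, and `known_level` covering all four levels.
#' @param parameter One of [fhp_parameters()].
#' @return An `"fhp_model"`.
#' @export
fit_diagnostic_model <- function(train, parameter) {
  train <- as.data.frame(train)
  if (!parameter %in% fhp_parameters()) {
    stop("`parameter` must be one of ", paste(fhp_parameters(), collapse = ", "),
         call. = FALSE)
  }
  need <- c("fnta", parameter, "known_level")
  miss <- setdiff(need, names(train))
  if (length(miss)) {
    stop("training cohort lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lv <- train$known_level
  absent <- setdiff(0:3, unique(lv))
  if (length(absent)) {
    stop("training cohort has no participants at level ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pts <- function(l) cbind(x = train[[parameter]][lv == l],
                           fnta = train$fnta[lv == l])
  xr <- range(train[[parameter]])
  fit_pair <- function(l) {
    ln <- fit_boundary(pts(l), pts(l + 1L), separates = c(l, l + 1L))
    # common plotting/ambiguity range across the whole cohort
    boundary_line(ln$k, ln$l1, ln$l2, xr[1L], xr[2L],
                  separates = c(l, l + 1L))
  }
  diagnostic_model(parameter,
                   blue = fit_pair(0L),
                   pink = fit_pair(1L),
                   red = fit_pair(2L))
}

#' Fit the full eight-model bank from a labelled cohort
#'
#' @inheritParams fit_diagnostic_model
#' @param thresholds Screening cutoffs stored alongside the models.
#' @return An `"fhp_model_bank"`.
#' @export
fit_model_bank <- function(train, thresholds = .fhp_default_thresholds) {
  models <- lapply(fhp_parameters(), function(p) fit_diagnostic_model(train, p))
  names(models) <- fhp_parameters()
  model_bank(models, thresholds = thresholds)
}
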
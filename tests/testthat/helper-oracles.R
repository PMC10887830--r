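# Independent oracles used across tests.

# Brute-force candidate-level oracle: sweep the parameter axis over a fine
# grid, classify (x, fnta) against each boundary by strict comparison with the
# line's FNTA at x, and union the per-x level assignments. Grid points where
# the FNTA equals a boundary exactly contribute nothing (measure-zero locus).
oracle_candidate_levels <- function(model, fnta, n_grid = 4001L) {
  eff <- function(ln, which) {
    if (which == "lo") ln$eff_x_min %||% ln$x_min else ln$eff_x_max %||% ln$x_max
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  lo <- max(vapply(model$lines, eff, 0, which = "lo"))
  hi <- min(vapply(model$lines, eff, 0, which = "hi"))
  xs <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(model$lines, boundary_fnta_at, numeric(n_grid), x = xs)
  ok <- rowSums(ys == fnta) == 0
  sort(unique(rowSums(ys[ok, , drop = FALSE] < fnta)))
}

# Closed-form mean of N(mu, sd) truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

# A bank of eight models whose boundaries are horizontal FNTA lines, i.e.
# voting collapses to pure threshold classification. `blue` may be a vector
# of 8 per-model constants to stagger the first boundary.
make_horizontal_bank <- function(blue = 12, pink = 25, red = 40) {
  blue <- rep_len(blue, 8L)
  models <- lapply(seq_along(fhp_parameters()), function(i) {
    hl <- function(v, sep) boundary_line(v, 0, -1, -50, 50, separates = sep)
    diagnostic_model(fhp_parameters()[i],
                     blue = hl(blue[i], c(0, 1)),
                     pink = hl(pink, c(1, 2)),
                     red = hl(red, c(2, 3)))
  })
  names(models) <- fhp_parameters()
  model_bank(models)
}

# Low-noise variant of the default cohort spec: per-level SDs shrunk by a
# factor, used to probe where fitted discriminants converge.
shrunk_cohort_spec <- function(factor = 0.1, n = rep(200L, 4L), seed = 42L) {
  spec <- default_cohort_spec(n = n, seed = seed)
  spec$levels <- lapply(spec$levels, function(ld) {
    level_distribution(ld$level, ld$fnta_mean, ld$fnta_sd * factor,
                       ld$param_means, ld$param_sds * factor, ld$n)
  })
  spec
}
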
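test_that("symmetric groups produce the FNTA midline as boundary", {
  withr::with_seed(42, {
    lo <- cbind(x = rnorm(2000), fnta = rnorm(2000, -1))
    hi <- cbind(x = rnorm(2000), fnta = rnorm(2000, 1))
  })
  ln <- fit_boundary(lo, hi, separates = c(0, 1))
  xs <- seq(ln$x_min, ln$x_max, length.out = 50)
  expect_true(all(abs(boundary_fnta_at(ln, xs)) < 0.05))
  expect_lt(ln$l2, 0)
})

test_that("groups separated only in FNTA give the midpoint boundary", {
  withr::with_seed(42, {
    lo <- cbind(x = rnorm(500, 10, 3), fnta = rnorm(500, 8, 2))
    hi <- cbind(x = rnorm(500, 10, 3), fnta = rnorm(500, 18, 2))
  })
  ln <- fit_boundary(lo, hi, separates = c(0, 1))
  mid <- mean(c(mean(lo[, 2]), mean(hi[, 2])))
  expect_equal(boundary_fnta_at(ln, 10), mid, tolerance = 0.02)
  expect_lt(abs(ln$l1 / ln$l2), 0.05)  # near-horizontal
})

test_that("degenerate inputs are rejected", {
  same <- cbind(x = rep(1, 5), fnta = rep(2, 5))
  expect_error(fit_boundary(same, same + 1), "singular|degenerate")
  expect_error(fit_boundary(cbind(1, 2), cbind(x = rnorm(5), fnta = rnorm(5))),
               "at least 2")
})

test_that("the fitted discriminant agrees with an independent LDA oracle", {
  skip_if_not_installed("MASS")
  withr::with_seed(42, {
    lo <- data.frame(x = rnorm(300, 20, 8), fnta = rnorm(300, 9, 4))
    hi <- data.frame(x = rnorm(300, 24, 8), fnta = rnorm(300, 17, 4))
    test_pts <- data.frame(x = runif(500, -5, 45), fnta = runif(500, 0, 28))
  })
  ln <- fit_boundary(lo, hi, separates = c(0, 1))
  fit <- MASS::lda(grp ~ x + fnta,
                   data = rbind(cbind(lo, grp = 0), cbind(hi, grp = 1)),
                   prior = c(0.5, 0.5))
  ours <- ln$k + ln$l1 * test_pts$x + ln$l2 * test_pts$fnta
  # establish which sign corresponds to the high group via its mean
  hi_sign <- sign(ln$k + ln$l1 * mean(hi$x) + ln$l2 * mean(hi$fnta))
  ours_class <- as.integer(sign(ours) == hi_sign)
  lda_class <- as.integer(predict(fit, test_pts)$class == "1")
  expect_equal(ours_class, lda_class)
})

test_that("boundaries fitted on the default cohort lie between class means", {
  cohort <- generate_cohort(default_cohort_spec(seed = 42))
  pts <- function(l) cbind(x = cohort$CSA[cohort$known_level == l],
                           fnta = cohort$fnta[cohort$known_level == l])
  ln <- fit_boundary(pts(0), pts(1), separates = c(0, 1))
  rng <- boundary_fnta_range(ln)
  expect_gt(rng[1], 8.61)
  expect_lt(rng[2], 17.25)
})

test_that("model fitting requires all four levels and keeps the line order", {
  cohort <- generate_cohort(default_cohort_spec(seed = 42))
  expect_error(fit_diagnostic_model(cohort[cohort$known_level != 2, ], "CSA"),
               "level 2")
  for (seed in c(1, 7, 23)) {
    cohort <- generate_cohort(default_cohort_spec(seed = seed))
    bank <- fit_model_bank(split_cohort(cohort, 0.7, seed = seed)$train)
    for (p in fhp_parameters()) {
      m <- bank$models[[p]]
      xmid <- mean(c(m$lines$blue$x_min, m$lines$blue$x_max))
      ys <- vapply(m$lines, boundary_fnta_at, 0, x = xmid)
      expect_true(!is.unsorted(ys, strictly = TRUE),
                  info = paste("seed", seed, p))
    }
  }
})
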
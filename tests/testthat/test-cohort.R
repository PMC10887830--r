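test_that("an all-zero-count spec yields an empty, well-formed cohort", {
  spec <- default_cohort_spec(n = c(0L, 0L, 0L, 0L), seed = 1)
  cohort <- generate_cohort(spec)
  expect_identical(nrow(cohort), 0L)
  expect_true(all(c("participant_id", "fnta", fhp_parameters(),
                    "known_level") %in% names(cohort)))
})

test_that("generation is a deterministic function of the spec and seed", {
  spec <- default_cohort_spec(seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(default_cohort_spec(seed = 43))))
  # the caller's RNG stream is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_cohort(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("truncated FNTA draws match the closed-form truncated-normal mean", {
  spec <- default_cohort_spec(n = c(0L, 10000L, 0L, 0L), seed = 42)
  cohort <- generate_cohort(spec)
  expect_true(all(cohort$known_level == 1L))
  expect_true(all(cohort$fnta >= 12 & cohort$fnta < 25))
  expect_equal(mean(cohort$fnta), truncnorm_mean(17.25, 3.82, 12, 25),
               tolerance = 0.2 / truncnorm_mean(17.25, 3.82, 12, 25))
})

test_that("untruncated draws recover the configured moments", {
  spec <- default_cohort_spec(n = rep(5000L, 4L), seed = 42)
  spec$truncate_fnta_to_level_range <- FALSE
  cohort <- generate_cohort(spec)
  # 72 simultaneous moment checks (9 variables x 4 levels, mean and SD):
  # bound each z-score at the 1% family-wise normal quantile rather than a
  # fixed per-check multiple
  z_max <- qnorm(1 - 0.01 / 2 / 72)
  for (ld in spec$levels) {
    sub <- cohort[cohort$known_level == ld$level, ]
    n <- nrow(sub)
    mus <- c(fnta = ld$fnta_mean, ld$param_means)
    sds <- c(fnta = ld$fnta_sd, ld$param_sds)
    for (v in names(mus)) {
      expect_lt(abs(mean(sub[[v]]) - mus[[v]]), z_max * sds[[v]] / sqrt(n))
      expect_lt(abs(sd(sub[[v]]) - sds[[v]]), z_max * sds[[v]] / sqrt(2 * n))
    }
  }
})

test_that("requested FNTA-parameter correlation is realized; default is zero", {
  spec <- default_cohort_spec(n = c(0L, 5000L, 0L, 0L), seed = 42)
  spec$truncate_fnta_to_level_range <- FALSE
  base <- generate_cohort(spec)
  for (p in c("CSA", "TK")) {
    expect_lt(abs(cor(base$fnta, base[[p]])), 3 / sqrt(nrow(base)))
  }
  spec$correlation_fnta_param <- c(CSA = 0.5)
  corr <- generate_cohort(spec)
  expect_equal(cor(corr$fnta, corr$CSA), 0.5, tolerance = 0.05)
  expect_lt(abs(cor(corr$fnta, corr$TK)), 3 / sqrt(nrow(corr)))
})

test_that("spec validation names the offending field", {
  expect_error(level_distribution(1, 17, -1, setNames(rep(0, 8), fhp_parameters()),
                                  setNames(rep(1, 8), fhp_parameters()), 5),
               "fnta_sd")
  expect_error(level_distribution(1, 17, 1, setNames(rep(0, 7), fhp_parameters()[1:7]),
                                  setNames(rep(1, 8), fhp_parameters()), 5),
               "param_means")
  good <- default_cohort_spec()$levels
  expect_error(cohort_spec(good[c(1, 1, 2, 3)]), "exactly once")
  expect_error(cohort_spec(good, correlation_fnta_param = c(CSA = 1.5)),
               "\\[-1, 1\\]")
  expect_error(cohort_spec(good, correlation_fnta_param = c(bogus = 0.1)),
               "fhp_parameters")
})

test_that("70/30 split of 145 participants yields the study's 102/43 sizes", {
  cohort <- generate_cohort(default_cohort_spec(seed = 1))
  expect_identical(nrow(cohort), 145L)
  sp <- split_cohort(cohort, 0.70, seed = 1)
  expect_identical(nrow(sp$train), 102L)
  expect_identical(nrow(sp$eval), 43L)
})

test_that("splitting partitions the cohort and stratification balances levels", {
  cohort <- generate_cohort(default_cohort_spec(seed = 5))
  sp <- split_cohort(cohort, 0.70, stratify = TRUE, seed = 5)
  expect_identical(sort(c(sp$train$participant_id, sp$eval$participant_id)),
                   sort(cohort$participant_id))
  expect_length(intersect(sp$train$participant_id, sp$eval$participant_id), 0L)
  # per-level eval counts within 1 of the proportional allocation
  n_eval <- nrow(sp$eval)
  for (l in 0:3) {
    expected <- n_eval * sum(cohort$known_level == l) / nrow(cohort)
    expect_lte(abs(sum(sp$eval$known_level == l) - expected), 1)
  }
  # determinism and small-case arithmetic
  sp2 <- split_cohort(cohort, 0.70, stratify = TRUE, seed = 5)
  expect_identical(sp, sp2)
  small <- split_cohort(cohort[1:10, ], 0.5, seed = 2)
  expect_identical(c(nrow(small$train), nrow(small$eval)), c(5L, 5L))
  expect_error(split_cohort(cohort[0, ], 0.7), "empty")
  expect_error(split_cohort(cohort, 1.2), "between 0 and 1")
})

test_that("cohort files round-trip through CSV with provenance comments", {
  cohort <- generate_cohort(default_cohort_spec(n = c(5L, 5L, 5L, 5L),
                                                seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# package: fhpdiag", lines)))
  expect_true(any(grepl("^# seed: 9", lines)))
  back <- read_cohort(path)
  expect_equal(back$fnta, cohort$fnta)
  expect_equal(back$CSA, cohort$CSA)
  expect_identical(back$known_level, cohort$known_level)
})
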
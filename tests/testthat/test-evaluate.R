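test_that("agreement ratio arithmetic and input checks", {
  expect_equal(agreement_ratio(c(0, 1, 2), c(0, 1, 2)), 100)
  expect_equal(agreement_ratio(c(0, 1), c(1, 1)), 50)
  expect_error(agreement_ratio(0:1, 0:2), "equal length")
  expect_error(agreement_ratio(integer(), integer()), "empty")
})

test_that("confusion report matches a brute-force tally on a hand example", {
  pc <- c(0, 0, 1, 2, 2, 3)
  d <- c(0, 1, 1, 2, 1, 3)
  rep <- confusion_report(pc, d, ids = letters[1:6])
  brute <- matrix(0, 4, 4)
  for (i in seq_along(pc)) brute[pc[i] + 1, d[i] + 1] <- brute[pc[i] + 1, d[i] + 1] + 1
  expect_equal(unname(unclass(rep$confusion)), brute)
  expect_equal(sum(rep$confusion), rep$n)
  expect_equal(rep$agreement_ratio, round(100 * 4 / 6, 2))
  expect_equal(rep$agreement_ratio,
               round(100 * sum(diag(rep$confusion)) / rep$n, 2))
  # row sums = PC frequencies, column sums = D frequencies
  expect_equal(unname(rowSums(rep$confusion)),
               as.vector(table(factor(pc, 0:3))))
  expect_equal(unname(colSums(rep$confusion)),
               as.vector(table(factor(d, 0:3))))
  expect_identical(rep$disagreements$participant, c("b", "e"))
})

test_that("rates sum to 100 where defined and are NA on empty margins", {
  rep <- confusion_report(c(0, 0, 1), c(0, 1, 1))
  expect_equal(unname(rep$tpr[1] + rep$fnr[1]), 100)
  expect_equal(unname(rep$ppv[2] + rep$fdr[2]), 100)
  expect_true(all(is.na(rep$tpr[3:4])))   # no screened level 2 or 3
  expect_true(all(is.na(rep$ppv[3:4])))
  perfect <- confusion_report(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(unname(perfect$tpr), rep(100, 4))
  expect_equal(unname(perfect$fdr), rep(0, 4))
  expect_error(confusion_report(c(0, 5), c(0, 1)), "0-3")
})

test_that("correlation table reproduces identity and rank-invariance cases", {
  cohort <- generate_cohort(default_cohort_spec(n = c(15L, 15L, 15L, 15L),
                                                seed = 42))
  cohort$CSA <- cohort$fnta                 # identical
  cohort$CCA <- exp(cohort$fnta / 20)       # strictly monotone, nonlinear
  tab <- correlation_table(cohort)
  expect_identical(tab$parameter, fhp_parameters())
  expect_equal(tab$pearson_r_fnta[tab$parameter == "CSA"], 1)
  expect_equal(tab$spearman_rho_fnta[tab$parameter == "CCA"], 1)
  expect_lt(tab$pearson_r_fnta[tab$parameter == "CCA"], 1)
  expect_true(all(tab$normality_p >= 0 & tab$normality_p <= 1, na.rm = TRUE))
  expect_true(all(abs(unlist(tab[, grepl("rho|_r_", names(tab))])) <= 1))
})

test_that("a constant parameter yields NA correlations with a warning", {
  cohort <- generate_cohort(default_cohort_spec(n = c(5L, 5L, 5L, 5L),
                                                seed = 3))
  cohort$TK <- 5
  expect_warning(tab <- correlation_table(cohort), "constant")
  expect_true(is.na(tab$pearson_r_fnta[tab$parameter == "TK"]))
})

test_that("asymptotic Spearman p agrees with a permutation estimate at n = 50", {
  cohort <- generate_cohort(default_cohort_spec(n = c(13L, 13L, 13L, 11L),
                                                seed = 42))
  tab <- correlation_table(cohort)
  # independent permutation oracle, written out here rather than via the
  # package's own permutation option
  obs <- abs(cor(cohort$CSA, cohort$fnta, method = "spearman"))
  perm <- withr::with_seed(42, vapply(1:10000, function(i) {
    abs(cor(cohort$CSA, sample(cohort$fnta), method = "spearman"))
  }, 0))
  p_perm <- (sum(perm >= obs - 1e-12) + 1) / 10001
  expect_equal(tab$spearman_p_fnta[tab$parameter == "CSA"], p_perm,
               tolerance = 0.02)
  # and the package's own permutation option lands in the same place
  tab_p <- correlation_table(cohort, p_method = "permutation",
                             n_perm = 2000, seed = 1)
  expect_equal(tab_p$spearman_p_fnta[tab_p$parameter == "CSA"], p_perm,
               tolerance = 0.03)
})

test_that("correlations are invariant to admissible rescalings", {
  cohort <- generate_cohort(default_cohort_spec(n = c(10L, 10L, 10L, 10L),
                                                seed = 11))
  tab <- correlation_table(cohort)
  scaled <- cohort
  scaled$CSA <- 3 * scaled$CSA + 7          # positive affine: both invariant
  scaled$TK <- scaled$TK^3                  # monotone: Spearman invariant
  tab2 <- correlation_table(scaled)
  expect_equal(tab2$pearson_r_fnta[1], tab$pearson_r_fnta[1])
  expect_equal(tab2$spearman_rho_fnta[1], tab$spearman_rho_fnta[1])
  expect_equal(tab2$spearman_rho_fnta[8], tab$spearman_rho_fnta[8])
})

test_that("level summary computes n-1 moments and handles sparse levels", {
  cohort <- data.frame(participant_id = c("a", "b", "c"),
                       fnta = c(10, 20, 30))
  for (p in fhp_parameters()) cohort[[p]] <- c(1, 2, 3)
  cohort$known_level <- c(0L, 0L, 1L)
  tab <- level_summary(cohort)
  l0 <- tab[tab$level == 0 & tab$variable == "fnta", ]
  expect_equal(l0$mean, 15)
  expect_equal(l0$sd, sd(c(10, 20)))
  l1 <- tab[tab$level == 1 & tab$variable == "fnta", ]
  expect_equal(l1$mean, 30)
  expect_true(is.na(l1$sd))               # single record: SD undefined
  l3 <- tab[tab$level == 3 & tab$variable == "fnta", ]
  expect_identical(l3$n, 0L)
  expect_true(is.na(l3$mean))
})

test_that("level summary recovers generator moments on a large cohort", {
  spec <- default_cohort_spec(n = rep(2000L, 4L), seed = 42)
  spec$truncate_fnta_to_level_range <- FALSE
  tab <- level_summary(generate_cohort(spec))
  for (ld in spec$levels) {
    row <- tab[tab$level == ld$level & tab$variable == "CSA", ]
    expect_equal(row$mean, ld$param_means[["CSA"]],
                 tolerance = 3 * ld$param_sds[["CSA"]] / sqrt(2000) /
                   abs(ld$param_means[["CSA"]]))
  }
})
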
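test_that("confusion_matrix counts with aneuploid/mosaic positive and drops no_result", {
  ids <- sprintf("s%02d", 1:10)
  truths <- data.frame(sample_id = ids,
                       class = rep(c("aneuploid", "euploid"), c(4, 6)))
  perfect <- data.frame(sample_id = ids, class = truths$class)
  cm <- confusion_matrix(perfect, truths)
  expect_identical(c(cm$TP, cm$FP, cm$TN, cm$FN), c(4L, 0L, 6L, 0L))

  all_pos <- data.frame(sample_id = ids, class = "aneuploid")
  cm <- confusion_matrix(all_pos, truths)
  expect_identical(c(cm$TP, cm$FP), c(4L, 6L))

  one_out <- perfect
  one_out$class[1] <- "no_result"
  cm <- quiet(confusion_matrix(one_out, truths))
  expect_identical(cm$n, 9L)
  expect_identical(cm$n_excluded, 1L)

  bad <- perfect
  bad$sample_id[1] <- "zzz"
  expect_error(confusion_matrix(bad, truths), "same unique sample ids")
})

test_that("diagnostic_metrics reproduces the published SCM/BF arithmetic", {
  # SCM vs ICM/WB reference, 148 embryos
  scm <- diagnostic_metrics(confusion_counts(TP = 43, FP = 20,
                                             TN = 81, FN = 4))
  expect_equal(scm$sensitivity$value, 43 / 47)
  expect_equal(scm$sensitivity$pct, 91.5)
  expect_equal(scm$specificity$pct, 80.2)  # 81/101
  expect_equal(scm$npv$pct, 95.3)          # 81/85
  expect_equal(scm$ppv$pct, 68.3)          # 43/63
  expect_equal(scm$concordance$pct, 83.8)  # 124/148

  bf <- diagnostic_metrics(confusion_counts(TP = 41, FP = 39,
                                            TN = 62, FN = 6))
  expect_equal(bf$specificity$pct, 61.4)   # 62/101
  expect_equal(bf$sensitivity$pct, 87.2)   # 41/47
  expect_equal(bf$npv$pct, 91.2)           # 62/68
  expect_equal(bf$ppv$pct, 51.3)           # 41/80, half-up rounding
  expect_equal(bf$concordance$pct, 69.6)   # 103/148

  perfect <- diagnostic_metrics(confusion_counts(5, 0, 5, 0))
  for (m in c("sensitivity", "specificity", "npv", "ppv", "concordance"))
    expect_equal(perfect[[m]]$value, 1)
  inverted <- diagnostic_metrics(confusion_counts(0, 5, 0, 5))
  for (m in c("sensitivity", "specificity", "npv", "ppv", "concordance"))
    expect_equal(inverted[[m]]$value, 0)

  # zero denominator -> undefined, not zero
  no_pos <- diagnostic_metrics(confusion_counts(0, 0, 10, 0))
  expect_true(is.na(no_pos$sensitivity$value))
  expect_true(is.na(no_pos$ppv$value))
})

test_that("round_half_up matches printed-table display rounding", {
  expect_equal(round_half_up(51.25, 1), 51.3) # round() would give 51.2
  expect_equal(round_half_up(91.489, 1), 91.5)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("pooling subgroup matrices is cellwise, commutative and identity-respecting", {
  icm_scm <- confusion_counts(TP = 27, FP = 9, TN = 51, FN = 2)
  wb_scm <- confusion_counts(TP = 16, FP = 11, TN = 30, FN = 2)
  tot <- pool_matrices(icm_scm, wb_scm)
  expect_identical(c(tot$TP, tot$FP, tot$TN, tot$FN), c(43, 20, 81, 4))
  tot_rev <- pool_matrices(wb_scm, icm_scm)
  expect_identical(tot[c("TP", "FP", "TN", "FN")],
                   tot_rev[c("TP", "FP", "TN", "FN")])
  zero <- confusion_counts(0, 0, 0, 0)
  same <- pool_matrices(icm_scm, zero)
  expect_identical(same[c("TP", "FP", "TN", "FN")],
                   icm_scm[c("TP", "FP", "TN", "FN")])
})

test_that("concordance excludes unevaluable samples and matches published counts", {
  x <- c("euploid", "aneuploid", "euploid")
  expect_equal(concordance(x, x, mode = "ploidy")$fraction, 1)

  # sex concordance 95/96 -> 99.0%
  calls <- c(rep("XX", 95), "XY")
  truths <- rep("XX", 96)
  sc <- concordance(calls, truths, mode = "sex")
  expect_identical(sc$matches, 95L)
  expect_equal(sc$pct, 99.0)

  # pooled sex counts (95+113)/(96+116) = 208/212 -> 98.1%
  calls2 <- c(rep("XY", 113), rep("XX", 3))
  truths2 <- rep("XY", 116)
  pooled_matches <- sc$matches + concordance(calls2, truths2, "sex")$matches
  pooled_n <- sc$evaluable + 116
  expect_identical(pooled_matches, 208L)
  expect_equal(round_half_up(100 * pooled_matches / pooled_n, 1), 98.1)

  # no_result / indeterminate excluded from the denominator
  calls3 <- c("XX", "indeterminate", "XY")
  truths3 <- c("XX", "XX", "XY")
  cc <- quiet(concordance(calls3, truths3, "sex"))
  expect_identical(cc$evaluable, 2L)
  expect_error(quiet(concordance("no_result", "XX", "sex")), "no evaluable")
})

test_that("chi_square_2x2 matches the textbook formula and base R", {
  ident <- chi_square_2x2(10, 10, 10, 10, correct = FALSE)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)

  # oracle: direct sum((O-E)^2/E) with all E = 2.5
  res <- chi_square_2x2(0, 5, 5, 0, correct = FALSE)
  expect_equal(res$statistic, 10)
  expect_equal(res$p, pchisq(10, 1, lower.tail = FALSE))

  # cross-check both conventions against the independent base implementation
  for (correct in c(TRUE, FALSE)) {
    mine <- chi_square_2x2(81, 20, 62, 39, correct = correct)
    ref <- suppressWarnings(
      stats::chisq.test(rbind(c(81, 20), c(62, 39)), correct = correct))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-9)
  }

  # invariance under row and column swaps
  a <- chi_square_2x2(81, 20, 62, 39)
  expect_equal(a$statistic, chi_square_2x2(62, 39, 81, 20)$statistic)
  expect_equal(a$statistic, chi_square_2x2(20, 81, 39, 62)$statistic)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("diagnostic_report scores assays per reference subgroup", {
  samples <- read.csv(fixture_path("cohort148_samples.csv"))
  truth <- data.frame(sample_id = samples$sample_id, class = samples$truth,
                      reference = samples$reference)
  sheets <- list(
    SCM = data.frame(sample_id = samples$sample_id,
                     class = samples$scm_call),
    BF = data.frame(sample_id = samples$sample_id,
                    class = samples$bf_call))
  rep <- diagnostic_report(sheets, truth)
  expect_equal(rep$metrics$total$SCM$specificity$pct, 80.2)
  expect_equal(rep$metrics$total$BF$specificity$pct, 61.4)
  expect_equal(rep$metrics$ICM$SCM$sensitivity$pct, 93.1) # 27/29
  expect_equal(rep$metrics$WB$BF$npv$pct, 92.9)           # 26/28
  expect_true(rep$comparisons$total$specificity < 0.05)
  expect_true(rep$comparisons$total$sensitivity > 0.05)
})
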
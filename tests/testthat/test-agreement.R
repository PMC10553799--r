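test_that("spearman correlation matches a rank-then-pearson oracle", {
  set.seed(3)
  x <- rnorm(50)
  expect_equal(spearman_rho(x, exp(x)), 1.0)
  expect_equal(spearman_rho(x, -x), -1.0)
  xt <- sample(1:8, 30, replace = TRUE) # ties
  yt <- sample(1:5, 30, replace = TRUE)
  expect_equal(spearman_rho(xt, yt), oracle_spearman(xt, yt), tolerance = 1e-12)
  expect_equal(spearman_rho(xt, yt), spearman_rho(yt, xt))
  expect_true(is.na(spearman_rho(rep(1, 10), rnorm(10))))
  expect_error(spearman_rho(c(1, 2), c(3, 4)), "degenerate")
  # pairs with a missing member are dropped first
  xm <- c(x, NA); ym <- c(exp(x), 5)
  expect_equal(spearman_rho(xm, ym), 1.0)
})

test_that("decile cross-tab counts every tract exactly once", {
  empty <- handmade_records()[0, ]
  expect_true(all(decile_crosstab(empty) == 0))

  diag_rec <- handmade_records()
  diag_rec$svi_decile <- diag_rec$adi_decile
  ct <- decile_crosstab(diag_rec)
  expect_true(all(ct[row(ct) != col(ct)] == 0))
  expect_equal(sum(diag(ct)), nrow(diag_rec))

  set.seed(4)
  rec <- data.frame(adi_decile = sample(1:10, 1000, replace = TRUE),
                    svi_decile = sample(1:10, 1000, replace = TRUE))
  ct2 <- decile_crosstab(rec)
  expect_equal(unname(ct2), oracle_crosstab(rec$adi_decile, rec$svi_decile))
  expect_equal(sum(ct2), 1000)
  expect_equal(unname(rowSums(ct2)),
               as.vector(table(factor(rec$adi_decile, levels = 1:10))))
  expect_equal(unname(colSums(ct2)),
               as.vector(table(factor(rec$svi_decile, levels = 1:10))))
})

test_that("agreement classes partition tracts at the stated thresholds", {
  rec <- data.frame(adi_decile = rep(10L, 10), svi_decile = 10L - 0:9)
  rec$delta <- abs(rec$adi_decile - rec$svi_decile)
  cls <- classify_agreement(rec)$agreement_class
  expect_equal(cls[rec$delta <= 1], rep("good", 2))
  expect_equal(cls[rec$delta >= 6], rep("poor", 4))
  expect_equal(cls[rec$delta %in% 2:5], rep("intermediate", 4))
  expect_error(agreement_thresholds(3, 3), "config")
  expect_error(agreement_thresholds(-1, 6), "config")
  # class partition property
  r <- classify_agreement(handmade_records())
  expect_equal(sum(table(r$agreement_class)), nrow(r))
})

test_that("agreement summary reports shares and both correlations on one tract set", {
  rec <- handmade_records()
  rec$delta <- abs(rec$adi_decile - rec$svi_decile)
  rec <- classify_agreement(rec)
  s <- agreement_summary(rec)
  expect_equal(s$n_total, 10)
  expect_equal(s$share_good, 6 / 10)
  expect_equal(s$share_poor, 3 / 10)
  expect_equal(s$rho_continuous, oracle_spearman(rec$adi_value, rec$svi_value))
  expect_equal(s$rho_decile, oracle_spearman(rec$adi_decile, rec$svi_decile))

  all_same <- rec
  all_same$svi_decile <- all_same$adi_decile
  all_same$svi_value <- all_same$adi_value / 100
  all_same$delta <- 0L
  s2 <- agreement_summary(classify_agreement(all_same))
  expect_equal(s2$share_good, 1.0)
  expect_equal(s2$share_poor, 0.0)
})

test_that("continuous and decile correlations nearly coincide without a confound", {
  res <- run_agreement(mechanism_params(0, seed = 2),
                       adi_reference_coefficients(mechanism_params(0, seed = 2)))
  s <- agreement_summary(res$records)
  expect_lt(abs(s$rho_continuous - s$rho_decile), 0.02)
})

test_that("the eight comparison groups reproduce a hand computation", {
  rec <- handmade_records()
  rec$delta <- abs(rec$adi_decile - rec$svi_decile)
  rec <- classify_agreement(rec)
  cmp <- build_comparisons(rec)
  expect_equal(nrow(cmp), 8)
  expect_equal(cmp$label, c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b"))

  # Comparison I anchors T1, T2, T8 (ADI decile 10)
  i_good <- cmp[cmp$label == "1a", ]
  expect_equal(i_good$n_anchor, 3)
  expect_equal(i_good$n_subgroup, 2) # T1, T8
  expect_equal(i_good$share, 2 / 3)
  expect_equal(i_good$mean_adi, mean(c(95, 99)))
  expect_equal(i_good$mean_svi_x100, mean(c(97, 99)))
  expect_equal(i_good$abs_difference, abs(97 - 98))
  i_poor <- cmp[cmp$label == "1b", ]
  expect_equal(i_poor$n_subgroup, 1) # T2
  expect_equal(i_poor$mean_adi, 91)
  expect_equal(i_poor$mean_svi_x100, 30)
  expect_equal(i_poor$abs_difference, 61)

  # Comparison III anchors T5, T9 (ADI decile 1): good T5, poor T9
  expect_equal(cmp[cmp$label == "3a", ]$n_subgroup, 1)
  expect_equal(cmp[cmp$label == "3b", ]$n_subgroup, 1)
  expect_equal(cmp[cmp$label == "3b", ]$mean_svi_x100, 70)

  # empty subgroup rows carry n = 0 and missing means
  rec2 <- rec[rec$agreement_class != "poor", ]
  cmp2 <- build_comparisons(rec2)
  expect_equal(cmp2[cmp2$label == "1b", ]$n_subgroup, 0)
  expect_true(is.na(cmp2[cmp2$label == "1b", ]$mean_adi))

  # anchor-set consistency forced by the delta arithmetic
  res <- run_agreement(mechanism_params(2, seed = 1),
                       adi_reference_coefficients(mechanism_params(2, seed = 1)))
  r <- res$records
  in_I <- r[r$adi_decile == 10, ]
  expect_true(all(in_I$svi_decile[in_I$agreement_class == "good"] %in% 9:10))
  expect_true(all(in_I$svi_decile[in_I$agreement_class == "poor"] <= 4))
})

test_that("swapping the indices transposes the cross-tab and mirrors comparisons", {
  rec <- classify_agreement(handmade_records())
  swapped <- rec
  swapped$adi_value <- rec$svi_value * 100
  swapped$svi_value <- rec$adi_value / 100
  swapped$adi_decile <- rec$svi_decile
  swapped$svi_decile <- rec$adi_decile
  expect_equal(decile_crosstab(swapped), t(decile_crosstab(rec)),
               ignore_attr = TRUE)
  cmp <- build_comparisons(rec)
  cmp_sw <- build_comparisons(swapped)
  expect_equal(cmp_sw[cmp_sw$label == "2a", ]$n_subgroup,
               cmp[cmp$label == "1a", ]$n_subgroup)
  expect_equal(cmp_sw[cmp_sw$label == "4b", ]$n_subgroup,
               cmp[cmp$label == "3b", ]$n_subgroup)
})

test_that("state summaries reconcile with the national counts", {
  rec <- classify_agreement(handmade_records())
  by_state <- summarize_by_state(rec)
  expect_equal(sum(by_state$n_total), nrow(rec))
  expect_equal(sum(by_state$n_good), sum(rec$agreement_class == "good"))
  expect_equal(sum(by_state$n_poor), sum(rec$agreement_class == "poor"))
  # group-by oracle
  for (s in by_state$state_code) {
    sub <- rec[rec$state_code == s, ]
    expect_equal(by_state$n_good[by_state$state_code == s],
                 sum(sub$agreement_class == "good"))
  }
  one_state <- rec
  one_state$state_code <- "S01"
  bs1 <- summarize_by_state(one_state)
  expect_equal(nrow(bs1), 1)
  expect_equal(bs1$n_good, sum(rec$agreement_class == "good"))
})

test_that("marginal decile counts diagnostic matches direct tabulation", {
  rec <- handmade_records()
  m <- decile_margin_counts(rec, "ADI", 10L)
  expect_equal(sum(m), sum(rec$adi_decile == 10))
  expect_equal(m[3], 1L) # T2: svi decile 3
  expect_equal(m[10], 2L)
})
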
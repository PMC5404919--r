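test_that("ROC handles perfect separation and pure overlap", {
  labs <- c(rep("control", 3), rep("case", 3))
  r <- roc_curve(c(10, 9, 8, 1, 2, 3), labs, direction = "low_is_positive")
  expect_equal(r$auc, 1.0)
  expect_equal(youden_cutoff(r)$youden_j, 1.0)

  r2 <- roc_curve(c(5, 5, 5, 5, 5, 5), labs)
  expect_equal(r2$auc, 0.5)

  expect_error(roc_curve(1:5, rep("case", 5)), "two classes")
})

test_that("trapezoid AUC equals the all-pairs Mann-Whitney oracle with ties", {
  set.seed(101)
  for (rep in 1:25) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    # integer-valued draws guarantee ties
    v <- c(round(rnorm(n1, 6, 2)), round(rnorm(n2, 8, 2)))
    labs <- c(rep("control", n1), rep("case", n2))
    for (dir in c("high_is_positive", "low_is_positive")) {
      r <- roc_curve(v, labs, direction = dir)
      expect_equal(r$auc, oracle_auc(v, labs, "case", dir), tolerance = 1e-9)
    }
  }
})

test_that("AUC is invariant under monotone transforms and flips with direction", {
  set.seed(55)
  v <- rnorm(30, 5, 2)
  labs <- rep(c("control", "case"), 15)
  r <- roc_curve(v, labs, direction = "high_is_positive")
  r_exp <- roc_curve(exp(v), labs, direction = "high_is_positive")
  expect_equal(r_exp$auc, r$auc, tolerance = 1e-12)
  r_flip <- roc_curve(v, labs, direction = "low_is_positive")
  expect_equal(r_flip$auc, 1 - r$auc, tolerance = 1e-12)
})

test_that("AUC matches pROC on a random instance", {
  set.seed(77)
  v <- c(rnorm(20, 0), rnorm(20, 1))
  labs <- c(rep("control", 20), rep("case", 20))
  r <- roc_curve(v, labs, direction = "high_is_positive")
  ref <- pROC::roc(response = labs, predictor = v, levels = c("control", "case"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("Youden cutoff equals the exhaustive-scan oracle", {
  set.seed(202)
  for (rep in 1:25) {
    n1 <- sample(4:15, 1); n2 <- sample(4:15, 1)
    v <- c(round(rnorm(n1, 6, 2)), round(rnorm(n2, 9, 2)))
    labs <- c(rep("control", n1), rep("case", n2))
    r <- roc_curve(v, labs, direction = "high_is_positive")
    y <- youden_cutoff(r)
    o <- oracle_youden(v, labs, "case", "high_is_positive")
    expect_equal(y$youden_j, o$j, tolerance = 1e-12)
    expect_equal(y$optimal_cutoff, o$cutoff, tolerance = 1e-12)
    expect_equal(y$accuracy, o$acc, tolerance = 1e-12)
    # J = sensitivity + specificity - 1 at every operating point
    expect_equal(max(r$sensitivity + r$specificity - 1), y$youden_j,
                 tolerance = 1e-12)
  }
})

test_that("accuracy and occupancy formulas give the printed spot values", {
  expect_equal(accuracy_from_counts(9, 2, 8, 1), 0.85)
  expect_equal(hippocampal_occupancy(3, 1), 0.75)
  expect_equal(hippocampal_occupancy(5, 0), 1.0)
  expect_equal(hippocampal_occupancy(0, 4), 0.0)
  expect_error(hippocampal_occupancy(0, 0), "zero")
  expect_error(hippocampal_occupancy(-1, 2), ">= 0")
})

test_that("ratio biomarkers divide per subject and guard the denominator", {
  tab <- data.frame(subject_id = c("s1", "s2", "s3"),
                    tau = c(600, 0, 450), NPTX2 = c(300, 250, 0))
  expect_equal(ratio_biomarker(tab[1:2, ], "tau", "NPTX2")$tau_over_NPTX2,
               c(2.0, 0.0))
  expect_error(ratio_biomarker(tab, "tau", "NPTX2"), "s3")
})

test_that("Pearson correlation matches the product-moment formula", {
  tab <- data.frame(x = 1:5, y = 2 * (1:5) + 1, yneg = -(1:5),
                    y2 = c(2, 1, 4, 3, 5), const = rep(1, 5))
  expect_equal(correlate(tab, "x", "y")$pearson_r, 1.0)
  expect_equal(correlate(tab, "x", "yneg")$pearson_r, -1.0)
  r <- correlate(tab, "x", "y2")
  expect_equal(r$pearson_r, 0.8)
  expect_equal(r$n, 5)
  # p from the t transform with n - 2 df
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(r$p_value, 2 * pt(-tstat, df = 3), tolerance = 1e-12)
  expect_error(correlate(tab, "x", "const"), "zero variance")
  expect_error(correlate(tab[1:2, ], "x", "y2"), ">= 3")
})

test_that("correlation tables use pairwise-complete observations", {
  tab <- data.frame(
    A = c(1, 2, 3, 4, NA, 6), B = c(2, 4, 5, 8, 10, NA),
    S = c(1.5, 2, 3.5, 4, 5, 6)
  )
  ct <- correlation_table(tab, c("A", "B"), "S", adjust = TRUE)
  expect_equal(ct$n, c(5, 5))
  expect_equal(ct$p_bh, p.adjust(ct$p_value, "BH"))
})

test_that("two-group t test and ANOVA behave at the edges", {
  tab <- data.frame(group = rep(c("control", "case"), each = 4),
                    A = c(1, 2, 3, 4, 1, 2, 3, 4))
  gc <- group_compare(tab, "A")
  expect_equal(gc$t_statistic, 0)
  expect_equal(gc$p_two_sided, 1)

  const <- data.frame(group = rep(c("control", "case"), each = 3),
                      A = c(5, 5, 5, 9, 9, 9))
  gc2 <- group_compare(const, "A")
  expect_true(gc2$degenerate)
  expect_equal(gc2$p_two_sided, 0)

  av <- one_way_anova(c(rnorm(5), rnorm(5, 3), rnorm(5, 6)),
                      rep(1:3, each = 5))
  expect_true(av$F_statistic > 0 && av$p_value <= 1)
  expect_error(one_way_anova(1:4, c(1, 1, 2, 3)), ">= 2")
})

test_that("the synthetic cohort separates groups as strongly as reported", {
  coh <- generate_cohort(cohort_config(seed = 9))
  r <- roc_curve(coh$NPTX2, coh$group)
  expect_equal(r$direction, "low_is_positive")  # NPTX2 falls in disease
  expect_gt(r$auc, 0.9)
  expect_lt(group_compare(coh, "NPTX2")$p_two_sided, 0.001)
  rat <- ratio_biomarker(coh, "tau", "NPTX2")
  r2 <- roc_curve(rat$tau_over_NPTX2, rat$group)
  expect_gte(r2$auc, r$auc - 0.05)  # ratio marker performs comparably or better
})
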
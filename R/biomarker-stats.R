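#' @importFrom stats cor.test t.test oneway.test median mad
NULL

#' ROC curve of an analyte against a binary diagnosis
#'
#' Operating points are taken at midpoints between consecutive distinct
#' analyte values (plus infinite endpoints), plotting sensitivity (true
#' positive rate) against 1 - specificity. The AUC is computed by the
#' trapezoid rule and equals the Mann-Whitney statistic U/(n1*n2) with
#' ties counted 1/2. Some markers fall in disease (NPTX2) and some
#' rise (tau): `direction = "auto"` orients the curve so AUC >= 0.5 and
#' records the orientation used.
#'
#' @param values Numeric analyte values, one per subject.
#' @param labels Group labels with exactly two classes.
#' @param positive The label of the positive (case) class (default
#'   `"case"`).
#' @param direction `"auto"`, `"high_is_positive"` (call positive when
#'   value >= cutoff) or `"low_is_positive"` (positive when value <=
#'   cutoff).
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(10, 9, 8, 1, 2, 3),
#'                c(rep("control", 3), rep("case", 3)),
#'                direction = "low_is_positive")
#' r$auc
roc_curve <- function(values, labels, positive = "case",
                      direction = c("auto", "high_is_positive",
                                    "low_is_positive")) {
  direction <- match.arg(direction)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.character(labels)[ok]
  classes <- unique(labels)
  if (length(classes) != 2 || !positive %in% classes) {
    stop("labels: need exactly two classes including the positive class",
         call. = FALSE)
  }
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  v <- sort(unique(values))
  thr <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else NULL, Inf)

  build <- function(dir) {
    if (dir == "high_is_positive") {
      sens <- vapply(thr, function(c0) mean(values[pos] >= c0), numeric(1))
      spec <- vapply(thr, function(c0) mean(values[!pos] < c0), numeric(1))
    } else {
      sens <- vapply(thr, function(c0) mean(values[pos] <= c0), numeric(1))
      spec <- vapply(thr, function(c0) mean(values[!pos] > c0), numeric(1))
    }
    fpr <- 1 - spec
    ord <- order(fpr, sens)
    auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
    list(sens = sens, spec = spec, auc = auc)
  }

  if (direction == "auto") {
    hi <- build("high_is_positive")
    direction <- if (hi$auc >= 0.5) "high_is_positive" else "low_is_positive"
  }
  b <- build(direction)
  structure(
    list(thresholds = thr, sensitivity = b$sens, specificity = b$spec,
         auc = b$auc, direction = direction, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' Youden-index optimal cutoff and accuracy
#'
#' Selects the operating point maximizing the Youden index
#' J = sensitivity + specificity - 1; ties are broken by higher
#' accuracy, then by lower cutoff. Accuracy is
#' (TP + TN) / (TP + FP + TN + FN) at the chosen cutoff.
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return List with `optimal_cutoff`, `youden_j`, `accuracy`,
#'   `sensitivity` and `specificity` at the cutoff.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  acc <- (roc$sensitivity * roc$n_pos + roc$specificity * roc$n_neg) /
    (roc$n_pos + roc$n_neg)
  # snap to a grid far below any real difference (counts are rational
  # with denominators <= n) so float noise cannot break tie-handling
  ord <- order(-round(j, 10), -round(acc, 10), roc$thresholds)
  k <- ord[1]
  list(
    optimal_cutoff = roc$thresholds[k],
    youden_j = j[k],
    accuracy = acc[k],
    sensitivity = roc$sensitivity[k],
    specificity = roc$specificity[k]
  )
}

#' Diagnostic accuracy from a confusion matrix
#'
#' @param tp,fp,tn,fn True/false positive/negative counts.
#' @return `(tp + tn) / (tp + fp + tn + fn)`.
#' @export
#' @examples
#' accuracy_from_counts(9, 2, 8, 1)  # 0.85
accuracy_from_counts <- function(tp, fp, tn, fn) {
  (tp + tn) / (tp + fp + tn + fn)
}

#' Ratio biomarker
#'
#' Appends a derived analyte `numerator/denominator` per subject (e.g.
#' tau/NPTX2, whose diagnostic performance exceeds either marker
#' alone).
#'
#' @param table Cohort data frame with a `subject_id` column.
#' @param numerator,denominator Analyte column names.
#' @param name Name of the new column (default
#'   `"<numerator>_over_<denominator>"`).
#' @return The table with the ratio column appended.
#' @export
ratio_biomarker <- function(table, numerator, denominator,
                            name = paste0(numerator, "_over_", denominator)) {
  stopifnot(numerator %in% names(table), denominator %in% names(table))
  den <- table[[denominator]]
  bad <- which(!is.na(den) & den <= 0)
  if (length(bad)) {
    stop(sprintf("denominator %s <= 0 for subject(s): %s", denominator,
                 paste(table$subject_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  table[[name]] <- table[[numerator]] / den
  table
}

#' Hippocampal occupancy score
#'
#' HOC = hippocampal volume / (hippocampal + temporal-horn volume), a
#' fraction in `[0, 1]` that accounts for ex-vacuo expansion of the
#' temporal horn as the hippocampus atrophies.
#'
#' @param hippo_vol,horn_vol Volumes in mm³ (>= 0); vectorized.
#' @return HOC fraction(s).
#' @export
#' @examples
#' hippocampal_occupancy(3, 1)  # 0.75
hippocampal_occupancy <- function(hippo_vol, horn_vol) {
  if (any(hippo_vol < 0, na.rm = TRUE) || any(horn_vol < 0, na.rm = TRUE)) {
    stop("volumes must be >= 0", call. = FALSE)
  }
  tot <- hippo_vol + horn_vol
  if (any(tot == 0, na.rm = TRUE)) {
    stop("hippocampal and temporal-horn volumes are both zero", call. = FALSE)
  }
  hippo_vol / tot
}

#' Pearson correlation of an analyte with a cognitive score
#'
#' Pairwise-complete Pearson product-moment correlation with a
#' two-sided p value from the t transform on n - 2 degrees of freedom.
#'
#' @param table Cohort data frame.
#' @param analyte,score_name Column names to correlate.
#' @return One-row data frame: `analyte`, `score_name`, `n`,
#'   `pearson_r`, `p_value`.
#' @export
correlate <- function(table, analyte, score_name) {
  stopifnot(analyte %in% names(table), score_name %in% names(table))
  x <- table[[analyte]]
  y <- table[[score_name]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop(sprintf("%s vs %s: need >= 3 paired observations", analyte,
                 score_name), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(sprintf("%s vs %s: zero variance, correlation undefined", analyte,
                 score_name), call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(
    analyte = analyte, score_name = score_name, n = length(x),
    pearson_r = unname(ct$estimate), p_value = ct$p.value,
    stringsAsFactors = FALSE
  )
}

#' Analyte-by-score Pearson correlation table
#'
#' One row per (analyte, score) pair with pairwise-complete n, r and
#' raw two-sided p (no multiple-testing adjustment, matching the
#' convention of reporting raw p values with a significance highlight);
#' a Benjamini-Hochberg column can be requested.
#'
#' @param table Cohort data frame.
#' @param analytes,scores Character vectors of column names.
#' @param adjust Add a `p_bh` Benjamini-Hochberg column (default FALSE).
#' @return Data frame with columns `analyte`, `score_name`, `n`,
#'   `pearson_r`, `p_value` (and optionally `p_bh`).
#' @export
correlation_table <- function(table, analytes, scores, adjust = FALSE) {
  rows <- list()
  for (a in analytes) {
    for (s in scores) {
      rows[[length(rows) + 1]] <- correlate(table, a, s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Two-group comparison of an analyte
#'
#' Two-tailed two-sample t test; Student's pooled-variance form by
#' default, Welch by flag.
#'
#' @param table Cohort data frame with a `group` column (two levels).
#' @param analyte Analyte column name.
#' @param var_equal Pooled-variance Student t (default TRUE).
#' @return List with `t_statistic`, `p_two_sided`, `df`, `group_means`.
#' @export
group_compare <- function(table, analyte, var_equal = TRUE) {
  stopifnot(analyte %in% names(table), "group" %in% names(table))
  g <- as.character(table$group)
  lv <- unique(g[!is.na(g)])
  if (length(lv) != 2) stop("group: need exactly two groups", call. = FALSE)
  x <- table[[analyte]][g == lv[1]]
  y <- table[[analyte]][g == lv[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  zero_var <- stats::sd(x) == 0 && stats::sd(y) == 0
  if (zero_var && mean(x) != mean(y)) {
    # degenerate: two distinct constants; difference certain
    return(list(t_statistic = Inf, p_two_sided = 0, df = NA_real_,
                group_means = stats::setNames(c(mean(x), mean(y)), lv),
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(
    t_statistic = unname(tt$statistic),
    p_two_sided = tt$p.value,
    df = unname(tt$parameter),
    group_means = stats::setNames(c(mean(x), mean(y)), lv),
    degenerate = FALSE
  )
}

#' One-way ANOVA across groups
#'
#' Classical one-way fixed-effects ANOVA (equal-variance F test).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (k >= 2 levels, each with >= 2
#'   observations).
#' @return List with `F_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(
    F_statistic = unname(ft$statistic),
    p_value = ft$p.value,
    df_between = unname(ft$parameter[1]),
    df_within = unname(ft$parameter[2])
  )
}
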
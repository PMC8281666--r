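# Independent oracles, written before the implementations they check.

# AUC by exhaustive threshold sweep: trapezoidal area under the empirical
# ROC curve over all distinct score cutoffs.
auc_sweep_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(c) mean(scores[labels] >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(scores[!labels] >= c), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# ICC(2,1) from brute-force two-way ANOVA mean squares obtained via
# stats::lm/anova (independent sums-of-squares path).
icc_anova_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  # only the mean squares are used, not anova()'s F-tests (which warn on a
  # perfect fit)
  a <- suppressWarnings(stats::anova(stats::lm(y ~ subj + rater, data = df)))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
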
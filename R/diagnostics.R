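# Diagnostic-statistics layer: empirical ROC with Youden-optimal cutoff
# and confusion metrics, DeLong comparison of correlated AUCs, two-way
# mixed absolute-agreement ICC, chi-squared and pooled t group tests, and
# univariate / backward-elimination multiple linear regression.

.binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  u <- unique(labels)
  if (length(u) != 2L && !(length(u) == 1L))
    stop("labels must have two classes", call. = FALSE)
  if (is.null(positive))
    positive <- if ("NASH" %in% u) "NASH" else sort(u)[2]
  labels == positive
}

# DeLong placement values: for each positive, the fraction of negatives
# it outranks (ties count 1/2); and the converse for negatives.
.placements <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), m = m, n = n,
       auc = mean(psi))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC over all distinct observed scores (a subject
#' is called positive when its score is at or above the cutoff), computes
#' the area under the curve by the trapezoidal rule with a DeLong-variance
#' normal 95% CI, selects the cutoff maximizing the Youden index
#' (sensitivity + specificity - 1; ties resolved to the lower cutoff) and
#' reports sensitivity, specificity, PPV, NPV and accuracy at that cutoff.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels class labels (two classes present).
#' @param positive label of the positive class (default `"NASH"` when
#'   present, else the alphabetically later label; for logical labels,
#'   `TRUE`).
#' @return object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  pos <- .binary_labels(labels, positive)
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  stopifnot(length(scores) == length(pos), all(is.finite(scores)))
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  m <- sum(pos); n <- sum(!pos)
  tp <- vapply(cuts, function(c) sum(scores[pos] >= c), 0)
  fp <- vapply(cuts, function(c) sum(scores[!pos] >= c), 0)
  tpr <- tp / m
  fpr <- fp / n
  # trapezoid over the curve traversed from (1,1) to (0,0)
  auc <- sum(diff(-fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pl <- .placements(scores, pos)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)))
  # Youden maximized on exact integer counts so ties are genuine;
  # which.max takes the first (= lowest) cutoff
  best <- which.max(tp * n - fp * m)
  cutoff <- cuts[best]
  pred <- scores >= cutoff
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  structure(list(
    thresholds = cuts, tpr = tpr, fpr = fpr, auc = auc, auc_var = v,
    ci95 = ci, youden_cutoff = cutoff,
    sensitivity = tp / m, specificity = tn / n,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / (m + n),
    n_pos = m, n_neg = n
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis: %d positives / %d negatives\n", x$n_pos,
              x$n_neg))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci95[1],
              x$ci95[2]))
  cat(sprintf(
    "  Youden cutoff %.4g: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, accuracy %.1f%%\n",
    x$youden_cutoff, 100 * x$sensitivity, 100 * x$specificity,
    100 * x$ppv, 100 * x$npv, 100 * x$accuracy))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' using the DeLong placement-value covariance: z = (AUC_a - AUC_b) / SE,
#' two-sided normal p. Identical scores give z = 0, p = 1.
#'
#' @param scores_a,scores_b numeric scores on the same subjects.
#' @param labels class labels (both classes present).
#' @param positive positive-class label, see [roc_analysis()].
#' @return object of class `delong_result`: `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length",
         call. = FALSE)
  pos <- .binary_labels(labels, positive)
  if (!any(pos) || all(pos))
    stop("both classes must be present", call. = FALSE)
  pa <- .placements(scores_a, pos)
  pb <- .placements(scores_b, pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else z <- d / sqrt(v)
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = max(v, 0),
                 z = z, p = if (is.infinite(z)) 0 else
                   2 * stats::pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f, z = %.3f, p = %.4f\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Two-way mixed absolute-agreement ICC (single measure)
#'
#' ICC(A,1) from the two-way ANOVA mean squares (subjects, raters,
#' residual):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' Absolute agreement penalizes systematic shifts between raters, so a
#' constant offset yields ICC < 1.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 3 subjects, >= 2 raters).
#' @return object of class `icc_result`: `icc`, the mean squares, and the
#'   model tag.
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L)
    stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("ratings must be finite", call. = FALSE)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0)
    stop("zero variance across subjects and raters; ICC undefined",
         call. = FALSE)
  structure(list(icc = (msr - mse) / denom, msr = msr, msc = msc,
                 mse = mse, n = n, k = k,
                 model = "two-way mixed, absolute agreement, single measure"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%s; %d subjects x %d raters)\n",
              x$icc, x$model, x$n, x$k))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic sum((O - E)^2 / E) with df = (r-1)(c-1) and upper-tail
#' p, without continuity correction.
#'
#' @param table matrix of nonnegative integer counts with positive row and
#'   column margins.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Two-sided test assuming equal variances. Degenerate inputs (zero pooled
#' variance) return p = 1 when the means agree and p = 0 (flagged via
#' `degenerate = TRUE`) when they differ.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2, finite).
#' @param welch use the Welch unequal-variance form instead.
#' @return list with `statistic`, `df`, `p`, and optionally `degenerate`.
#' @export
t_test_pooled <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 observations", call. = FALSE)
  if (any(!is.finite(c(group_a, group_b))))
    stop("groups must be finite", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    eq <- mean(group_a) == mean(group_b)
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

.beta_std <- function(b, x, y) b * stats::sd(x) / stats::sd(y)

#' Univariate and backward-elimination multiple linear regression
#'
#' In `"univariate"` mode each predictor is regressed on its own and
#' reported with the unstandardized slope B, the standardized Beta
#' (B * SD(x)/SD(y)), its p-value and 95% CI. In `"multiple_backward"`
#' mode all predictors enter one model and the predictor with the largest
#' p-value is dropped iteratively while that p-value exceeds `alpha_stay`;
#' the final model is reported along with the retained predictor set.
#'
#' @param y numeric response.
#' @param predictors numeric matrix or data frame of predictors.
#' @param mode `"univariate"` or `"multiple_backward"`.
#' @param alpha_stay significance level a predictor needs to stay in the
#'   backward-elimination model.
#' @return object of class `regression_result`: data frame `table`
#'   (predictor, B, beta, p, ci_lo, ci_hi), `retained`, `mode`.
#' @export
regress <- function(y, predictors, mode = c("univariate",
                                            "multiple_backward"),
                    alpha_stay = 0.05) {
  mode <- match.arg(mode)
  X <- as.data.frame(predictors)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("x", seq_along(X))
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("need n > number of predictors + 1", call. = FALSE)
  row_of <- function(fit, var, xvec) {
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)[var, ]
    data.frame(predictor = var, B = sm[var, 1],
               beta = .beta_std(sm[var, 1], xvec, y),
               p = sm[var, 4], ci_lo = ci[1], ci_hi = ci[2],
               row.names = NULL)
  }
  if (mode == "univariate") {
    tab <- do.call(rbind, lapply(names(X), function(v) {
      d <- data.frame(y = y, x = X[[v]])
      fit <- stats::lm(y ~ x, data = d)
      r <- row_of(fit, "x", X[[v]])
      r$predictor <- v
      r
    }))
    return(structure(list(table = tab, retained = names(X),
                          mode = mode), class = "regression_result"))
  }
  keep <- names(X)
  repeat {
    d <- cbind(y = y, X[keep])
    fit <- stats::lm(y ~ ., data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop("singular design; offending predictors: ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    sm <- summary(fit)$coefficients
    pv <- sm[setdiff(rownames(sm), "(Intercept)"), 4]
    if (length(pv) == 0L || max(pv) <= alpha_stay) break
    worst <- names(pv)[which.max(pv)]
    keep <- setdiff(keep, worst)
    if (length(keep) == 0L) break
  }
  tab <- if (length(keep))
    do.call(rbind, lapply(keep, function(v) {
      r <- row_of(fit, v, X[[v]])
      r$predictor <- v
      r
    }))
  else data.frame(predictor = character(), B = numeric(), beta = numeric(),
                  p = numeric(), ci_lo = numeric(), ci_hi = numeric())
  structure(list(table = tab, retained = keep, mode = mode),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear regression (%s); retained: %s\n", x$mode,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
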
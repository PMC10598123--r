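test_that("ROC handles the canonical edge cases", {
  labs <- c(rep("NASH", 4), rep("simple_steatosis", 4))
  perfect <- roc_analysis(c(4, 3, 5, 6, 1, 0, 2, -1), labs)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  flat <- roc_analysis(rep(0.3, 8), labs)
  expect_equal(flat$auc, 0.5)
  expect_error(roc_analysis(1:4, rep("NASH", 4)), "both classes")
  # curve monotone, AUC equals trapezoid, CI ordered and bounded
  set.seed(2)
  r <- roc_analysis(rnorm(20), rep(c("NASH", "simple_steatosis"), 10))
  expect_true(all(diff(r$tpr) <= 0))
  expect_true(all(diff(r$fpr) <= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("AUC equals the exhaustive Mann-Whitney pair count", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    npos <- sample(2:(n - 2), 1)
    pos <- c(rep(TRUE, npos), rep(FALSE, n - npos))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    r <- roc_analysis(scores, pos)
    expect_equal(r$auc, mw_auc(scores, pos), tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals an exhaustive threshold scan", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    pos <- runif(n) > 0.5
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[1] <- FALSE
    scores <- round(rnorm(n), 1)
    r <- roc_analysis(scores, pos)
    cand <- c(-Inf, sort(unique(scores)), Inf)
    # integer-count scan: exact arithmetic, so ties are genuine
    y <- vapply(cand, function(cc)
      sum(scores[pos] >= cc) * sum(!pos) -
        sum(scores[!pos] >= cc) * sum(pos), 0)
    best <- min(cand[y == max(y)])  # ties -> lower threshold
    expect_identical(r$youden_cutoff, best)
    expect_equal(r$sensitivity + r$specificity - 1,
                 max(y) / (sum(pos) * sum(!pos)), tolerance = 1e-12)
  }
})

test_that("DeLong test is symmetric and exact for identical scores", {
  set.seed(33)
  labs <- rep(c("NASH", "simple_steatosis"), each = 8)
  a <- rnorm(16); b <- rnorm(16)
  same <- delong_test(a, a, labs)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_test(a, b, labs)
  ba <- delong_test(b, a, labs)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_gte(ab$var_diff, 0)
  expect_error(delong_test(a, b[1:8], labs), "equal length")
})

test_that("DeLong p agrees with a 10,000-draw subject bootstrap at n = 16", {
  set.seed(34)
  labs <- rep(c(TRUE, FALSE), each = 8)
  a <- rnorm(16) + labs * 1.0
  b <- rnorm(16) + labs * 0.4
  dl <- delong_test(a, b, labs)
  pos_i <- which(labs); neg_i <- which(!labs)
  B <- 10000
  d <- numeric(B)
  for (r in seq_len(B)) {
    ip <- sample(pos_i, replace = TRUE)
    ineg <- sample(neg_i, replace = TRUE)
    idx <- c(ip, ineg)
    lb <- labs[idx]
    d[r] <- mw_auc(a[idx], lb) - mw_auc(b[idx], lb)
  }
  p_boot <- 2 * min(mean(d <= 0), mean(d >= 0))
  expect_lt(abs(dl$p - min(p_boot, 1)), 0.05)
})

test_that("ICC(A,1) matches the mean-squares oracle and its definition", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_absolute(cbind(x, x))$icc, 1)
  shifted <- icc_absolute(cbind(x, x + 2))
  expect_lt(shifted$icc, 1)
  expect_gt(shifted$icc, 0)
  set.seed(35)
  for (i in 1:10) {
    r <- matrix(rnorm(20), 10, 2)
    got <- icc_absolute(r)$icc
    # direct two-way ANOVA mean squares
    n <- 10; k <- 2
    grand <- mean(r)
    msr <- k * sum((rowMeans(r) - grand)^2) / (n - 1)
    msc <- n * sum((colMeans(r) - grand)^2) / (k - 1)
    sse <- 0
    for (s in 1:n) for (j in 1:k)
      sse <- sse + (r[s, j] - rowMeans(r)[s] - colMeans(r)[j] + grand)^2
    mse <- sse / ((n - 1) * (k - 1))
    oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_true(got >= -1 && got <= 1)
  }
  expect_error(icc_absolute(matrix(1, 5, 2)), "undefined")
  expect_error(icc_absolute(matrix(1:4, 2, 2)), "subjects")
})

test_that("chi-squared equals the brute-force observed/expected loop", {
  # worked example from published class-conditional inflammation counts
  tab <- rbind(c(13, 5, 0), c(0, 18, 10))
  r <- chi2_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  expect_equal(r$statistic, stat, tolerance = 1e-12)
  expect_equal(r$statistic, 29.57, tolerance = 1e-3)
  expect_lt(r$p, 0.0001)
  expect_equal(r$df, 2)
  # O = E gives zero statistic
  even <- rbind(c(10, 10), c(10, 10))
  expect_equal(chi2_test(even)$statistic, 0)
  expect_equal(chi2_test(even)$p, 1)
  expect_equal(chi2_test(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  set.seed(36)
  for (i in 1:15) {
    t2 <- matrix(rpois(6, 8) + 1, 2, 3)
    got <- chi2_test(t2)
    E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    stat <- 0
    for (a in 1:2) for (b in 1:3)
      stat <- stat + (t2[a, b] - E[a, b])^2 / E[a, b]
    expect_equal(got$statistic, stat, tolerance = 1e-12)
    expect_equal(got$p, pchisq(stat, 2, lower.tail = FALSE))
  }
  expect_error(chi2_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("ROC and DeLong agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(40)
  labs <- rep(c(1, 0), each = 10)
  a <- rnorm(20) + labs
  b <- rnorm(20) + 0.5 * labs
  ra <- roc_analysis(a, labs == 1)
  pa <- pROC::roc(labs, a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  expect_equal(ra$auc, as.numeric(pROC::auc(pa)), tolerance = 1e-12)
  pb <- pROC::roc(labs, b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  dl <- delong_test(a, b, labs == 1)
  pt <- pROC::roc.test(pa, pb, method = "delong", paired = TRUE)
  expect_equal(dl$p, pt$p.value, tolerance = 1e-9)
  expect_equal(dl$auc_a - dl$auc_b, as.numeric(pROC::auc(pa)) -
                 as.numeric(pROC::auc(pb)), tolerance = 1e-12)
})

test_that("pooled t-test matches closed form and handles degeneracy", {
  expect_equal(t_test_pooled(c(1, 1, 1), c(1, 1, 1))$p, 1)
  set.seed(37)
  a <- rnorm(10); b <- rnorm(10, mean = 5)
  r <- t_test_pooled(a, b)
  expect_lt(r$p, 1e-6)
  r_sw <- t_test_pooled(b, a)
  expect_equal(r$p, r_sw$p)
  expect_equal(r$statistic, -r_sw$statistic)
  # closed form pooled t
  sp <- sqrt(((9 * var(a)) + (9 * var(b))) / 18)
  tval <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(r$statistic, tval, tolerance = 1e-12)
  deg <- t_test_pooled(c(2, 2), c(3, 3))
  expect_equal(deg$p, 0)
  expect_true(isTRUE(deg$degenerate))
})

test_that("regression slopes, betas and backward elimination behave", {
  x <- seq(0, 10, length.out = 50)
  y <- 2 * x
  r <- suppressWarnings(regress(y, data.frame(x = x),
                                mode = "univariate"))
  expect_equal(r$table$B, 2, tolerance = 1e-10)
  expect_equal(r$table$beta, 1, tolerance = 1e-10)
  expect_lt(r$table$p, 1e-12)
  # on a noisy fit the 95% CI brackets the true slope
  set.seed(44)
  yn <- 2 * x + rnorm(50, sd = 0.8)
  rn <- regress(yn, data.frame(x = x), mode = "univariate")
  expect_true(rn$table$ci_lo <= 2 && 2 <= rn$table$ci_hi)
  # standardized beta invariant to rescaling the predictor
  set.seed(38)
  x2 <- rnorm(50); y2 <- x2 + rnorm(50)
  b1 <- regress(y2, data.frame(x = x2), "univariate")$table$beta
  b2 <- regress(y2, data.frame(x = 10 * x2), "univariate")$table$beta
  expect_equal(b1, b2, tolerance = 1e-12)
  # backward elimination always keeps the real predictor; spurious
  # predictors survive at most at the familywise alpha rate
  # (1 - 0.95^3, about 14% per replicate)
  keep_true <- 0; keep_exact <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    X <- data.frame(p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n),
                    p4 = rnorm(n))
    yy <- 3 * X$p1 + rnorm(n)
    fit <- regress(yy, X, "multiple_backward")
    if ("p1" %in% fit$retained) keep_true <- keep_true + 1
    if (identical(fit$retained, "p1")) keep_exact <- keep_exact + 1
  }
  expect_equal(keep_true, 20)
  expect_gte(keep_exact, 13)
  # singular designs are reported
  Xs <- data.frame(a = x, b = x)
  expect_error(regress(y, Xs, "multiple_backward"), "singular")
})
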
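# Supervised link from imaging features (UDC signatures, RLE, FF) to
# histology: stratified cross-validated Random Forest classification of
# NASH vs simple steatosis and Random Forest regression of each SAF
# component, with low/high-grade association tests on the out-of-fold
# predictions.

.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop("class '", cl, "' has fewer subjects (", length(idx),
           ") than folds (", folds, "); stratification impossible",
           call. = FALSE)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Cross-validated Random Forest classification
#'
#' Stratified k-fold cross-validation: a Random Forest is trained on each
#' training split and the held-out subjects receive its class-probability
#' score for the positive class. Every subject is scored exactly once
#' out-of-fold.
#'
#' @param features numeric matrix or data frame, one row per subject.
#' @param labels class labels (two classes, each with at least `folds`
#'   subjects).
#' @param positive label treated as the positive class (default
#'   `"NASH"` if present, else the rarer class).
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment and forests).
#' @param ntree trees per forest.
#' @return object of class `cv_prediction`: list with `scores`
#'   (out-of-fold positive-class probabilities), `labels`, `positive`,
#'   `fold`, `folds`, `ntree`, `seed`.
#' @export
cv_classify <- function(features, labels, positive = NULL, folds = 5L,
                        seed = 1L, ntree = 500L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  if (is.null(positive))
    positive <- if ("NASH" %in% labels) "NASH" else
      names(which.min(table(labels)))
  fold <- .stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  y <- factor(labels)
  for (f in seq_len(folds)) {
    tr <- fold != f
    set.seed(seed * 1000L + f)
    rf <- randomForest::randomForest(features[tr, , drop = FALSE],
                                     y = droplevels(y[tr]), ntree = ntree)
    pr <- stats::predict(rf, features[!tr, , drop = FALSE], type = "prob")
    scores[!tr] <- pr[, positive]
  }
  structure(list(scores = scores, labels = labels, positive = positive,
                 fold = fold, folds = folds, ntree = ntree, seed = seed),
            class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf(
    "Out-of-fold RF scores: %d subjects, %d folds, positive = '%s'\n",
    length(x$scores), x$folds, x$positive))
  for (cl in unique(x$labels)) {
    s <- x$scores[x$labels == cl]
    cat(sprintf("  %-18s %.2f +/- %.2f (n = %d)\n", cl, mean(s),
                stats::sd(s), length(s)))
  }
  invisible(x)
}

#' Cross-validated Random Forest regression of SAF components
#'
#' One Random Forest regression per histology component (steatosis,
#' inflammation, ballooning, fibrosis), each cross-validated with the same
#' fold layout (stratified on the NASH label when given, plain otherwise).
#'
#' @param features numeric matrix or data frame, one row per subject.
#' @param grades data frame with one numeric column per SAF component.
#' @param labels optional class labels used to stratify folds.
#' @param folds number of folds.
#' @param seed integer seed.
#' @param ntree trees per forest.
#' @return named list (per component) of lists with `predictions`
#'   (out-of-fold), `grades`, `fold`.
#' @export
cv_regress_components <- function(features, grades, labels = NULL,
                                  folds = 5L, seed = 1L, ntree = 500L) {
  features <- as.matrix(features)
  grades <- as.data.frame(grades)
  n <- nrow(features)
  stopifnot(nrow(grades) == n)
  fold <- if (is.null(labels))
    {set.seed(seed); sample(rep(seq_len(folds), length.out = n))}
  else .stratified_folds(as.character(labels), folds, seed)
  out <- lapply(names(grades), function(comp) {
    g <- as.numeric(grades[[comp]])
    if (stats::sd(g) == 0)
      stop("grade vector for '", comp, "' is constant; regression target ",
           "degenerate", call. = FALSE)
    preds <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      set.seed(seed * 1000L + f)
      # grades are few-valued integers; randomForest's regression warning
      # about few unique response values is expected here
      rf <- suppressWarnings(
        randomForest::randomForest(features[tr, , drop = FALSE],
                                   y = g[tr], ntree = ntree))
      preds[!tr] <- stats::predict(rf, features[!tr, , drop = FALSE])
    }
    list(predictions = preds, grades = g, fold = fold)
  })
  names(out) <- names(grades)
  out
}

#' Default low/high dichotomization cuts for SAF components
#'
#' Steatosis: grades 0-1 low vs 2-3 high; fibrosis: stages < 3 low vs >= 3
#' high; inflammation and ballooning: 0-1 low vs 2 high.
#'
#' @return named list of threshold grades (high stratum is `grade >= cut`).
#' @export
lowhigh_cuts <- function() {
  list(steatosis = 2L, fibrosis = 3L, inflammation = 2L, ballooning = 2L)
}

#' Low- versus high-grade association test
#'
#' Dichotomizes the actual histology grades of one SAF component and
#' compares the out-of-fold model predictions between the low and high
#' strata with a pooled-variance two-sample t-test.
#'
#' @param predictions numeric out-of-fold predictions (from
#'   [cv_regress_components()] or [cv_classify()] scores).
#' @param grades integer actual grades of the component.
#' @param component one of `"steatosis"`, `"fibrosis"`, `"inflammation"`,
#'   `"ballooning"`.
#' @param cuts named list of cut grades, see [lowhigh_cuts()].
#' @return list with `p`, `statistic`, `cut`, `n_low`, `n_high`.
#' @export
lowhigh_test <- function(predictions, grades,
                         component = c("steatosis", "fibrosis",
                                       "inflammation", "ballooning"),
                         cuts = lowhigh_cuts()) {
  component <- match.arg(component)
  cut <- cuts[[component]]
  high <- grades >= cut
  if (!any(high) || all(high))
    stop("empty stratum for ", component, " at cut >= ", cut, call. = FALSE)
  tt <- t_test_pooled(predictions[!high], predictions[high])
  list(p = tt$p, statistic = tt$statistic, cut = cut,
       n_low = sum(!high), n_high = sum(high))
}
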
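# End-to-end orchestration: simulate -> segment -> quantify -> UDC ->
# predict -> diagnostic statistics, with a single global seed propagated
# to every stage.

#' Pipeline configuration
#'
#' Nested stage configuration for [run_pipeline()]. The global `seed`
#' deterministically derives every stage seed, so a run is reproducible
#' end to end.
#'
#' @param seed global integer seed.
#' @param cohort a [cohort_config()]; its `rng_seed` is overridden by
#'   `seed`.
#' @param segmentation_mode `"truth"` (use generator masks), `"otsu"`
#'   (threshold fallback segmenter) or `"network"` (train the
#'   encoder-decoder on the first `seg_train_n` studies).
#' @param seg_train_n training studies for `"network"` mode.
#' @param n_rois,roi_radius ROI placement parameters per subject/reader.
#' @param udc_sequences sequences receiving independent DCN models whose
#'   signatures are concatenated (default unenhanced T1 + HBP: a
#'   20-component signature).
#' @param csi logical, additionally train a chemical-shift model (patches
#'   pooled over in-/opposed-phase) yielding a separate 10-component
#'   signature.
#' @param n_patches patches per DCN model.
#' @param patch_size patch side in pixels.
#' @param k clusters per sequence model.
#' @param dcn a [dcn_config()]; its `rng_seed` is overridden by `seed`.
#' @param stride signature sliding-window stride.
#' @param folds,ntree cross-validation folds and forest size.
#' @param scale `"desk"` or `"paper_scale"`; the latter raises
#'   `n_patches` to 50000 and refuses to run unless `force = TRUE`.
#' @param force confirm a `paper_scale` run.
#' @param output_dir optional directory; when set, stage outputs (cohort
#'   files, signature and quantification CSVs, report JSON/Markdown) are
#'   written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(n_subjects = 60L,
                                                   class_mix = 0.6),
                            segmentation_mode = c("otsu", "truth",
                                                  "network"),
                            seg_train_n = 8L,
                            n_rois = 9L, roi_radius = 3,
                            udc_sequences = c("t1_pre", "t1_hbp"),
                            csi = TRUE,
                            n_patches = 2000L, patch_size = 16L, k = 10L,
                            dcn = dcn_config(), stride = 2L,
                            folds = 5L, ntree = 500L,
                            scale = c("desk", "paper_scale"),
                            force = FALSE,
                            output_dir = NULL) {
  segmentation_mode <- match.arg(segmentation_mode)
  scale <- match.arg(scale)
  if (scale == "paper_scale") {
    if (!force)
      stop("paper_scale extracts 50,000 patches per sequence and takes ",
           "hours on one CPU; pass force = TRUE to confirm", call. = FALSE)
    n_patches <- 50000L
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  cohort$rng_seed <- as.integer(seed)
  dcn$rng_seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 segmentation_mode = segmentation_mode,
                 seg_train_n = as.integer(seg_train_n),
                 n_rois = as.integer(n_rois), roi_radius = roi_radius,
                 udc_sequences = udc_sequences, csi = csi,
                 n_patches = as.integer(n_patches),
                 patch_size = as.integer(patch_size), k = as.integer(k),
                 dcn = dcn, stride = as.integer(stride),
                 folds = as.integer(folds), ntree = as.integer(ntree),
                 scale = scale, output_dir = output_dir),
            class = "pipeline_config")
}

.group_summary <- function(x, labs) {
  out <- lapply(split(x, labs), function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out
}

# Pooled CSI signature: window histograms of in- and opposed-phase
# combined into a single k-component vector.
.csi_signature <- function(model, study, stride) {
  a <- udc_signature(model, study, sequence = "in_phase", stride = stride)
  b <- udc_signature(model, study, sequence = "opposed_phase",
                     stride = stride)
  s <- (unclass(a) + unclass(b)) / 2
  structure(s / sum(s), class = "udc_signature",
            sequences = "csi", blocks = model$k)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> segment -> quantify -> UDC training -> signatures
#' -> cross-validated prediction -> diagnostic statistics and collects
#' every stage result in a run report. Identical configurations produce
#' identical reports.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`; see Details. Its main blocks:
#'   `segmentation` (mean Dice/recall/precision of the chosen segmenter
#'   against the generator masks), `quantification` (per-subject mean RLE
#'   and FF for two synthetic readers, with ICC), `udc` (signature
#'   matrices), `prediction` (out-of-fold NASH scores, SAF-component
#'   regressions, low/high tests), `stats` (group summaries, t/chi-square
#'   tests, ROC blocks, DeLong comparisons, Table-5-style regressions),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- generate_cohort(config$cohort)
  labs <- vapply(cohort$subjects, `[[`, "", "nash_label")
  grades <- summary(cohort)[, c("steatosis", "inflammation", "ballooning",
                                "fibrosis")]

  # --- segmentation ---------------------------------------------------
  masks <- lapply(cohort$studies, `[[`, "liver_mask")
  seg_metrics <- NULL
  if (config$segmentation_mode == "otsu") {
    pred <- lapply(cohort$studies, function(st) otsu_segment(st$t1_hbp))
    mets <- mapply(function(p, st) evaluate_segmentation(p, st$liver_mask),
                   pred, cohort$studies, SIMPLIFY = FALSE)
    seg_metrics <- list(
      mode = "otsu",
      dice = mean(vapply(mets, `[[`, 0, "dice")),
      recall = mean(vapply(mets, `[[`, 0, "recall")),
      precision = mean(vapply(mets, `[[`, 0, "precision")))
    masks <- pred
  } else if (config$segmentation_mode == "network") {
    tr <- seq_len(min(config$seg_train_n, length(cohort$studies)))
    model <- train_segmenter(cohort$studies[tr],
                             segmenter_spec(rng_seed = seed))
    pred <- lapply(cohort$studies, function(st) segment(model, st$t1_hbp))
    mets <- mapply(function(p, st) evaluate_segmentation(p, st$liver_mask),
                   pred, cohort$studies, SIMPLIFY = FALSE)
    seg_metrics <- list(
      mode = "network",
      dice = mean(vapply(mets, `[[`, 0, "dice")),
      recall = mean(vapply(mets, `[[`, 0, "recall")),
      precision = mean(vapply(mets, `[[`, 0, "precision")))
    masks <- pred
  } else {
    seg_metrics <- list(mode = "truth", dice = 1, recall = 1,
                        precision = 1)
  }
  seg_cohort <- cohort
  for (i in seq_along(masks)) {
    if (!any(masks[[i]])) masks[[i]] <- cohort$studies[[i]]$liver_mask
    seg_cohort$studies[[i]]$liver_mask <- masks[[i]]
  }

  # --- ROI quantification (two synthetic readers) ---------------------
  r1 <- quantify_cohort(seg_cohort, config$n_rois, config$roi_radius,
                        seed = seed)
  r2 <- quantify_cohort(seg_cohort, config$n_rois, config$roi_radius,
                        seed = seed + 1000L)
  icc_rle <- icc_absolute(cbind(r1$rle_mean, r2$rle_mean))
  icc_ff <- icc_absolute(cbind(r1$ff_mean, r2$ff_mean))

  # --- UDC ------------------------------------------------------------
  models <- list()
  for (sq in config$udc_sequences) {
    set.seed(seed)
    ps <- extract_patches(seg_cohort, sq, config$n_patches,
                          config$patch_size)
    models[[sq]] <- train_dcn(ps, config$k, config$dcn)
  }
  X <- cohort_signatures(models, seg_cohort, stride = config$stride)
  X_csi <- NULL
  csi_model <- NULL
  if (config$csi) {
    set.seed(seed)
    p_in <- extract_patches(seg_cohort, "in_phase",
                            ceiling(config$n_patches / 2),
                            config$patch_size)
    p_opp <- extract_patches(seg_cohort, "opposed_phase",
                             config$n_patches %/% 2L, config$patch_size)
    pooled <- structure(list(
      pixels = abind_first(p_in$pixels, p_opp$pixels),
      meta = rbind(p_in$meta, p_opp$meta), sequence = "csi",
      patch_size = p_in$patch_size,
      min_mask_fraction = p_in$min_mask_fraction), class = "patch_set")
    csi_model <- train_dcn(pooled, config$k, config$dcn)
    X_csi <- do.call(rbind, lapply(seg_cohort$studies, function(st)
      unclass(.csi_signature(csi_model, st, config$stride))))
    colnames(X_csi) <- paste0("csi_c", seq_len(config$k))
    rownames(X_csi) <- rownames(X)
  }

  # --- prediction -----------------------------------------------------
  cv <- cv_classify(X, labs, folds = config$folds, seed = seed,
                    ntree = config$ntree)
  cv_csi <- if (config$csi)
    cv_classify(X_csi, labs, folds = config$folds, seed = seed,
                ntree = config$ntree)
  cvr <- cv_regress_components(X, grades, labels = labs,
                               folds = config$folds, seed = seed,
                               ntree = config$ntree)
  lowhigh <- lapply(names(cvr), function(comp) {
    res <- try(lowhigh_test(cvr[[comp]]$predictions, cvr[[comp]]$grades,
                            comp), silent = TRUE)
    if (inherits(res, "try-error")) list(p = NA_real_) else res
  })
  names(lowhigh) <- names(cvr)

  # --- diagnostic statistics ------------------------------------------
  nash <- labs == "NASH"
  grp <- list(
    udc_score = .group_summary(cv$scores, labs),
    rle = .group_summary(r1$rle_mean, labs),
    ff = .group_summary(r1$ff_mean, labs))
  tt <- list(
    udc_score = t_test_pooled(cv$scores[!nash], cv$scores[nash])$p,
    rle = t_test_pooled(r1$rle_mean[!nash], r1$rle_mean[nash])$p,
    ff = t_test_pooled(r1$ff_mean[!nash], r1$ff_mean[nash])$p)
  chi2 <- lapply(names(grades), function(comp) {
    tab <- table(labs, grades[[comp]])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    chi2_test(unclass(tab))[c("statistic", "df", "p")]
  })
  names(chi2) <- names(grades)
  roc_udc <- roc_analysis(cv$scores, labs)
  roc_rle <- roc_analysis(-r1$rle_mean, labs)  # RLE lower in NASH
  roc_ff <- roc_analysis(r1$ff_mean, labs)
  comb_feats <- cbind(X, rle_mean = r1$rle_mean, ff_mean = r1$ff_mean)
  if (config$csi) comb_feats <- cbind(comb_feats, X_csi)
  cv_comb <- cv_classify(comb_feats, labs, folds = config$folds,
                         seed = seed, ntree = config$ntree)
  roc_comb <- roc_analysis(cv_comb$scores, labs)
  delong <- list(
    combined_vs_udc = delong_test(cv_comb$scores, cv$scores, labs),
    udc_vs_rle = delong_test(cv$scores, -r1$rle_mean, labs),
    udc_vs_ff = delong_test(cv$scores, r1$ff_mean, labs))
  regression <- list(
    rle_univariate = regress(r1$rle_mean, grades, "univariate"),
    rle_backward = regress(r1$rle_mean, grades, "multiple_backward"),
    ff_univariate = regress(r1$ff_mean, grades, "univariate"),
    ff_backward = regress(r1$ff_mean, grades, "multiple_backward"))

  report <- structure(list(
    config = config,
    cohort = summary(cohort),
    segmentation = seg_metrics,
    quantification = list(reader1 = r1, reader2 = r2,
                          icc_rle = icc_rle$icc, icc_ff = icc_ff$icc),
    udc = list(signatures = X, csi_signatures = X_csi),
    prediction = list(nash_cv = cv, csi_cv = cv_csi, components = cvr,
                      lowhigh = lowhigh),
    stats = list(group_summaries = grp, t_tests = tt, chi2 = chi2,
                 roc = list(udc = roc_udc, rle = roc_rle, ff = roc_ff,
                            combined = roc_comb),
                 delong = delong, regression = regression)
  ), class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# rbind along the first dimension of two n x p x p arrays
abind_first <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("==== NASH vs simple steatosis pipeline report ====\n")
  labs <- x$cohort$nash_label
  cat(sprintf("Cohort: %d subjects (%d NASH / %d simple steatosis)\n",
              nrow(x$cohort), sum(labs == "NASH"), sum(labs != "NASH")))
  cat(sprintf("Segmentation (%s): Dice %.3f, recall %.3f, precision %.3f\n",
              x$segmentation$mode, x$segmentation$dice,
              x$segmentation$recall, x$segmentation$precision))
  cat(sprintf("Inter-reader ICC(A,1): RLE %.3f, FF %.3f\n",
              x$quantification$icc_rle, x$quantification$icc_ff))
  for (nm in names(x$stats$group_summaries)) {
    g <- x$stats$group_summaries[[nm]]
    cat(sprintf("%-10s steatosis %.2f +/- %.2f | NASH %.2f +/- %.2f | t-test p = %.4g\n",
                nm, g$simple_steatosis["mean"], g$simple_steatosis["sd"],
                g$NASH["mean"], g$NASH["sd"], x$stats$t_tests[[nm]]))
  }
  for (nm in names(x$stats$roc)) {
    r <- x$stats$roc[[nm]]
    cat(sprintf("ROC %-9s AUC %.3f (CI %.2f-%.2f), acc %.1f%%, sens %.1f%%, spec %.1f%%\n",
                nm, r$auc, r$ci95[1], r$ci95[2], 100 * r$accuracy,
                100 * r$sensitivity, 100 * r$specificity))
  }
  cat(sprintf("Backward elimination: RLE keeps {%s}; FF keeps {%s}\n",
              paste(x$stats$regression$rle_backward$retained, collapse = ","),
              paste(x$stats$regression$ff_backward$retained, collapse = ",")))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.json` (all scalar blocks), `signatures.csv`,
#' `quantification.csv` and a human-readable `report.md`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- report$quantification
  utils::write.csv(cbind(q$reader1,
                         rle_mean_r2 = q$reader2$rle_mean,
                         ff_mean_r2 = q$reader2$ff_mean),
                   file.path(dir, "quantification.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(report$udc$signatures),
                              report$udc$signatures,
                              check.names = FALSE),
                   file.path(dir, "signatures.csv"), row.names = FALSE)
  roc_block <- lapply(report$stats$roc, function(r)
    r[c("auc", "ci95", "youden_cutoff", "sensitivity", "specificity",
        "ppv", "npv", "accuracy")])
  json <- list(
    seed = report$config$seed,
    n_subjects = nrow(report$cohort),
    segmentation = report$segmentation,
    icc = list(rle = q$icc_rle, ff = q$icc_ff),
    group_summaries = report$stats$group_summaries,
    t_tests = report$stats$t_tests,
    chi2 = report$stats$chi2,
    roc = roc_block,
    delong = lapply(report$stats$delong, function(d)
      d[c("auc_a", "auc_b", "z", "p")]),
    regression_retained = list(
      rle = report$stats$regression$rle_backward$retained,
      ff = report$stats$regression$ff_backward$retained),
    lowhigh_p = lapply(report$prediction$lowhigh, `[[`, "p")
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- utils::capture.output(print(report))
  writeLines(c("# Pipeline run report", "", "```", md, "```"),
             file.path(dir, "report.md"))
  invisible(dir)
}
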
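# Shared fixtures, generated once per test run. Small deterministic
# cohorts plus one tiny trained DCN and one trained segmenter, reused
# across files to keep the suite fast.

fix_cohort0 <- generate_cohort(
  cohort_config(n_subjects = 4, noise_sd = 0, rng_seed = 3))

fix_cohort <- generate_cohort(cohort_config(n_subjects = 8, rng_seed = 5))

fix_dcn <- local({
  set.seed(11)
  ps <- extract_patches(fix_cohort, "t1_hbp", n_total = 400,
                        patch_size = 16)
  train_dcn(ps, k = 5,
            dcn_config(pretrain_epochs = 3, joint_epochs = 3,
                       rng_seed = 2))
})

# Desk-schedule segmenter trained on the 8 fixture studies (used by both
# the unit tests and the acceptance suite).
fix_segmenter <- train_segmenter(fix_cohort$studies,
                                 segmenter_spec(rng_seed = 1))

# Independent pairwise (Mann-Whitney) AUC: count of positive-negative
# pairs ranked correctly, ties half.
mw_auc <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  s <- 0
  for (xi in x) for (yi in y) s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Build an mr_study by hand from matrices (for brute-force fixtures).
make_study <- function(t1_pre, t1_hbp, in_phase, opposed_phase, mask) {
  structure(list(t1_pre = t1_pre, t1_hbp = t1_hbp, in_phase = in_phase,
                 opposed_phase = opposed_phase, liver_mask = mask),
            class = "mr_study")
}
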
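# Synthetic two-class liver-MRI cohort generator. Each subject gets a SAF
# histology profile, a blob liver mask and four co-registered 2-D sequences
# (unenhanced T1, hepatobiliary-phase T1, in-phase, opposed-phase) whose
# signal model is analytically invertible by the downstream RLE/FF formulas:
#   in-phase      = (W + L) + noise          with L/(W+L) = FF/100
#   opposed-phase = (W - L) + noise
#   T1 pre        = (baseline + texture) + noise
#   T1 HBP        = (baseline + texture) * (1 + RLE) + noise
#   RLE           = rle_base - rle_per_fibrosis*F - rle_per_inflammation*A
# The texture field is zero-mean inside the mask and parameterised by the
# histology grades, so texture carries class information independently of
# the mean signal level.

#' Synthetic cohort configuration
#'
#' Builds the configuration consumed by [generate_cohort()] and
#' [render_study()]. Defaults emulate the published derivation cohort: a
#' NASH prevalence of 28/46, 64x64 single-slice studies, grade frequencies
#' from [saf_grade_tables()], an RLE around 1.6 in mild disease declining
#' with fibrosis stage and inflammation activity, and fat fractions binned
#' by steatosis grade on the dual-echo scale.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param class_mix probability that a subject is NASH, in (0, 1]; class
#'   membership is drawn per subject so the empirical ratio converges to
#'   this value.
#' @param image_size pixels per side of the square slice.
#' @param noise_sd additive Gaussian noise SD in intensity units (>= 0);
#'   intensities are truncated at zero.
#' @param baseline_t1 unenhanced-T1 liver baseline intensity.
#' @param csi_total combined water+lipid signal (in-phase level).
#' @param background out-of-liver background intensity.
#' @param rle_base RLE of a liver with fibrosis stage 0 and inflammation 0.
#' @param rle_per_fibrosis RLE decrease per fibrosis stage.
#' @param rle_per_inflammation RLE decrease per inflammation activity.
#' @param ff_bins 4x2 matrix of (low, high) true-fat-fraction percent bins
#'   indexed by steatosis grade 0-3. Bins live on the dual-echo scale,
#'   which caps at 50 percent, so histology-percent bins are mapped to
#'   roughly half their nominal span.
#' @param texture named list of per-grade texture amplitudes (intensity
#'   units per grade step): `inflammation` (isotropic blobs whose
#'   granularity grows with activity), `fibrosis` (anisotropic streaks),
#'   `ballooning` (band-pass speckle), `steatosis` (fine checkerboard
#'   speckle).
#' @param grade_probs class-conditional grade distributions, see
#'   [saf_grade_tables()].
#' @param effects `"strong"` keeps the default effect sizes; `"none"`
#'   zeroes every texture amplitude and both RLE slopes and collapses the
#'   fat-fraction bins, producing a cohort whose images carry no class
#'   information beyond noise.
#' @param rng_seed integer seed from which the whole cohort is reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 46L,
                          class_mix = 28 / 46,
                          image_size = 64L,
                          noise_sd = 4,
                          baseline_t1 = 250,
                          csi_total = 200,
                          background = 40,
                          rle_base = 1.6,
                          rle_per_fibrosis = 0.12,
                          rle_per_inflammation = 0.08,
                          ff_bins = NULL,
                          texture = list(inflammation = 26, fibrosis = 18,
                                         ballooning = 32, steatosis = 3),
                          grade_probs = saf_grade_tables(),
                          effects = c("strong", "none"),
                          rng_seed = 1L) {
  effects <- match.arg(effects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (class_mix <= 0 || class_mix > 1)
    stop("class_mix must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (image_size < 32L) stop("image_size must be >= 32", call. = FALSE)
  if (is.null(ff_bins))
    ff_bins <- rbind(g0 = c(0.5, 2.5), g1 = c(2.5, 16.5),
                     g2 = c(17, 33), g3 = c(33, 45))
  if (effects == "none") {
    texture <- list(inflammation = 0, fibrosis = 0, ballooning = 0,
                    steatosis = 0)
    rle_per_fibrosis <- 0
    rle_per_inflammation <- 0
    ff_bins <- rbind(g0 = c(2.5, 16.5), g1 = c(2.5, 16.5),
                     g2 = c(2.5, 16.5), g3 = c(2.5, 16.5))
  }
  if (any(ff_bins < 0) || any(ff_bins[, 2] >= 50))
    stop("ff_bins must lie in [0, 50) percent (dual-echo cap)",
         call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), class_mix = class_mix,
    image_size = as.integer(image_size), noise_sd = noise_sd,
    baseline_t1 = baseline_t1, csi_total = csi_total,
    background = background, rle_base = rle_base,
    rle_per_fibrosis = rle_per_fibrosis,
    rle_per_inflammation = rle_per_inflammation,
    ff_bins = ff_bins, texture = texture, grade_probs = grade_probs,
    effects = effects, rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

# Separable smoothing with edge-replicating shifts; k is an odd-length
# normalized kernel, applied along rows then columns (or one axis only).
.shift_conv <- function(m, k, axis) {
  H <- nrow(m); W <- ncol(m)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (o in seq_along(k)) {
    s <- o - r - 1L
    if (axis == 1L) {
      idx <- pmin(pmax(seq_len(H) + s, 1L), H)
      out <- out + k[o] * m[idx, , drop = FALSE]
    } else {
      idx <- pmin(pmax(seq_len(W) + s, 1L), W)
      out <- out + k[o] * m[, idx, drop = FALSE]
    }
  }
  out
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.blur2 <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  .shift_conv(.shift_conv(m, k, 1L), k, 2L)
}

.unit_sd <- function(m) {
  s <- stats::sd(m)
  if (s > 0) m / s else m
}

# Gaussian bump of peak 1 and radius r = ceil(3*sigma).
.bump_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  outer(k, k)
}

.add_bumps <- function(f, centers, kern, amp) {
  half <- (nrow(kern) - 1L) %/% 2L
  H <- nrow(f); W <- ncol(f)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    ys <- max(1L, cy - half):min(H, cy + half)
    xs <- max(1L, cx - half):min(W, cx + half)
    f[ys, xs] <- f[ys, xs] +
      amp * kern[ys - cy + half + 1L, xs - cx + half + 1L, drop = FALSE]
  }
  f
}

.sample_mask_px <- function(mask, n) {
  idx <- which(mask)
  px <- idx[sample.int(length(idx), n, replace = TRUE)]
  cbind((px - 1L) %% nrow(mask) + 1L, (px - 1L) %/% nrow(mask) + 1L)
}

# Zero-mean (inside the mask) texture field parameterised by SAF grades.
# Each component is a localized structure process with its own shape and
# scale, so grades leave visually distinct patch-level appearances:
# inflammation = many small dark foci, ballooning = sparse bright swollen
# discs, fibrosis = dark elongated streaks at random orientations,
# steatosis = fine alternating speckle.
texture_field <- function(histology, H, W, texture, mask) {
  f <- matrix(0, H, W)
  area <- sum(mask)
  dens <- area / (64 * 64 * 0.25)  # structure counts scale with liver area
  g <- histology$inflammation
  if (texture$inflammation > 0 && g > 0)
    f <- .add_bumps(f, .sample_mask_px(mask, round(24 * g * dens)),
                    .bump_kernel(1.0), -texture$inflammation)
  b <- histology$ballooning
  if (texture$ballooning > 0 && b > 0)
    f <- .add_bumps(f, .sample_mask_px(mask, round(10 * b * dens)),
                    .bump_kernel(2.0), texture$ballooning)
  fs <- histology$fibrosis
  if (texture$fibrosis > 0 && fs > 0) {
    kern <- .bump_kernel(0.9)
    for (l in seq_len(round(5 * fs * dens))) {
      c0 <- .sample_mask_px(mask, 1L)
      th <- stats::runif(1, 0, pi)
      len <- 12 + 3 * fs
      tt <- seq(-len / 2, len / 2, by = 0.7)
      pts <- unique(cbind(round(c0[1] + tt * sin(th)),
                          round(c0[2] + tt * cos(th))))
      pts <- pts[pts[, 1] >= 1 & pts[, 1] <= H &
                   pts[, 2] >= 1 & pts[, 2] <= W, , drop = FALSE]
      if (nrow(pts)) f <- .add_bumps(f, pts, kern, -texture$fibrosis * 0.7)
    }
  }
  s <- histology$steatosis
  if (texture$steatosis > 0 && s > 0) {
    checker <- outer(seq_len(H), seq_len(W),
                     function(i, j) (-1)^((i + j) %% 2))
    f <- f + texture$steatosis * s *
      .unit_sd(matrix(stats::rnorm(H * W), H, W) * checker)
  }
  f[!mask] <- 0
  if (any(mask)) f[mask] <- f[mask] - mean(f[mask])
  f
}

# Randomized convex-ish liver blob: star-shaped region with low-order
# harmonic boundary perturbations, retried until large enough.
random_blob_mask <- function(H, W, max_tries = 50L) {
  xg <- matrix(rep(seq_len(W), each = H), H, W)
  yg <- matrix(rep(seq_len(H), W), H, W)
  for (i in seq_len(max_tries)) {
    cy <- H / 2 + stats::runif(1, -0.06, 0.06) * H
    cx <- W / 2 + stats::runif(1, -0.06, 0.06) * W
    r0 <- stats::runif(1, 0.30, 0.36) * min(H, W)
    a <- stats::runif(3, -0.10, 0.10)
    ph <- stats::runif(3, 0, 2 * pi)
    th <- atan2(yg - cy, xg - cx)
    rad <- r0 * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                   a[3] * cos(4 * th + ph[3]))
    rad <- pmin(rad, 0.46 * min(H, W))
    mask <- sqrt((xg - cx)^2 + (yg - cy)^2) <= rad
    mask[1, ] <- FALSE; mask[H, ] <- FALSE
    mask[, 1] <- FALSE; mask[, W] <- FALSE
    if (sum(mask) >= 0.15 * H * W) return(mask)
  }
  stop("failed to generate a liver mask of sufficient area", call. = FALSE)
}

.true_rle <- function(config, histology) {
  config$rle_base - config$rle_per_fibrosis * histology$fibrosis -
    config$rle_per_inflammation * histology$inflammation
}

#' Render the MR study of one synthetic subject
#'
#' Produces the four co-registered sequences plus the liver mask for a
#' subject record, following the additive water/lipid model for the
#' chemical-shift pair and a multiplicative hepatobiliary enhancement for
#' the T1 pair (see the package vignette). The grade-parameterised texture
#' field is shared between the unenhanced and HBP images (the enhancement
#' is multiplicative on the textured slice), which keeps zero-noise ROI
#' quantification exactly invertible. Consumes the current random stream.
#'
#' @param record a subject record from [generate_cohort()], or any list
#'   with elements `histology` ([saf_profile()]), `true_fat_fraction` and
#'   `true_rle`.
#' @param config a [cohort_config()].
#' @return an object of class `mr_study`: list of matrices `t1_pre`,
#'   `t1_hbp`, `in_phase`, `opposed_phase` and logical `liver_mask`.
#' @export
render_study <- function(record, config) {
  H <- config$image_size; W <- config$image_size
  ff <- record$true_fat_fraction
  rle <- record$true_rle
  if (ff < 0 || ff >= 50)
    stop("true_fat_fraction must be in [0, 50) on the dual-echo scale",
         call. = FALSE)
  if (rle <= -1)
    stop("true_rle must be > -1", call. = FALSE)
  mask <- random_blob_mask(H, W)
  tex <- texture_field(record$histology, H, W, config$texture, mask)
  bg <- config$background
  pre0 <- matrix(bg, H, W)
  pre0[mask] <- config$baseline_t1 + tex[mask]
  if (any(pre0 <= 0))
    stop("texture amplitudes drive T1 intensity non-positive; ",
         "reduce texture amplitudes or raise baseline_t1", call. = FALSE)
  hbp0 <- matrix(bg, H, W)
  hbp0[mask] <- pre0[mask] * (1 + rle)
  lipid <- config$csi_total * ff / 100
  in0 <- matrix(bg, H, W); in0[mask] <- config$csi_total
  opp0 <- matrix(bg, H, W); opp0[mask] <- config$csi_total - 2 * lipid
  if (any(opp0 < 0))
    stop("opposed-phase intensity negative; fat fraction too high",
         call. = FALSE)
  noisy <- function(m) {
    if (config$noise_sd == 0) return(m)
    pmax(m + matrix(stats::rnorm(H * W, sd = config$noise_sd), H, W), 0)
  }
  structure(list(t1_pre = noisy(pre0), t1_hbp = noisy(hbp0),
                 in_phase = noisy(in0), opposed_phase = noisy(opp0),
                 liver_mask = mask),
            class = "mr_study")
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-subject class membership, SAF histology (conditioned on the
#' class via [sample_histology()]), true fat fraction (uniform within the
#' steatosis-grade bin) and true RLE (linear in fibrosis stage and
#' inflammation activity), then renders each study with [render_study()].
#' Fully reproducible from `config$rng_seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `nash_cohort`: list with `subjects` (list of
#'   records: `subject_id`, `histology`, `nash_label`,
#'   `true_fat_fraction`, `true_rle`), `studies` (list of `mr_study`) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  n <- config$n_subjects
  subjects <- vector("list", n)
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (stats::runif(1) < config$class_mix) "NASH" else
      "simple_steatosis"
    hist <- sample_histology(config, cls)
    bin <- config$ff_bins[hist$steatosis + 1L, ]
    rec <- list(
      subject_id = sprintf("S%03d", i),
      histology = hist,
      nash_label = cls,
      true_fat_fraction = stats::runif(1, bin[1], bin[2]),
      true_rle = .true_rle(config, hist)
    )
    subjects[[i]] <- rec
    studies[[i]] <- render_study(rec, config)
  }
  structure(list(subjects = subjects, studies = studies, config = config),
            class = "nash_cohort")
}

#' @export
print.nash_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "nash_label")
  cat(sprintf(
    "Synthetic NAFLD cohort: %d subjects (%d NASH, %d simple steatosis), %dx%d images\n",
    length(labs), sum(labs == "NASH"), sum(labs != "NASH"),
    x$config$image_size, x$config$image_size))
  invisible(x)
}

#' Cohort summary table
#'
#' @param object a `nash_cohort`.
#' @param ... unused.
#' @return data frame with one row per subject: id, the four SAF grades,
#'   the NASH label and the generative truths.
#' @export
summary.nash_cohort <- function(object, ...) {
  do.call(rbind, lapply(object$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               steatosis = s$histology$steatosis,
               inflammation = s$histology$inflammation,
               ballooning = s$histology$ballooning,
               fibrosis = s$histology$fibrosis,
               nash_label = s$nash_label,
               true_fat_fraction = s$true_fat_fraction,
               true_rle = s$true_rle)
  }))
}

#' Write a cohort to disk
#'
#' Writes one NIfTI file per sequence per subject (`<id>_<sequence>.nii.gz`
#' plus `<id>_mask.nii.gz`), a `cohort.csv` with grades, labels and
#' generative truths, and a `config.json` snapshot.
#'
#' @param cohort a `nash_cohort`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- c("t1_pre", "t1_hbp", "in_phase", "opposed_phase")
  for (i in seq_along(cohort$subjects)) {
    id <- cohort$subjects[[i]]$subject_id
    st <- cohort$studies[[i]]
    for (s in seqs)
      RNifti::writeNifti(st[[s]], file.path(dir, paste0(id, "_", s, ".nii.gz")),
                         datatype = "double")
    RNifti::writeNifti(st$liver_mask * 1,
                       file.path(dir, paste0(id, "_mask.nii.gz")),
                       datatype = "uint8")
  }
  utils::write.csv(summary(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  cfg$ff_bins <- unclass(cfg$ff_bins)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `nash_cohort` (config restored from the JSON snapshot; the
#'   `grade_probs` element is re-built from the defaults if absent).
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE)
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- cohort_config(
    n_subjects = cfgj$n_subjects, class_mix = cfgj$class_mix,
    image_size = cfgj$image_size, noise_sd = cfgj$noise_sd,
    baseline_t1 = cfgj$baseline_t1, csi_total = cfgj$csi_total,
    background = cfgj$background, rle_base = cfgj$rle_base,
    rle_per_fibrosis = cfgj$rle_per_fibrosis,
    rle_per_inflammation = cfgj$rle_per_inflammation,
    ff_bins = matrix(unlist(cfgj$ff_bins), ncol = 2,
                     dimnames = list(c("g0", "g1", "g2", "g3"), NULL)),
    texture = as.list(cfgj$texture),
    rng_seed = cfgj$rng_seed)
  seqs <- c("t1_pre", "t1_hbp", "in_phase", "opposed_phase")
  subjects <- vector("list", nrow(tab))
  studies <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$subject_id[i]
    subjects[[i]] <- list(
      subject_id = id,
      histology = saf_profile(tab$steatosis[i], tab$inflammation[i],
                              tab$ballooning[i], tab$fibrosis[i]),
      nash_label = tab$nash_label[i],
      true_fat_fraction = tab$true_fat_fraction[i],
      true_rle = tab$true_rle[i])
    imgs <- lapply(seqs, function(s) {
      m <- RNifti::readNifti(file.path(dir, paste0(id, "_", s, ".nii.gz")))
      matrix(as.vector(m), nrow = dim(m)[1])
    })
    names(imgs) <- seqs
    mk <- RNifti::readNifti(file.path(dir, paste0(id, "_mask.nii.gz")))
    imgs$liver_mask <- matrix(as.vector(mk) > 0.5, nrow = dim(mk)[1])
    studies[[i]] <- structure(imgs, class = "mr_study")
  }
  structure(list(subjects = subjects, studies = studies, config = cfg),
            class = "nash_cohort")
}
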
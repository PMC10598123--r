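test_that("RLE and FF formulas give the textbook values", {
  expect_equal(relative_enhancement(100, 250), 1.5)
  expect_equal(relative_enhancement(123, 123), 0)
  expect_equal(relative_enhancement(200, 100), -0.5)
  expect_equal(fat_fraction(100, 60), 20)
  expect_equal(fat_fraction(77, 77), 0)
  expect_equal(fat_fraction(100, 0), 50)
  expect_error(relative_enhancement(0, 10), "pre_si")
  expect_error(fat_fraction(-5, 10), "si_in")
})

test_that("RLE and FF are invariant under joint intensity rescaling", {
  set.seed(3)
  for (i in 1:20) {
    pre <- runif(1, 50, 300); post <- runif(1, 50, 600)
    sin_ <- runif(1, 50, 300); sopp <- runif(1, 0, sin_)
    s <- runif(1, 0.1, 10)
    expect_equal(relative_enhancement(s * pre, s * post),
                 relative_enhancement(pre, post))
    expect_equal(fat_fraction(s * sin_, s * sopp),
                 fat_fraction(sin_, sopp))
  }
  # FF strictly decreasing in the opposed-phase signal
  ffs <- fat_fraction(100, seq(0, 100, by = 10))
  expect_true(all(diff(ffs) < 0))
})

test_that("ROI means equal brute-force pixel loops on a hand fixture", {
  set.seed(8)
  H <- 8
  imgs <- replicate(4, matrix(runif(H * H, 10, 100), H, H),
                    simplify = FALSE)
  st <- make_study(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]],
                   matrix(TRUE, H, H))
  roi <- list(center = c(4L, 5L), radius = 2)
  q <- quantify_study(st, list(roi))
  # brute force: loop every pixel, test disk membership
  acc <- c(0, 0, 0, 0); n <- 0
  for (y in 1:H) for (x in 1:H) {
    if ((y - 4)^2 + (x - 5)^2 <= 4) {
      n <- n + 1
      for (k in 1:4) acc[k] <- acc[k] + imgs[[k]][y, x]
    }
  }
  expect_equal(q$per_roi$pre_si, acc[1] / n)
  expect_equal(q$per_roi$post_si, acc[2] / n)
  expect_equal(q$per_roi$si_in, acc[3] / n)
  expect_equal(q$per_roi$si_opp, acc[4] / n)
})

test_that("zero-noise quantification inverts the generative truths", {
  for (i in seq_along(fix_cohort0$subjects)) {
    st <- fix_cohort0$studies[[i]]
    truth <- fix_cohort0$subjects[[i]]
    set.seed(100 + i)
    q <- quantify_study(st, place_rois(st$liver_mask))
    expect_equal(q$ff_mean, truth$true_fat_fraction, tolerance = 1e-9)
    expect_equal(q$rle_mean, truth$true_rle, tolerance = 1e-9)
  }
})

test_that("ROI placement yields disjoint interior disks, reproducibly", {
  mask <- matrix(TRUE, 64, 64)
  set.seed(4)
  rois <- place_rois(mask, n = 9, min_radius = 3)
  expect_length(rois, 9)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    px <- expand.grid(y = 1:64, x = 1:64)
    inside <- (px$y - r$center[1])^2 + (px$x - r$center[2])^2 <= r$radius^2
    expect_true(all(px$y[inside] >= 1 & px$y[inside] <= 64))
    for (j in seq_len(i - 1)) {
      d <- sqrt(sum((r$center - rois[[j]]$center)^2))
      expect_gt(d, 2 * r$radius)
    }
  }
  set.seed(4)
  expect_identical(place_rois(mask, n = 9, min_radius = 3), rois)
  expect_error(place_rois(matrix(TRUE, 4, 4), n = 1, min_radius = 3),
               "radius")
})

test_that("noisy FF means are unbiased for the generative fat fraction", {
  coh <- generate_cohort(cohort_config(n_subjects = 23, noise_sd = 4,
                                       rng_seed = 12))
  errs <- c()
  set.seed(77)
  for (i in seq_along(coh$subjects)) {
    st <- coh$studies[[i]]
    q <- quantify_study(st, place_rois(st$liver_mask))
    errs <- c(errs, q$per_roi$ff - coh$subjects[[i]]$true_fat_fraction)
  }
  expect_gte(length(errs), 200)
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("clinical scores match hand-calculator oracles", {
  labs <- list(age = 50, bmi = 28, ast = 50, alt = 25, ast_uln = 40,
               platelets = 250, albumin = 40, bilirubin = 17.104,
               ifg_diabetes = 0)
  sc <- clinical_scores(labs)
  expect_equal(sc$fib4, 50 * 50 / (250 * sqrt(25)))  # = 2
  expect_equal(sc$albi, 0.66 * log10(17.104) - 0.0852 * 40,
               tolerance = 1e-12)
  expect_equal(sc$albi, -2.594, tolerance = 1e-3)
  expect_equal(sc$apri, (50 / 40) * 100 / 250)
  labs2 <- labs; labs2$ifg_diabetes <- 1
  expect_equal(clinical_scores(labs2)$nfs - sc$nfs, 1.13)
  labs3 <- labs; labs3$platelets <- 0
  expect_error(clinical_scores(labs3), "platelets")
  expect_error(clinical_scores(labs[-1]), "missing lab fields")
})
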
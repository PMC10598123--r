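test_that("patch extraction honors count, mask fraction and seed", {
  set.seed(11)
  ps <- extract_patches(fix_cohort, "t1_hbp", n_total = 100,
                        patch_size = 16, min_mask_fraction = 0.9)
  expect_equal(dim(ps$pixels), c(100, 16, 16))
  expect_equal(nrow(ps$meta), 100)
  for (t in 1:100) {
    st <- fix_cohort$studies[[ps$meta$subject[t]]]
    win <- st$liver_mask[ps$meta$row[t]:(ps$meta$row[t] + 15),
                         ps$meta$col[t]:(ps$meta$col[t] + 15)]
    expect_gte(mean(win), 0.9)
  }
  set.seed(11)
  ps2 <- extract_patches(fix_cohort, "t1_hbp", n_total = 100,
                         patch_size = 16, min_mask_fraction = 0.9)
  expect_identical(ps, ps2)
  expect_error(extract_patches(fix_cohort, "t1_hbp", 10, patch_size = 128),
               "patch_size")
})

test_that("single-cluster model assigns everything to one cluster", {
  set.seed(1)
  ps <- extract_patches(fix_cohort, "t1_pre", n_total = 60,
                        patch_size = 16)
  m1 <- train_dcn(ps, k = 1,
                  dcn_config(pretrain_epochs = 1, joint_epochs = 1,
                             rng_seed = 1))
  sig <- udc_signature(m1, fix_cohort$studies[[1]])
  expect_equal(as.numeric(sig), 1)
  expect_true(all(m1$assignments == 1L))
})

test_that("nearest-centroid assignment equals a brute-force scan", {
  set.seed(14)
  cen <- matrix(rnorm(5 * 16), 5, 16)
  z <- matrix(rnorm(40 * 16), 40, 16)
  got <- nashudc:::.nearest_centroid(z, cen)
  for (i in 1:40) {
    d <- apply(cen, 1, function(cc) sum((z[i, ] - cc)^2))
    expect_identical(got[i], which.min(d))
  }
  # exact tie between clusters 2 and 5 resolves to the lower index
  cen_tie <- cen; cen_tie[5, ] <- cen_tie[2, ]
  a <- nashudc:::.nearest_centroid(cen_tie[2, , drop = FALSE], cen_tie)
  expect_identical(a, 2L)
  # a patch whose latent code sits on centroid j maps to j
  zj <- cen[3, , drop = FALSE]
  expect_identical(nashudc:::.nearest_centroid(zj, cen), 3L)
})

test_that("assign_cluster matches predict() and validates shape", {
  patch <- fix_dcn_patch <- matrix(rnorm(256), 16, 16)
  idx <- assign_cluster(fix_dcn, patch)
  expect_true(idx >= 1 && idx <= fix_dcn$k)
  arr <- array(patch, c(1, 16, 16))
  expect_identical(predict(fix_dcn, arr), idx)
  expect_error(assign_cluster(fix_dcn, matrix(0, 8, 8)), "shape")
})

test_that("signatures are normalized histograms over all valid windows", {
  sig <- udc_signature(fix_dcn, fix_cohort$studies[[2]])
  expect_length(sig, fix_dcn$k)
  expect_equal(sum(sig), 1, tolerance = 1e-12)
  expect_true(all(sig >= 0))
  # stride-1 signature equals exhaustive enumeration of valid windows
  st <- fix_cohort$studies[[3]]
  sig1 <- udc_signature(fix_dcn, st, stride = 1L)
  img <- nashudc:::.znorm_masked(st$t1_hbp, st$liver_mask)
  counts <- numeric(fix_dcn$k)
  H <- nrow(img)
  for (r in 1:(H - 15)) for (cc in 1:(H - 15)) {
    win_mask <- st$liver_mask[r:(r + 15), cc:(cc + 15)]
    if (mean(win_mask) >= fix_dcn$min_mask_fraction) {
      a <- assign_cluster(fix_dcn, img[r:(r + 15), cc:(cc + 15)])
      counts[a] <- counts[a] + 1
    }
  }
  expect_equal(unclass(sig1), counts / sum(counts), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("signature is invariant under joint cluster relabeling", {
  sig <- udc_signature(fix_dcn, fix_cohort$studies[[1]])
  perm <- c(3L, 1L, 5L, 2L, 4L)
  m2 <- fix_dcn
  m2$centroids <- fix_dcn$centroids[perm, ]
  sig2 <- udc_signature(m2, fix_cohort$studies[[1]])
  # cluster j of m2 is cluster perm[j] of the original
  expect_equal(as.numeric(sig2), as.numeric(sig)[perm],
               tolerance = 1e-12)
})

test_that("concatenation keeps per-sequence blocks and their unit sums", {
  sig_hbp <- udc_signature(fix_dcn, fix_cohort$studies[[1]])
  m_pre <- fix_dcn; m_pre$sequence <- "t1_pre"
  sig_pre <- udc_signature(m_pre, fix_cohort$studies[[1]],
                           sequence = "t1_pre")
  both <- concat_signatures(sig_pre, sig_hbp)
  expect_length(both, 10)
  expect_equal(unclass(both)[1:5], unclass(sig_pre), ignore_attr = TRUE)
  expect_equal(sum(both[1:5]), 1, tolerance = 1e-12)
  expect_equal(sum(both[6:10]), 1, tolerance = 1e-12)
  expect_error(concat_signatures(sig_hbp, sig_hbp), "same sequence")
})

test_that("DCN training is deterministic and recovers planted texture families", {
  set.seed(2)
  ps <- extract_patches(fix_cohort, "t1_hbp", n_total = 80,
                        patch_size = 16)
  cfg <- dcn_config(pretrain_epochs = 2, joint_epochs = 2, rng_seed = 7)
  ma <- train_dcn(ps, k = 3, cfg)
  mb <- train_dcn(ps, k = 3, cfg)
  expect_identical(ma$centroids, mb$centroids)
  expect_error(train_dcn(ps, k = 200, cfg), "exceeds")

  # three visually distinct synthetic families -> ARI > 0.8 at k = 3
  set.seed(30)
  n_fam <- 80
  mk_patch <- function(kind) {
    p <- matrix(rnorm(256, sd = 0.5), 16, 16)
    if (kind == 2) {  # bright central disc
      p <- nashudc:::.add_bumps(p, matrix(c(8L, 8L), 1),
                                nashudc:::.bump_kernel(2.4), 6)
    } else if (kind == 3) {  # vertical dark band
      p[, 7:9] <- p[, 7:9] - 5
    }
    p
  }
  fam <- rep(1:3, each = n_fam)
  px <- array(0, c(3 * n_fam, 16, 16))
  for (i in seq_along(fam)) px[i, , ] <- mk_patch(fam[i])
  ps3 <- structure(list(pixels = px,
                        meta = data.frame(subject = 1, row = 1, col = 1),
                        sequence = "t1_hbp", patch_size = 16L,
                        min_mask_fraction = 0.9), class = "patch_set")
  m3 <- train_dcn(ps3, k = 3,
                  dcn_config(pretrain_epochs = 6, joint_epochs = 6,
                             rng_seed = 3))
  expect_gt(adjusted_rand(m3$assignments, fam), 0.8)
})
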
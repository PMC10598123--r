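# Unsupervised deep clustering (UDC) of liver texture. Patches sampled
# inside liver masks are embedded by a convolutional autoencoder whose
# latent space is partitioned into k prototype clusters (joint
# reconstruction + clustering objective); a liver's signature is the
# normalized histogram of cluster assignments over a sliding window.

.integral_window_sums <- function(mask, p) {
  H <- nrow(mask); W <- ncol(mask)
  if (p > H || p > W) stop("patch_size exceeds image side", call. = FALSE)
  S <- matrix(0, H + 1L, W + 1L)
  # S[i+1, j+1] = sum(mask[1:i, 1:j])
  S[-1, -1] <- t(apply(apply(mask * 1, 2, cumsum), 1, cumsum))
  nh <- H - p + 1L; nw <- W - p + 1L
  S[(1L + p):(H + 1L), (1L + p):(W + 1L)] -
    S[1:nh, (1L + p):(W + 1L)] -
    S[(1L + p):(H + 1L), 1:nw] + S[1:nh, 1:nw]
}

.valid_positions <- function(mask, p, min_frac) {
  ws <- .integral_window_sums(mask, p)
  which(ws >= min_frac * p * p, arr.ind = TRUE)
}

.znorm_masked <- function(img, mask) {
  v <- img[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) s <- 1
  (img - mean(v)) / s
}

#' Extract random patches from a cohort
#'
#' Samples `n_total` square patches (with replacement) uniformly over all
#' valid window positions pooled across subjects. A position is valid when
#' the window lies fully inside the image and at least `min_mask_fraction`
#' of its pixels fall inside the liver mask. Each subject's slice is
#' z-normalized (zero mean, unit variance inside the mask) before
#' patching, so patches encode texture rather than mean signal level.
#' Consumes the current random stream.
#'
#' @param cohort a `nash_cohort`, or any list with `studies` (list of
#'   `mr_study`).
#' @param sequence sequence tag: `"t1_pre"`, `"t1_hbp"`, `"in_phase"` or
#'   `"opposed_phase"`.
#' @param n_total number of patches to draw.
#' @param patch_size window side in pixels (divisible by 8).
#' @param min_mask_fraction minimum in-mask pixel fraction per window.
#' @return object of class `patch_set`: list with `pixels` (array
#'   n x p x p), `meta` (data frame subject, row, col of the 1-based
#'   top-left corner), `sequence`, `patch_size`, `min_mask_fraction`.
#' @export
extract_patches <- function(cohort, sequence = "t1_hbp", n_total = 2000L,
                            patch_size = 16L, min_mask_fraction = 0.9) {
  stopifnot(patch_size >= 8L)
  pools <- lapply(seq_along(cohort$studies), function(i) {
    st <- cohort$studies[[i]]
    pos <- .valid_positions(st$liver_mask, patch_size, min_mask_fraction)
    if (nrow(pos) == 0L) return(NULL)
    cbind(subject = i, pos)
  })
  pool <- do.call(rbind, pools)
  if (is.null(pool) || nrow(pool) == 0L)
    stop("no valid patch position in any study; relax min_mask_fraction ",
         "or reduce patch_size", call. = FALSE)
  norm_imgs <- lapply(cohort$studies, function(st)
    .znorm_masked(st[[sequence]], st$liver_mask))
  draw <- pool[sample.int(nrow(pool), n_total, replace = TRUE), ,
               drop = FALSE]
  px <- array(0, c(n_total, patch_size, patch_size))
  for (t in seq_len(n_total)) {
    i <- draw[t, 1]; r <- draw[t, 2]; cc <- draw[t, 3]
    px[t, , ] <- norm_imgs[[i]][r:(r + patch_size - 1L),
                                cc:(cc + patch_size - 1L)]
  }
  structure(list(pixels = px,
                 meta = data.frame(subject = draw[, 1], row = draw[, 2],
                                   col = draw[, 3]),
                 sequence = sequence, patch_size = as.integer(patch_size),
                 min_mask_fraction = min_mask_fraction),
            class = "patch_set")
}

#' DCN training configuration
#'
#' @param latent_dim latent-space dimension of the autoencoder.
#' @param lambda weight of the clustering loss (latent distance to the
#'   assigned centroid) relative to the reconstruction loss.
#' @param pretrain_epochs autoencoder-only epochs before clustering starts.
#' @param joint_epochs epochs of the alternating joint phase.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param channels feature channels of the three convolution stages.
#' @param rng_seed seed for initialization and batch order.
#' @return object of class `dcn_config`.
#' @export
dcn_config <- function(latent_dim = 16L, lambda = 0.1,
                       pretrain_epochs = 10L, joint_epochs = 10L,
                       batch_size = 256L, lr = 1e-3, channels = 8L,
                       rng_seed = 1L) {
  structure(list(latent_dim = as.integer(latent_dim), lambda = lambda,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 channels = as.integer(channels),
                 rng_seed = as.integer(rng_seed)),
            class = "dcn_config")
}

.dcn_nets <- function(p, ch, latent_dim) {
  pb <- p %/% 8L  # bottleneck side after three stride-2 convolutions
  list(
    encoder = list(nn_conv(3, 3, 1, ch, stride = 2L), nn_relu(),
                   nn_conv(3, 3, ch, ch, stride = 2L), nn_relu(),
                   nn_conv(3, 3, ch, ch, stride = 2L), nn_relu(),
                   nn_dense(pb * pb * ch, latent_dim)),
    decoder = list(nn_dense(latent_dim, pb * pb * ch), nn_relu(),
                   nn_reshape(pb, pb, ch),
                   nn_up2(), nn_conv(3, 3, ch, ch), nn_relu(),
                   nn_up2(), nn_conv(3, 3, ch, ch), nn_relu(),
                   nn_up2(), nn_conv(1, 1, ch, 1)),
    bottleneck = pb)
}

.encode_batchwise <- function(encoder, px, batch = 512L) {
  n <- dim(px)[1]
  out <- NULL
  for (s in seq(1L, n, batch)) {
    e <- min(n, s + batch - 1L)
    x <- array(px[s:e, , , drop = FALSE], c(e - s + 1L, dim(px)[2],
                                            dim(px)[3], 1))
    z <- nn_forward(encoder, x)$out
    out <- rbind(out, z)
  }
  out
}

# Exact squared distances patch-code x centroid; ties resolved to the
# lowest cluster index.
.nearest_centroid <- function(z, centroids) {
  n <- nrow(z); k <- nrow(centroids)
  D <- matrix(0, n, k)
  for (j in seq_len(k))
    D[, j] <- rowSums(sweep(z, 2L, centroids[j, ], "-")^2)
  max.col(-D, ties.method = "first")
}

#' Train a deep clustering network on image patches
#'
#' Joint autoencoder + k-means training: a convolutional encoder (three
#' convolution stages) maps patches to a low-dimensional latent space, a
#' mirrored decoder (three upsampling stages) reconstructs them, and k
#' centroids partition the latent space. After an autoencoder-only
#' pretraining phase, centroids are initialized by k-means on the latent
#' codes; the joint phase then alternates (a) Adam steps on the network
#' minimizing reconstruction error plus `lambda` times the distance of
#' each code to its assigned centroid, and (b) hard reassignment of
#' patches to the nearest centroid, with centroids re-estimated as the
#' mean of their assigned codes.
#'
#' @param patches a `patch_set` from [extract_patches()].
#' @param k number of clusters (default 10).
#' @param config a [dcn_config()].
#' @return object of class `dcn_model`: encoder, decoder, `centroids`
#'   (k x latent_dim), assignments of the training patches, loss history
#'   and a config snapshot.
#' @export
train_dcn <- function(patches, k = 10L, config = dcn_config()) {
  stopifnot(inherits(patches, "patch_set"), k >= 1L)
  px <- patches$pixels
  n <- dim(px)[1]
  p <- patches$patch_size
  if (k > n) stop("k exceeds the number of patches", call. = FALSE)
  if (p %% 8L != 0L)
    stop("patch_size must be divisible by 8 (three pooling stages)",
         call. = FALSE)
  set.seed(config$rng_seed)
  nets <- .dcn_nets(p, config$channels, config$latent_dim)
  enc <- nets$encoder; dec <- nets$decoder
  senc <- nn_adam_init(enc); sdec <- nn_adam_init(dec)
  step <- 0L
  loss_hist <- c()
  run_epoch <- function(centroids, assign) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0L
    for (s in seq(1L, n, config$batch_size)) {
      idx <- ord[s:min(n, s + config$batch_size - 1L)]
      B <- length(idx)
      x <- array(px[idx, , , drop = FALSE], c(B, p, p, 1))
      fe <- nn_forward(enc, x)
      z <- fe$out
      fd <- nn_forward(dec, z)
      xhat <- fd$out
      rec <- mean((xhat - x)^2)
      gxhat <- 2 * (xhat - x) / length(x)
      bd <- nn_backward(dec, fd$caches, gxhat)
      gz <- bd$gin
      loss <- rec
      if (!is.null(centroids)) {
        diffz <- z - centroids[assign[idx], , drop = FALSE]
        loss <- loss + config$lambda * mean(diffz^2)
        gz <- gz + config$lambda * 2 * diffz / length(diffz)
      }
      if (!is.finite(loss))
        stop("DCN training diverged (non-finite loss); config: latent_dim=",
             config$latent_dim, " lambda=", config$lambda, " lr=", config$lr,
             call. = FALSE)
      be <- nn_backward(enc, fe$caches, gz, need_input_grad = FALSE)
      step <<- step + 1L
      ue <- nn_adam_step(enc, be$grads, senc, step, lr = config$lr)
      enc <<- ue$net; senc <<- ue$state
      ud <- nn_adam_step(dec, bd$grads, sdec, step, lr = config$lr)
      dec <<- ud$net; sdec <<- ud$state
      tot <- tot + loss; nb <- nb + 1L
    }
    tot / nb
  }
  for (ep in seq_len(config$pretrain_epochs))
    loss_hist <- c(loss_hist, run_epoch(NULL, NULL))
  z <- .encode_batchwise(enc, px)
  km <- stats::kmeans(z, centers = k, nstart = 5L, iter.max = 100L)
  centroids <- unname(km$centers)
  assign <- .nearest_centroid(z, centroids)
  for (ep in seq_len(config$joint_epochs)) {
    loss_hist <- c(loss_hist, run_epoch(centroids, assign))
    z <- .encode_batchwise(enc, px)
    assign <- .nearest_centroid(z, centroids)
    for (j in seq_len(k)) {
      memb <- assign == j
      if (any(memb))
        centroids[j, ] <- colMeans(z[memb, , drop = FALSE])
    }
  }
  assign <- .nearest_centroid(z, centroids)
  structure(list(encoder = enc, decoder = dec, centroids = centroids,
                 assignments = assign, k = as.integer(k),
                 patch_size = p, latent_dim = config$latent_dim,
                 sequence = patches$sequence,
                 min_mask_fraction = patches$min_mask_fraction,
                 config = config, loss = loss_hist),
            class = "dcn_model")
}

#' @export
print.dcn_model <- function(x, ...) {
  cat(sprintf(
    "DCN model: k = %d clusters, %dx%d patches, latent dim %d, sequence %s\n",
    x$k, x$patch_size, x$patch_size, x$latent_dim, x$sequence))
  cat(sprintf("  cluster occupancy of training patches: %s\n",
              paste(tabulate(x$assignments, x$k), collapse = " ")))
  invisible(x)
}

#' Assign a patch to its nearest cluster
#'
#' Encodes the patch and returns the index (1-based) of the nearest
#' centroid in latent space; ties break to the lowest index.
#'
#' @param model a `dcn_model`.
#' @param patch numeric matrix of side `model$patch_size` (already on the
#'   z-normalized intensity scale used at training).
#' @return integer cluster index in `[1, k]`.
#' @export
assign_cluster <- function(model, patch) {
  stopifnot(inherits(model, "dcn_model"), is.matrix(patch))
  if (!all(dim(patch) == model$patch_size))
    stop("patch shape does not match the model", call. = FALSE)
  x <- array(patch, c(1, dim(patch), 1))
  z <- nn_forward(model$encoder, x)$out
  .nearest_centroid(z, model$centroids)[1]
}

#' @rdname assign_cluster
#' @param object a `dcn_model`.
#' @param newdata a patch matrix or an array n x p x p of patches.
#' @param ... unused.
#' @export
predict.dcn_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(assign_cluster(object, newdata))
  z <- .encode_batchwise(object$encoder, newdata)
  .nearest_centroid(z, object$centroids)
}

#' Sliding-window UDC signature of a study
#'
#' Parses the liver slice with a sliding window (same validity rule as
#' patch extraction), assigns every window to its nearest cluster and
#' returns the normalized histogram of assignments: the relative
#' proportion of the liver that belongs to each of the k clusters.
#'
#' @param model a `dcn_model`.
#' @param study an `mr_study`.
#' @param sequence sequence tag; defaults to the sequence the model was
#'   trained on.
#' @param stride window stride in pixels; the default of 2 parses the
#'   liver near-exhaustively, which stabilizes the histogram on the small
#'   masks of desk-scale studies.
#' @param min_mask_fraction window validity rule; defaults to the model's.
#' @return object of class `udc_signature`: numeric vector of length k
#'   summing to 1, with attributes `sequences` and `blocks`.
#' @export
udc_signature <- function(model, study, sequence = model$sequence,
                          stride = 2L,
                          min_mask_fraction = model$min_mask_fraction) {
  stopifnot(inherits(model, "dcn_model"), inherits(study, "mr_study"))
  p <- model$patch_size
  img <- .znorm_masked(study[[sequence]], study$liver_mask)
  pos <- .valid_positions(study$liver_mask, p, min_mask_fraction)
  keep <- (pos[, 1] - 1L) %% stride == 0L & (pos[, 2] - 1L) %% stride == 0L
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop("no valid window in the study at this stride/mask fraction",
         call. = FALSE)
  px <- array(0, c(nrow(pos), p, p))
  for (t in seq_len(nrow(pos)))
    px[t, , ] <- img[pos[t, 1]:(pos[t, 1] + p - 1L),
                     pos[t, 2]:(pos[t, 2] + p - 1L)]
  a <- predict(model, px)
  h <- tabulate(a, model$k)
  structure(h / sum(h), class = "udc_signature",
            sequences = sequence, blocks = model$k)
}

#' Concatenate UDC signatures from different sequences
#'
#' Joins per-sequence signatures of the same subject into one feature
#' vector (e.g. unenhanced T1 + hepatobiliary phase: 10 + 10 = 20
#' components); each block keeps its own unit sum.
#'
#' @param a,b `udc_signature` objects with disjoint sequence tags.
#' @return a `udc_signature` of length `length(a) + length(b)`.
#' @export
concat_signatures <- function(a, b) {
  stopifnot(inherits(a, "udc_signature"), inherits(b, "udc_signature"))
  if (length(intersect(attr(a, "sequences"), attr(b, "sequences"))) > 0L)
    stop("cannot concatenate signatures from the same sequence",
         call. = FALSE)
  structure(c(unclass(a), unclass(b)), class = "udc_signature",
            sequences = c(attr(a, "sequences"), attr(b, "sequences")),
            blocks = c(attr(a, "blocks"), attr(b, "blocks")))
}

#' @export
print.udc_signature <- function(x, ...) {
  cat(sprintf("UDC signature (%s): %s\n",
              paste(attr(x, "sequences"), collapse = " + "),
              paste(sprintf("%.3f", unclass(x)), collapse = " ")))
  invisible(x)
}

#' Cohort-level UDC feature matrix
#'
#' Computes the per-subject concatenated signature across one or more
#' trained per-sequence models.
#'
#' @param models named list of `dcn_model` objects, names are sequence
#'   tags (e.g. `list(t1_pre = ..., t1_hbp = ...)`).
#' @param cohort a `nash_cohort`.
#' @param stride window stride passed to [udc_signature()].
#' @return numeric matrix, one row per subject, columns named
#'   `<sequence>_c<j>`.
#' @export
cohort_signatures <- function(models, cohort,
                              stride = NULL) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  rows <- lapply(cohort$studies, function(st) {
    sigs <- lapply(names(models), function(sq) {
      m <- models[[sq]]
      s <- if (is.null(stride)) 2L else stride
      udc_signature(m, st, sequence = sq, stride = s)
    })
    sig <- Reduce(concat_signatures, sigs)
    unclass(sig)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- unlist(lapply(names(models), function(sq)
    paste0(sq, "_c", seq_len(models[[sq]]$k))))
  rownames(mat) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  mat
}
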
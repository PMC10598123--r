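#' Segmenter training specification
#'
#' Hyperparameters of the small encoder-decoder liver segmenter: a 2-level
#' contracting/expanding convolutional network sized for 64x64 desk-scale
#' slices, trained with Adam on a pixelwise binary cross-entropy loss.
#'
#' @param channels integer vector of length 2: feature channels at the two
#'   encoder levels.
#' @param epochs full-batch training epochs.
#' @param lr Adam learning rate.
#' @param sequence which sequence to segment on; the hepatobiliary-phase
#'   image is the default (it offers the strongest liver-background
#'   contrast).
#' @param rng_seed seed for weight initialization.
#' @return object of class `segmenter_spec`.
#' @export
segmenter_spec <- function(channels = c(8L, 16L), epochs = 120L, lr = 5e-3,
                           sequence = "t1_hbp", rng_seed = 1L) {
  stopifnot(length(channels) == 2L, all(channels >= 1L), epochs >= 1L,
            lr > 0)
  structure(list(channels = as.integer(channels),
                 epochs = as.integer(epochs), lr = lr, sequence = sequence,
                 rng_seed = as.integer(rng_seed)),
            class = "segmenter_spec")
}

.znorm_image <- function(img) {
  s <- stats::sd(img)
  if (s == 0) img - mean(img) else (img - mean(img)) / s
}

.seg_net <- function(ch) {
  list(nn_conv(3, 3, 1, ch[1]), nn_relu(), nn_pool2(),
       nn_conv(3, 3, ch[1], ch[2]), nn_relu(), nn_pool2(),
       nn_conv(3, 3, ch[2], ch[2]), nn_relu(), nn_up2(),
       nn_conv(3, 3, ch[2], ch[1]), nn_relu(), nn_up2(),
       nn_conv(3, 3, ch[1], 1))
}

#' Train the encoder-decoder liver segmenter
#'
#' Fits the small convolutional segmentation network on studies with known
#' masks. Images are z-normalized per slice; training is full-batch and
#' deterministic for a fixed `spec$rng_seed`.
#'
#' @param studies list of `mr_study` objects (>= 2) whose `liver_mask`
#'   serves as ground truth.
#' @param spec a [segmenter_spec()].
#' @return object of class `liver_segmenter` with elements `net`, `spec`
#'   and `loss` (per-epoch training loss; decreasing over training).
#' @export
train_segmenter <- function(studies, spec = segmenter_spec()) {
  if (length(studies) < 2L)
    stop("need at least 2 training studies", call. = FALSE)
  dims <- vapply(studies, function(s) dim(s[[spec$sequence]]), integer(2))
  if (any(dims != dims[, 1]))
    stop("training images must share one shape", call. = FALSE)
  H <- dims[1, 1]; W <- dims[2, 1]
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("image sides must be divisible by 4", call. = FALSE)
  B <- length(studies)
  x <- array(0, c(B, H, W, 1))
  y <- array(0, c(B, H, W, 1))
  for (i in seq_len(B)) {
    x[i, , , 1] <- .znorm_image(studies[[i]][[spec$sequence]])
    y[i, , , 1] <- studies[[i]]$liver_mask * 1
  }
  set.seed(spec$rng_seed)
  net <- .seg_net(spec$channels)
  state <- nn_adam_init(net)
  losses <- numeric(spec$epochs)
  n <- length(y)
  for (ep in seq_len(spec$epochs)) {
    fw <- nn_forward(net, x)
    p <- 1 / (1 + exp(-fw$out))
    eps <- 1e-12
    losses[ep] <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    if (!is.finite(losses[ep]))
      stop("segmenter training diverged (non-finite loss)", call. = FALSE)
    bk <- nn_backward(net, fw$caches, (p - y) / n, need_input_grad = FALSE)
    up <- nn_adam_step(net, bk$grads, state, ep, lr = spec$lr)
    net <- up$net; state <- up$state
  }
  structure(list(net = net, spec = spec, loss = losses),
            class = "liver_segmenter")
}

#' @export
print.liver_segmenter <- function(x, ...) {
  cat(sprintf(
    "Liver segmenter: 2-level encoder-decoder (%d/%d channels), %d epochs, final loss %.4f\n",
    x$spec$channels[1], x$spec$channels[2], x$spec$epochs,
    x$loss[length(x$loss)]))
  invisible(x)
}

#' Segment a liver image
#'
#' Applies a trained [train_segmenter()] model; the sigmoid output is
#' thresholded at 0.5.
#'
#' @param model a `liver_segmenter`.
#' @param image numeric matrix (a single slice of the sequence the model
#'   was trained on) with finite entries.
#' @return logical matrix of the same shape.
#' @export
segment <- function(model, image) {
  stopifnot(inherits(model, "liver_segmenter"), is.matrix(image))
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  d <- dim(image)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("image sides must be divisible by 4", call. = FALSE)
  x <- array(0, c(1, d[1], d[2], 1))
  x[1, , , 1] <- .znorm_image(image)
  logit <- nn_forward(model$net, x)$out[1, , , 1]
  matrix(logit > 0, d[1], d[2])
}

#' @rdname segment
#' @param ... passed on.
#' @param newdata image matrix.
#' @param object a `liver_segmenter`.
#' @export
predict.liver_segmenter <- function(object, newdata, ...) {
  segment(object, newdata)
}

#' Threshold-based fallback segmenter
#'
#' Analytic alternative to the trained network: Otsu threshold on the
#' (hepatobiliary-phase) slice, keep the largest connected component and
#' fill holes. Useful to decouple downstream stages from network training.
#'
#' @param image numeric matrix.
#' @return logical matrix.
#' @export
otsu_segment <- function(image) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(FALSE, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(norm)
  thr <- EBImage::otsu(img)
  bin <- EBImage::fillHull(EBImage::bwlabel(img > thr))
  lab <- EBImage::bwlabel(bin > 0)
  labd <- matrix(as.vector(EBImage::imageData(lab)), nrow = nrow(image))
  if (max(labd) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  counts <- tabulate(labd[labd > 0])
  labd == which.max(counts)
}

#' Segmentation overlap metrics
#'
#' Dice, recall and precision between a predicted and a ground-truth mask:
#' dice = 2|P^T|/(|P|+|T|), recall = |P^T|/|T|, precision = |P^T|/|P|.
#' An empty prediction yields precision 1 with attribute
#' `empty_prediction = TRUE`.
#'
#' @param pred logical matrix, predicted mask.
#' @param truth logical matrix, ground truth (nonempty).
#' @return list with `dice`, `recall`, `precision`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.matrix(truth))
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must share one shape", call. = FALSE)
  pred <- pred > 0; truth <- truth > 0
  if (!any(truth)) stop("truth mask is empty", call. = FALSE)
  inter <- sum(pred & truth)
  np <- sum(pred); nt <- sum(truth)
  res <- list(dice = 2 * inter / (np + nt),
              recall = inter / nt,
              precision = if (np == 0) 1 else inter / np)
  if (np == 0) attr(res, "empty_prediction") <- TRUE
  res
}
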
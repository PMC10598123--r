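#' Relative liver enhancement
#'
#' RLE = (PostSI - PreSI) / PreSI, the fractional hepatobiliary-phase
#' signal gain over the unenhanced T1 signal. Vectorized.
#'
#' @param pre_si unenhanced T1 signal intensity (PreSI), > 0.
#' @param post_si hepatobiliary-phase signal intensity (PostSI).
#' @return dimensionless enhancement, >= -1 for nonnegative `post_si`.
#' @examples
#' relative_enhancement(100, 250)  # 1.5
#' @export
relative_enhancement <- function(pre_si, post_si) {
  if (any(!is.finite(pre_si)) || any(pre_si <= 0))
    stop("pre_si must be finite and > 0", call. = FALSE)
  (post_si - pre_si) / pre_si
}

#' Dual-echo chemical-shift fat fraction
#'
#' FF = (SIin - SIopp) / (2 * SIin) * 100, the percent signal loss of the
#' liver parenchyma on opposed-phase relative to in-phase images.
#' Vectorized.
#'
#' @param si_in in-phase signal intensity (SIin), > 0.
#' @param si_opp opposed-phase signal intensity (SIopp).
#' @return fat fraction in percent (50 at `si_opp = 0`).
#' @examples
#' fat_fraction(100, 60)  # 20
#' @export
fat_fraction <- function(si_in, si_opp) {
  if (any(!is.finite(si_in)) || any(si_in <= 0))
    stop("si_in must be finite and > 0", call. = FALSE)
  (si_in - si_opp) / (2 * si_in) * 100
}

.disk_pixels <- function(cy, cx, r, H, W) {
  span <- floor(r)
  ys <- max(1L, cy - span):min(H, cy + span)
  xs <- max(1L, cx - span):min(W, cx + span)
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$y - cy)^2 + (grid$x - cx)^2 <= r^2
  grid[keep, , drop = FALSE]
}

.disk_inside <- function(cy, cx, r, mask) {
  H <- nrow(mask); W <- ncol(mask)
  if (cy - r < 1 || cy + r > H || cx - r < 1 || cx + r > W) return(FALSE)
  px <- .disk_pixels(cy, cx, r, H, W)
  all(mask[cbind(px$y, px$x)])
}

#' Place circular ROIs inside a liver mask
#'
#' Samples `n` pairwise-disjoint circular ROIs fully inside the mask, with
#' centers biased toward large distance from the mask boundary (emulating
#' placement away from vessels and the liver edge). ROI sites stand in for
#' the nine Couinaud-segment measurement sites of the clinical protocol.
#'
#' @param mask logical matrix, the liver mask.
#' @param n number of ROIs (default 9).
#' @param min_radius disk radius in pixels (> 0; default 3, the package's
#'   mapping of the ">= 1 cm diameter" rule onto a 64x64 grid).
#' @param max_tries sampling attempts before failing.
#' @return list of ROIs, each `list(center = c(row, col), radius)`; centers
#'   are 1-based pixel indices.
#' @export
place_rois <- function(mask, n = 9L, min_radius = 3, max_tries = 5000L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- matrix(as.vector(EBImage::imageData(dm)), nrow = nrow(mask))
  dm <- pmin(dm, max(dim(mask)))  # all-foreground masks have no boundary
  cand <- which(dm > min_radius, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    stop("mask admits no disk of radius ", min_radius, call. = FALSE)
  w <- dm[cand]^2  # bias toward deep interior
  rois <- list()
  tries <- 0L
  while (length(rois) < n && tries < max_tries) {
    tries <- tries + 1L
    i <- sample.int(nrow(cand), 1L, prob = w)
    cy <- cand[i, 1]; cx <- cand[i, 2]
    ok <- .disk_inside(cy, cx, min_radius, mask)
    if (ok && length(rois) > 0L) {
      for (r0 in rois) {
        d2 <- (r0$center[1] - cy)^2 + (r0$center[2] - cx)^2
        if (d2 <= (2 * min_radius + 1)^2) { ok <- FALSE; break }
      }
    }
    if (ok)
      rois[[length(rois) + 1L]] <- list(center = c(cy, cx),
                                        radius = min_radius)
  }
  if (length(rois) < n)
    stop("could not place ", n, " disjoint ROIs of radius ", min_radius,
         " inside the mask after ", max_tries, " attempts", call. = FALSE)
  rois
}

#' Quantify one study over a set of ROIs
#'
#' Measures the mean signal intensity of every sequence over each ROI disk
#' and derives per-ROI RLE and FF plus their across-ROI arithmetic means
#' (the study-level summary used for group statistics).
#'
#' @param study an `mr_study`.
#' @param rois list of ROIs from [place_rois()].
#' @return object of class `quant_result`: list with `per_roi` (data frame
#'   of roi_id, center, pre_si, post_si, si_in, si_opp, rle, ff),
#'   `rle_mean` and `ff_mean`.
#' @export
quantify_study <- function(study, rois) {
  stopifnot(inherits(study, "mr_study"))
  H <- nrow(study$t1_pre); W <- ncol(study$t1_pre)
  rows <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    if (!.disk_inside(roi$center[1], roi$center[2], roi$radius,
                      study$liver_mask))
      stop("ROI ", i, " extends outside the liver mask", call. = FALSE)
    px <- .disk_pixels(roi$center[1], roi$center[2], roi$radius, H, W)
    idx <- cbind(px$y, px$x)
    pre <- mean(study$t1_pre[idx]); post <- mean(study$t1_hbp[idx])
    sin_ <- mean(study$in_phase[idx]); sopp <- mean(study$opposed_phase[idx])
    data.frame(roi_id = i, center_row = roi$center[1],
               center_col = roi$center[2], radius = roi$radius,
               pre_si = pre, post_si = post, si_in = sin_, si_opp = sopp,
               rle = relative_enhancement(pre, post),
               ff = fat_fraction(sin_, sopp))
  })
  per_roi <- do.call(rbind, rows)
  structure(list(per_roi = per_roi,
                 rle_mean = mean(per_roi$rle),
                 ff_mean = mean(per_roi$ff)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("ROI quantification: %d ROIs, mean RLE = %.3f, mean FF = %.2f%%\n",
              nrow(x$per_roi), x$rle_mean, x$ff_mean))
  invisible(x)
}

#' Quantify a whole cohort
#'
#' Convenience wrapper: places ROIs per subject (seeded) and returns the
#' cohort table of mean RLE and FF. A second, independently seeded pass can
#' serve as a synthetic "reader 2" for inter-reader agreement analyses.
#'
#' @param cohort a `nash_cohort`.
#' @param n number of ROIs per subject.
#' @param min_radius ROI radius in pixels.
#' @param seed integer seed controlling ROI placement for this reader.
#' @return data frame: subject_id, nash_label, rle_mean, ff_mean.
#' @export
quantify_cohort <- function(cohort, n = 9L, min_radius = 3, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(cohort$subjects), function(i) {
    q <- quantify_study(cohort$studies[[i]],
                        place_rois(cohort$studies[[i]]$liver_mask, n,
                                   min_radius))
    data.frame(subject_id = cohort$subjects[[i]]$subject_id,
               nash_label = cohort$subjects[[i]]$nash_label,
               rle_mean = q$rle_mean, ff_mean = q$ff_mean)
  }))
}

#' Clinical fibrosis and liver-function scores
#'
#' Computes FIB-4, the NAFLD fibrosis score (NFS), ALBI and APRI from a
#' laboratory panel:
#' \itemize{
#'   \item FIB-4 = age (years) x AST / (platelets x sqrt(ALT))
#'   \item NFS = -1.675 + 0.037 x age + 0.094 x BMI + 1.13 x IFG/diabetes
#'     + 0.99 x AST/ALT - 0.013 x platelets - 0.66 x albumin (g/dL)
#'   \item ALBI = 0.66 x log10(bilirubin umol/L) - 0.0852 x albumin (g/L)
#'   \item APRI = (AST / AST upper limit of normal) x 100 / platelets
#' }
#'
#' @param labs named list or one-row data frame with `age` (years), `bmi`
#'   (kg/m^2), `ast`, `alt` (U/L), `ast_uln` (U/L, upper limit of normal
#'   AST), `platelets` (10^9/L), `albumin` (g/L), `bilirubin` (umol/L),
#'   `ifg_diabetes` (0/1).
#' @return named list with `fib4`, `nfs`, `albi`, `apri`.
#' @examples
#' clinical_scores(list(age = 50, bmi = 28, ast = 50, alt = 25,
#'   ast_uln = 40, platelets = 250, albumin = 40, bilirubin = 17.104,
#'   ifg_diabetes = 0))
#' @export
clinical_scores <- function(labs) {
  need <- c("age", "bmi", "ast", "alt", "ast_uln", "platelets", "albumin",
            "bilirubin", "ifg_diabetes")
  miss <- setdiff(need, names(labs))
  if (length(miss)) stop("missing lab fields: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  l <- lapply(labs[need], as.numeric)
  if (l$platelets <= 0 || l$alt <= 0 || l$ast_uln <= 0 || l$bilirubin <= 0)
    stop("platelets, ALT, AST ULN and bilirubin must be > 0", call. = FALSE)
  list(
    fib4 = l$age * l$ast / (l$platelets * sqrt(l$alt)),
    nfs = -1.675 + 0.037 * l$age + 0.094 * l$bmi + 1.13 * l$ifg_diabetes +
      0.99 * l$ast / l$alt - 0.013 * l$platelets - 0.66 * (l$albumin / 10),
    albi = 0.66 * log10(l$bilirubin) - 0.0852 * l$albumin,
    apri = (l$ast / l$ast_uln) * 100 / l$platelets
  )
}
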
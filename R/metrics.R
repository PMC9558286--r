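#' Median absolute error between two volumes
#'
#' The median of `|y - yhat|` over in-mask voxels: a local, outlier-robust
#' image-similarity summary for `[0,1]`-normalized images (lower is better).
#'
#' @param y,yhat [volume()]s (or 3D arrays) on the same grid.
#' @param mask binary array; defaults to `y`'s mask, else the full grid.
#' @return Scalar median absolute error.
#' @export
mae <- function(y, yhat, mask = NULL) {
  ya <- if (inherits(y, "ms_volume")) y$data else y
  ha <- if (inherits(yhat, "ms_volume")) yhat$data else yhat
  if (!identical(dim(ya), dim(ha))) stop("grid mismatch")
  m <- mask %||% (if (inherits(y, "ms_volume")) y$mask else NULL) %||% array(1, dim(ya))
  if (sum(m) == 0) stop("empty mask")
  median(abs(ya[m > 0] - ha[m > 0]))
}

#' SSIM stabilizing constants
#'
#' Defaults are the universal choices `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`,
#' `c3 = c2 / 2`, with dynamic range `L = 1` for `[0,1]` images.
#'
#' @param L dynamic range.
#' @param c1,c2,c3 overrides (all strictly positive).
#' @return A list of class `ssim_constants`.
#' @export
ssim_constants <- function(L = 1, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2,
                           c3 = c2 / 2) {
  stopifnot(c1 > 0, c2 > 0, c3 > 0, L > 0)
  structure(list(c1 = c1, c2 = c2, c3 = c3, L = L), class = "ssim_constants")
}

# the three SSIM factors from summary statistics
ssim_factors <- function(my, mh, sy, sh, cov_yh, k) {
  lum <- (2 * my * mh + k$c1) / (my^2 + mh^2 + k$c1)
  con <- (2 * sy * sh + k$c2) / (sy^2 + sh^2 + k$c2)
  str <- (cov_yh + k$c3) / (sy * sh + k$c3)
  lum * con * str
}

#' Structural similarity index (global, three-factor form)
#'
#' The product of luminance, contrast and structure-correlation factors
#' computed from the in-mask means, standard deviations and covariance:
#' a single global similarity score in `(-1, 1]`, 1 iff the images are
#' identical up to the stabilizers. A windowed variant (mean of the same
#' score over non-overlapping cubic windows) is available via `windowed`
#' as a local cross-check; the global form is the primary metric.
#'
#' @param y,yhat [volume()]s (or arrays) with intensities in `[0, 1]`.
#' @param mask binary array; defaults to `y`'s mask, else the full grid.
#' @param k an [ssim_constants()].
#' @param windowed `FALSE` (global, default) or a window side in voxels.
#' @return Scalar SSIM.
#' @export
ssim <- function(y, yhat, mask = NULL, k = ssim_constants(), windowed = FALSE) {
  ya <- if (inherits(y, "ms_volume")) y$data else y
  ha <- if (inherits(yhat, "ms_volume")) yhat$data else yhat
  if (!identical(dim(ya), dim(ha))) stop("grid mismatch")
  m <- mask %||% (if (inherits(y, "ms_volume")) y$mask else NULL) %||% array(1, dim(ya))
  if (!isFALSE(windowed)) {
    s <- as.integer(windowed)
    org <- patch_origins(dim(ya), s, s)
    vals <- c()
    for (i in seq_len(nrow(org))) {
      o <- org[i, ]
      idx <- list(o[1]:(o[1] + s - 1), o[2]:(o[2] + s - 1), o[3]:(o[3] + s - 1))
      mm <- m[idx[[1]], idx[[2]], idx[[3]]]
      if (mean(mm) < 0.5) next
      vals <- c(vals, ssim(ya[idx[[1]], idx[[2]], idx[[3]]],
                           ha[idx[[1]], idx[[2]], idx[[3]]], mask = mm, k = k))
    }
    if (!length(vals)) stop("no window with sufficient mask coverage")
    return(mean(vals))
  }
  sel <- m > 0
  if (sum(sel) < 2) stop("mask must contain at least 2 voxels")
  yv <- ya[sel]; hv <- ha[sel]
  n <- length(yv)
  my <- mean(yv); mh <- mean(hv)
  sy <- sqrt(sum((yv - my)^2) / (n - 1))
  sh <- sqrt(sum((hv - mh)^2) / (n - 1))
  cv <- sum((yv - my) * (hv - mh)) / (n - 1)
  ssim_factors(my, mh, sy, sh, cv, k)
}

#' Lesion-wise matching under the one-voxel-overlap rule
#'
#' A ground-truth component is a true positive if at least one of its voxels
#' overlaps any predicted component, else a false negative; a predicted
#' component overlapping no ground-truth component is a false positive.
#' `tp + fn` equals the number of ground-truth components.
#'
#' @param pred,gt integer component-labeled masks ([volume()]s from
#'   [postprocess()] or arrays; binary masks are component-labeled first).
#' @return List `(tp, fp, fn)`.
#' @export
match_lesions <- function(pred, gt) {
  pa <- if (inherits(pred, "ms_volume")) pred$data else pred
  ga <- if (inherits(gt, "ms_volume")) gt$data else gt
  if (!identical(dim(pa), dim(ga))) stop("grid mismatch")
  ensure_labeled <- function(a) {
    u <- unique(as.vector(a))
    if (all(u %in% c(0, 1))) cpp_label_components(a, 26L) else a
  }
  pa <- ensure_labeled(pa); ga <- ensure_labeled(ga)
  gl <- setdiff(unique(as.vector(ga)), 0)
  pl <- setdiff(unique(as.vector(pa)), 0)
  tp <- sum(vapply(gl, function(g) any(pa[ga == g] > 0), logical(1)))
  fn <- length(gl) - tp
  fp <- sum(vapply(pl, function(p) all(ga[pa == p] == 0), logical(1)))
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
}

#' Lesion-wise detection scores
#'
#' Sensitivity = TP/(TP+FN), FDR = FP/(FP+TP), Precision = TP/(TP+FP).
#' A ratio whose denominator is 0 is undefined and reported as `NA`
#' (e.g. sensitivity on a stable case); `precision = 1 - fdr` holds whenever
#' `tp + fp > 0`.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return A list of class `ms_scores` with the counts and the three ratios.
#' @export
detection_scores <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (fp + tp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens, fdr = fdr,
                 precision = prec), class = "ms_scores")
}

#' @export
print.ms_scores <- function(x, ...) {
  cat(sprintf("TP %d, FP %d, FN %d | sensitivity %s, FDR %s, precision %s\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$sensitivity), "undef", sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$fdr), "undef", sprintf("%.3f", x$fdr)),
              ifelse(is.na(x$precision), "undef", sprintf("%.3f", x$precision))))
  invisible(x)
}

#' Stable-case false-positive counting
#'
#' Over stable cases (no ground-truth lesions, `tp + fn = 0`): the number and
#' percentage (rounded to the nearest integer percent) of cases with at least
#' one false-positive component.
#'
#' @param scores list of `ms_scores` (or a data.frame with tp/fp/fn columns),
#'   restricted to stable cases.
#' @return List `(count, percent)`.
#' @export
fp_case_count <- function(scores) {
  if (inherits(scores, "data.frame")) {
    tp <- scores$tp; fp <- scores$fp; fn <- scores$fn
  } else {
    if (!length(scores)) stop("empty score list")
    tp <- vapply(scores, `[[`, numeric(1), "tp")
    fp <- vapply(scores, `[[`, numeric(1), "fp")
    fn <- vapply(scores, `[[`, numeric(1), "fn")
  }
  if (!length(tp)) stop("empty score list")
  if (any(tp + fn > 0)) stop("fp_case_count expects stable cases only (tp+fn = 0)")
  n <- length(fp)
  cnt <- sum(fp > 0)
  list(count = as.integer(cnt), percent = as.integer(round(100 * cnt / n)))
}

# exact two-sided signed-rank p-value with midranks, by dynamic programming
# over the (doubled) rank-sum distribution
exact_signrank_p <- function(d) {
  n <- length(d)
  r2 <- as.integer(round(2 * rank(abs(d))))
  v2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # distribution of sum of a random subset of r2 (each included w.p. 1/2)
  dist <- numeric(tot + 1)
  dist[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), dist[seq_len(tot + 1 - w)])
    dist <- dist + shifted
  }
  dist <- dist / 2^n
  pless <- sum(dist[seq_len(v2 + 1)])
  pgreater <- sum(dist[(v2 + 1):(tot + 1)])
  min(1, 2 * min(pless, pgreater))
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided signed-rank test on paired per-case scores. Undefined scores
#' (`NA`, e.g. sensitivity on stable cases) are dropped pairwise; zero
#' differences are dropped; the exact distribution (with midranks under ties)
#' is used for n <= 25 remaining pairs and the normal approximation with tie
#' correction and continuity correction otherwise. When every difference is
#' zero the p-value 1 is returned with attribute `degenerate = TRUE`.
#'
#' @param scores_a,scores_b numeric vectors of equal length, paired by case.
#' @param min_pairs minimum usable pairs required (default 6; smaller paired
#'   sets carry almost no power but remain computable when lowered).
#' @return The two-sided p-value, with attributes `n_effective` and
#'   `statistic` (the positive-rank sum V).
#' @export
compare_models <- function(scores_a, scores_b, min_pairs = 6L) {
  if (length(scores_a) != length(scores_b)) stop("paired vectors must match in length")
  keep <- !(is.na(scores_a) | is.na(scores_b))
  a <- scores_a[keep]; b <- scores_b[keep]
  if (length(a) < min_pairs) stop("need at least ", min_pairs, " paired cases")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    attr(p, "n_effective") <- 0L
    return(p)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    p <- exact_signrank_p(d)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- v - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
  }
  attr(p, "n_effective") <- n
  attr(p, "statistic") <- v
  p
}

#' Score one case lesion-wise
#'
#' Convenience wrapper: component-labels the binary ground truth, matches it
#' against a predicted component map and returns the detection scores.
#'
#' @param pred_labels labeled prediction ([postprocess()] output).
#' @param gt_mask binary ground-truth [volume()] or array.
#' @return An `ms_scores`.
#' @export
score_case <- function(pred_labels, gt_mask) {
  m <- match_lesions(pred_labels, gt_mask)
  detection_scores(m$tp, m$fp, m$fn)
}
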
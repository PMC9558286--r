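#' FLAIR intensity clustering (generator conditioning input)
#'
#' Clusters in-mask intensities into `c` classes with a 1D Gaussian-mixture
#' EM (k-means++ initialization, 5 restarts, best likelihood kept, variance
#' floor), optionally followed by `smoothing` iterations of 26-neighbourhood
#' mode filtering of the label map within the mask. Labels are re-indexed so
#' cluster means ascend: channel 0 is always the darkest cluster, which keeps
#' the conditioning semantics stable across images — a prerequisite for the
#' synthesis model to transfer between cases. Mixture parameters are fitted
#' on a seeded subsample of at most 8000 in-mask voxels; the final
#' max-posterior assignment covers every in-mask voxel.
#'
#' Typical cluster counts are 3 (CSF/GM/WM), 5, 7 or 9, the larger values
#' capturing partial-volume shells at tissue interfaces; any `c >= 2` is
#' accepted with a warning. An externally computed label map (e.g. from a
#' dedicated tissue-segmentation tool) can be supplied via `labels` and is
#' wrapped verbatim.
#'
#' @param vol a [volume()] with non-empty mask.
#' @param c number of clusters.
#' @param smoothing non-negative integer, mode-filter iterations.
#' @param seed integer seed (initialization).
#' @param max_iter,tol EM stopping rule.
#' @param labels optional precomputed integer label [volume()] (plug-in path);
#'   values 0..c-1 in-mask.
#' @return An object of class `ms_clustermap` with fields `labels` (integer
#'   [volume()], background sentinel -1), `c`, `means`, `sds`, `mixing`.
#' @export
cluster_intensities <- function(vol, c, smoothing = 0L, seed = 1L,
                                max_iter = 100L, tol = 1e-8, labels = NULL) {
  if (is.null(vol$mask) || sum(vol$mask) == 0) stop("non-empty mask required")
  c <- as.integer(c)
  if (c < 2) stop("c must be >= 2")
  if (!c %in% c(3L, 5L, 7L, 9L))
    warning("cluster count ", c, " outside the usual {3,5,7,9}")
  msel <- vol$mask > 0
  x <- vol$data[msel]
  if (!is.null(labels)) {
    lab_in <- as.integer(labels$data[msel])
    return(finalize_clustermap(vol, lab_in, c, msel, smoothing = 0L))
  }
  if (length(unique(x)) < c) stop("fewer than c distinct in-mask intensities")
  fit <- with_seed(seed, {
    xs <- if (length(x) > 8000) sample(x, 8000) else x
    best <- NULL
    for (r in 1:5) {
      f <- gmm1d_em(xs, c, max_iter, tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best
  })
  # hard assignment of every in-mask voxel by max posterior
  post <- posterior1d(x, fit)
  lab_in <- max.col(post, ties.method = "first") - 1L
  finalize_clustermap(vol, lab_in, c, msel, smoothing, fit)
}

# canonical ordering + smoothing + summaries
finalize_clustermap <- function(vol, lab_in, c, msel, smoothing, fit = NULL) {
  x <- vol$data[msel]
  means_raw <- vapply(0:(c - 1), function(k) {
    if (any(lab_in == k)) mean(x[lab_in == k]) else Inf
  }, numeric(1))
  ord <- order(means_raw)
  remap <- integer(c); remap[ord] <- 0:(c - 1)
  lab_in <- remap[lab_in + 1L]
  lab <- array(-1L, dim(vol$data))
  lab[msel] <- lab_in
  if (smoothing > 0)
    lab <- cpp_mode_filter(lab, vol$mask, as.integer(smoothing), c)
  lab_in <- lab[msel]
  if (!all(0:(c - 1) %in% lab_in))
    warning("some cluster labels are unoccupied after smoothing")
  means <- vapply(0:(c - 1), function(k) mean(x[lab_in == k]), numeric(1))
  sds <- vapply(0:(c - 1), function(k) {
    v <- x[lab_in == k]; if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  mixing <- vapply(0:(c - 1), function(k) mean(lab_in == k), numeric(1))
  structure(list(labels = volume(array(as.double(lab), dim(lab)),
                                 spacing = vol$spacing, affine = vol$affine,
                                 mask = vol$mask),
                 c = c, means = means, sds = sds, mixing = mixing,
                 em = if (!is.null(fit)) fit[c("means", "sds", "mixing", "loglik")]),
            class = "ms_clustermap")
}

#' @export
print.ms_clustermap <- function(x, ...) {
  cat(sprintf("<ClusterMap c=%d>\n", x$c))
  print(data.frame(label = 0:(x$c - 1), mean = signif(x$means, 4),
                   sd = signif(x$sds, 4), mixing = signif(x$mixing, 4)))
  invisible(x)
}

# k-means++ initialized 1D Gaussian mixture EM; variance floor applied
gmm1d_em <- function(x, c, max_iter = 100L, tol = 1e-8, var_floor = 1e-6) {
  n <- length(x)
  # k-means++ seeding
  ctrs <- numeric(c)
  ctrs[1] <- x[sample.int(n, 1)]
  d2 <- (x - ctrs[1])^2
  for (k in 2:c) {
    p <- d2 / sum(d2)
    ctrs[k] <- x[sample.int(n, 1, prob = p)]
    d2 <- pmin(d2, (x - ctrs[k])^2)
  }
  mu <- sort(ctrs)
  sg <- rep(sd(x) / c, c)
  pi_k <- rep(1 / c, c)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:c, function(k) pi_k[k] * stats::dnorm(x, mu[k], sg[k]), numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(resp * x) / nk
    sg <- sqrt(pmax(colSums(resp * (outer(x, mu, `-`))^2) / nk, var_floor))
    pi_k <- nk / n
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(means = mu, sds = sg, mixing = pi_k, loglik = ll)
}

posterior1d <- function(x, fit) {
  c <- length(fit$means)
  dens <- vapply(1:c, function(k)
    fit$mixing[k] * stats::dnorm(x, fit$means[k], fit$sds[k]), numeric(length(x)))
  dens / pmax(rowSums(dens), 1e-300)
}

#' One-hot encoding of a cluster map
#'
#' Channel `k` is the indicator of label `k`; channels sum to 1 inside the
#' mask and are 0 outside. This is the c-channel conditioning input of the
#' synthesis generator.
#'
#' @param cm an `ms_clustermap`.
#' @return A 4D array `(D, H, W, c)`.
#' @export
one_hot <- function(cm) {
  lab <- cm$labels$data
  d <- dim(lab)
  out <- array(0, c(d, cm$c))
  for (k in 0:(cm$c - 1)) out[, , , k + 1] <- (lab == k) * 1
  out
}

#' Per-voxel cluster-mean image
#'
#' Replaces every in-mask voxel by its cluster's mean intensity: the
#' piecewise-constant approximation of the clustered image. Used as a
#' reference baseline when judging synthesis quality.
#'
#' @param cm an `ms_clustermap`.
#' @return A [volume()].
#' @export
cluster_mean_image <- function(cm) {
  lab <- cm$labels$data
  img <- array(0, dim(lab))
  for (k in 0:(cm$c - 1)) img[lab == k] <- cm$means[k + 1]
  volume(img, spacing = cm$labels$spacing, affine = cm$labels$affine,
         mask = cm$labels$mask)
}
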
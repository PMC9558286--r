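#' Affine transform between volume grids
#'
#' A 4x4 homogeneous map between 0-based voxel coordinates of two grids:
#' `matrix` maps coordinates of the `from` space to coordinates of the
#' `to` (fixed) space. Last row must be `(0,0,0,1)` and the matrix invertible.
#'
#' @param matrix 4x4 homogeneous matrix.
#' @param from,to optional space identifiers used to catch composition errors.
#' @return An object of class `ms_affine`.
#' @export
affine_transform <- function(matrix, from = "", to = "") {
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (!isTRUE(all.equal(matrix[4, ], c(0, 0, 0, 1))))
    stop("last row of an affine transform must be (0,0,0,1)")
  if (abs(det(matrix)) < 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, from = from, to = to), class = "ms_affine")
}

#' @export
print.ms_affine <- function(x, ...) {
  cat(sprintf("<AffineTransform %s -> %s>\n", x$from, x$to))
  print(signif(x$matrix, 4))
  invisible(x)
}

# Build an affine from a parameter vector.
# translation: (tx,ty,tz); rigid: + rotations (rad) about `center`;
# affine: + log-scales (3) and shears (3).
affine_from_params <- function(params, dof = c("translation", "rigid", "affine"),
                               center = c(0, 0, 0)) {
  dof <- match.arg(dof)
  t <- params[1:3]
  M <- diag(3)
  if (dof != "translation") {
    a <- params[4:6]
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
    Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
    M <- Rz %*% Ry %*% Rx
  }
  if (dof == "affine") {
    s <- exp(params[7:9])
    sh <- params[10:12]
    S <- diag(s)
    Sh <- diag(3); Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
    M <- M %*% Sh %*% S
  }
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- center - M %*% center + t
  affine_transform(A)
}

n_params <- function(dof) switch(dof, translation = 3L, rigid = 6L, affine = 12L)

#' Compose two affine transforms
#'
#' `compose(a, b)` with `a: X -> Y` and `b: Y -> Z` yields the single
#' transform `X -> Z`; applying the composition equals applying `a` then `b`.
#' Used to carry the baseline image to template space through the follow-up
#' registration in one interpolation.
#'
#' @param a,b [affine_transform()]s.
#' @return An [affine_transform()].
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "ms_affine"), inherits(b, "ms_affine"))
  if (nzchar(a$to) && nzchar(b$from) && !identical(a$to, b$from))
    stop("space mismatch: cannot compose ", a$to, " with ", b$from)
  affine_transform(b$matrix %*% a$matrix, from = a$from, to = b$to)
}

#' Resample a volume through an affine transform
#'
#' Samples `vol` on the grid of `target_grid` through `t` (which maps `vol`'s
#' voxel space to the target's). Linear interpolation for intensities,
#' nearest for label/mask volumes; out-of-field voxels are set to 0. The
#' attached mask, when present, is carried along with nearest interpolation.
#'
#' @param vol the moving [volume()].
#' @param t an [affine_transform()] mapping `vol` to `target_grid`.
#' @param target_grid a [volume()] defining the output grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return A [volume()] on the target grid.
#' @export
resample <- function(vol, t, target_grid, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  inv <- solve(t$matrix) # target voxel -> source voxel
  out <- cpp_resample_affine(vol$data, inv, dim(target_grid$data),
                             if (interpolation == "nearest") 0L else 1L)
  msk <- NULL
  if (!is.null(vol$mask))
    msk <- cpp_resample_affine(vol$mask, inv, dim(target_grid$data), 0L)
  volume(out, spacing = target_grid$spacing, affine = target_grid$affine, mask = msk)
}

# masked MSE between fixed and moving-resampled-through-params
reg_objective <- function(params, dof, moving, fixed, mmask, fmask, center) {
  t <- affine_from_params(params, dof, center)
  inv <- solve(t$matrix)
  warped <- cpp_resample_affine(moving, inv, dim(fixed), 1L)
  wmask <- cpp_resample_affine(mmask, inv, dim(fixed), 0L)
  sel <- fmask > 0 & wmask > 0
  if (!any(sel)) return(mean((fixed - warped)^2) + 10) # heavily penalized fallback
  mean((fixed[sel] - warped[sel])^2)
}

#' Affine registration by multi-resolution optimization
#'
#' Estimates the affine transform carrying `moving` onto `fixed` by
#' minimizing the mean squared intensity difference within the intersected
#' brain masks, with a coarse-to-fine grid pyramid and Nelder-Mead
#' optimization. Intended for mono-modal alignment (e.g. baseline to
#' follow-up before new-lesion detection). Deterministic given the inputs.
#'
#' @param moving,fixed [volume()]s; masks are used when present, otherwise
#'   the full grid is taken as mask.
#' @param dof `"translation"`, `"rigid"` (default) or `"affine"`.
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit optimizer iteration budget per level.
#' @return An [affine_transform()] mapping moving voxel coordinates to fixed
#'   voxel coordinates, with attributes `objective_before`/`objective_after`
#'   and `converged`.
#' @export
affine_register <- function(moving, fixed, dof = c("rigid", "translation", "affine"),
                            levels = c(4L, 2L), maxit = 300L) {
  dof <- match.arg(dof)
  mmask <- moving$mask %||% array(1, dim(moving$data))
  fmask <- fixed$mask %||% array(1, dim(fixed$data))
  if (identical(dim(mmask), dim(fmask)) && !any(mmask > 0 & fmask > 0))
    stop("no overlap between moving and fixed masks")
  center <- (dim(fixed$data) - 1) / 2
  params <- numeric(n_params(dof))
  obj0 <- reg_objective(params, dof, moving$data, fixed$data, mmask, fmask, center)
  scale_mat <- function(f) { # full-res voxel -> level-f voxel (block-mean aligned)
    S <- diag(4)
    S[1:3, 1:3] <- diag(3) / f
    S[1:3, 4] <- -(f - 1) / (2 * f)
    S
  }
  converged <- TRUE
  for (f in c(as.integer(levels), 1L)) {
    if (f > 1L) {
      mv <- cpp_block_mean(moving$data, f); fx <- cpp_block_mean(fixed$data, f)
      mm <- (cpp_block_mean(mmask, f) > 0.5) * 1; fm <- (cpp_block_mean(fmask, f) > 0.5) * 1
    } else {
      mv <- moving$data; fx <- fixed$data; mm <- mmask; fm <- fmask
    }
    S <- scale_mat(f)
    obj_f <- function(p) {
      # evaluate the full-resolution transform on the level-f grids
      t_full <- affine_from_params(p, dof, center)$matrix
      t_lvl <- S %*% t_full %*% solve(S)
      warped <- cpp_resample_affine(mv, solve(t_lvl), dim(fx), 1L)
      wmask <- cpp_resample_affine(mm, solve(t_lvl), dim(fx), 0L)
      sel <- fm > 0 & wmask > 0
      if (!any(sel)) return(mean((fx - warped)^2) + 10)
      mean((fx[sel] - warped[sel])^2)
    }
    scale_par <- c(rep(1, 3), rep(0.02, max(0, n_params(dof) - 3)))
    opt <- optim(params, obj_f, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = scale_par,
                                reltol = 1e-9))
    if (opt$convergence != 0 && f == 1L) converged <- FALSE
    params <- opt$par
  }
  obj1 <- reg_objective(params, dof, moving$data, fixed$data, mmask, fmask, center)
  if (obj1 > obj0) { # optimizer made things worse: fall back to identity, flagged
    params <- numeric(n_params(dof))
    obj1 <- obj0
    converged <- FALSE
  }
  t <- affine_from_params(params, dof, center)
  attr(t, "objective_before") <- obj0
  attr(t, "objective_after") <- obj1
  attr(t, "converged") <- converged
  attr(t, "params") <- params
  t
}

# Three-class Otsu (two thresholds) on a 256-bin histogram; returns the pair
# sorted ascending. The lower threshold separates air from the darkest tissue
# (CSF), which a two-class split merges with the background when the brain's
# own intensity spread dominates the between-class variance.
otsu_thresholds2 <- function(x) {
  brk <- seq(min(x), max(x), length.out = 257)
  cnt <- tabulate(findInterval(x, brk, all.inside = TRUE), nbins = 256)
  w <- cnt / sum(cnt)
  mids <- (brk[-1] + brk[-257]) / 2
  cw <- c(0, cumsum(w)); cm <- c(0, cumsum(w * mids))
  cls <- function(a, b) { # class mass and variance contribution over bins a..b
    wk <- cw[b + 1] - cw[a]
    if (wk < 1e-12) return(NA_real_)
    mk <- (cm[b + 1] - cm[a]) / wk
    wk * mk^2
  }
  best <- -Inf; t1 <- 1L; t2 <- 2L
  for (i in 1:254) {
    s1 <- cls(1, i)
    if (is.na(s1)) next
    for (j in (i + 1):255) {
      s2 <- cls(i + 1, j); s3 <- cls(j + 1, 256)
      if (is.na(s2) || is.na(s3)) next
      v <- s1 + s2 + s3
      if (v > best) { best <- v; t1 <- i; t2 <- j }
    }
  }
  c(brk[t1 + 1], brk[t2 + 1])
}

#' Brain extraction (skull stripping)
#'
#' Built-in implementation: three-class Otsu intensity thresholds (air / dark
#' tissue / bright tissue), mask above the lower threshold, largest
#' 26-connected component, one pass of morphological closing. Two-class Otsu
#' merges CSF with the air background whenever the brain's internal contrast
#' dominates the between-class variance, so the three-class split is used and
#' the air/tissue boundary taken. The contract also accepts a precomputed mask
#' (e.g. from an external brain-extraction tool), which is returned verbatim,
#' so external tools plug in without code changes.
#'
#' @param vol a [volume()].
#' @param mask optional precomputed binary mask [volume()] (plug-in path).
#' @return A binary mask [volume()].
#' @export
skull_strip <- function(vol, mask = NULL) {
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), dim(vol$data))) stop("supplied mask grid mismatch")
    return(mask)
  }
  x <- vol$data
  if (all(x == x[1])) stop("empty mask after thresholding (constant image)")
  thr <- otsu_thresholds2(as.vector(x))[1]
  bin <- (x > thr) * 1
  if (sum(bin) == 0) stop("empty mask after thresholding")
  lab <- cpp_label_components(bin, 26L)
  n <- attr(lab, "n_components")
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which.max(sizes)
  m <- (lab == keep) * 1
  m <- cpp_minmax_filter(m, TRUE)   # dilate
  m <- cpp_minmax_filter(m, FALSE)  # erode (closing)
  volume((m > 0.5) * 1, spacing = vol$spacing, affine = vol$affine)
}

#' Normalize in-mask intensities to [0, 1]
#'
#' Maps `(x - p_lo) / (p_hi - p_lo)` and clips to `[0, 1]`, where `p_lo` and
#' `p_hi` are in-mask percentiles (defaults 1st and 99th); out-of-mask voxels
#' are set to 0. Percentile clipping makes the mapping robust to intensity
#' outliers. Idempotent up to clipping.
#'
#' @param vol a [volume()] with a non-empty mask.
#' @param pct_lo,pct_hi percentile bounds in `[0, 100]`.
#' @return A [volume()] with in-mask intensities in `[0, 1]`.
#' @export
normalize01 <- function(vol, pct_lo = 1, pct_hi = 99) {
  if (is.null(vol$mask) || sum(vol$mask) == 0) stop("mask present and non-empty required")
  x <- vol$data
  v <- x[vol$mask > 0]
  p <- quantile(v, c(pct_lo, pct_hi) / 100, names = FALSE, type = 7)
  if (p[2] <= p[1]) stop("constant in-mask image: cannot normalize")
  y <- (x - p[1]) / (p[2] - p[1])
  y[y < 0] <- 0; y[y > 1] <- 1
  y <- y * vol$mask
  volume(y, spacing = vol$spacing, affine = vol$affine, mask = vol$mask)
}

#' Preprocess a longitudinal case
#'
#' The standard chain before synthesis/detection: the follow-up is registered
#' to the template (identity when the follow-up grid itself acts as template,
#' the default for phantoms), the baseline is registered to the follow-up and
#' carried to template space through the composed transform in a single
#' interpolation, masks are attached (computed by [skull_strip()] unless
#' already present), and all volumes are intensity-normalized to [0, 1].
#'
#' @param case an `ms_case`.
#' @param template optional template [volume()]; `NULL` uses the follow-up grid.
#' @param dof registration degrees of freedom (see [affine_register()]).
#' @return An `ms_case` with preprocessed volumes; the transforms used are
#'   attached as attribute `transforms`.
#' @export
preprocess_case <- function(case, template = NULL, dof = "rigid") {
  fu <- case$followup
  bl <- case$baseline
  ensure_mask <- function(v) { if (is.null(v$mask)) v$mask <- skull_strip(v)$data; v }
  fu <- lapply(fu, ensure_mask)
  bl <- lapply(bl, ensure_mask)
  t_fu <- if (is.null(template)) {
    affine_transform(diag(4), from = "followup", to = "template")
  } else {
    affine_register(fu[["FLAIR"]], template, dof = dof)
  }
  tgt <- template %||% fu[["FLAIR"]]
  t_bl2fu <- affine_register(bl[["FLAIR"]], fu[["FLAIR"]], dof = dof)
  t_bl2fu$to <- "followup"; t_fu$from <- "followup"
  t_bl <- compose(t_bl2fu, t_fu)
  fu_out <- lapply(fu, function(v) {
    out <- if (is.null(template)) v else resample(v, t_fu, tgt)
    normalize01(out)
  })
  bl_out <- lapply(bl, function(v) normalize01(resample(v, t_bl, tgt)))
  msk <- case$new_lesion_mask
  if (!is.null(msk) && !is.null(template)) msk <- resample(msk, t_fu, tgt, "nearest")
  out <- longitudinal_case(case$case_id, bl_out, fu_out, msk)
  attr(out, "transforms") <- list(followup_to_template = t_fu,
                                  baseline_to_template = t_bl,
                                  baseline_to_followup = t_bl2fu)
  out
}
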
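# Patch tiling: regular stride lattices clipped to fit the grid, extraction
# with an optional in-mask filter, and overlap-aware reassembly with a
# separable Hann window (a partition of unity after weight normalisation, so
# constants are conserved).

#' Patch origin lattice
#'
#' Origins along one axis: `seq(1, n - size + 1, by = stride)`, with the final
#' origin `n - size + 1` appended when the lattice does not already reach it,
#' so the whole volume is covered.
#'
#' @param dims integer grid size.
#' @param size patch side.
#' @param stride lattice step.
#' @return Matrix with one row per origin (1-based voxel coordinates).
#' @export
patch_origins <- function(dims, size, stride) {
  if (any(dims < size)) stop("grid smaller than patch")
  ax <- lapply(dims, function(n) {
    o <- seq(1L, n - size + 1L, by = stride)
    if (o[length(o)] != n - size + 1L) o <- c(o, n - size + 1L)
    o
  })
  as.matrix(expand.grid(d = ax[[1]], h = ax[[2]], w = ax[[3]]))
}

#' Extract training patches
#'
#' Cuts `size`^3 patches from a multi-channel input and its single-channel
#' target on a regular stride lattice. With `mask` given, patches whose brain
#' fraction is below `min_mask_frac` are dropped.
#'
#' @param channels 4D array `(D,H,W,C)` of input channels.
#' @param target a [volume()] (the synthesis target) or `NULL`.
#' @param size patch side (default 32).
#' @param stride lattice step (default = size).
#' @param mask optional 3D binary array.
#' @param min_mask_frac minimum in-mask voxel fraction to keep a patch.
#' @return List with `origins` (matrix), `x` (list of `(size^3, C)` arrays) and
#'   `y` (list of 3D arrays or NULL).
#' @export
extract_patches <- function(channels, target = NULL, size = 32L, stride = size,
                            mask = NULL, min_mask_frac = 0) {
  d <- dim(channels)[1:3]
  org <- patch_origins(d, size, stride)
  keep <- rep(TRUE, nrow(org))
  if (!is.null(mask) && min_mask_frac > 0) {
    for (i in seq_len(nrow(org))) {
      o <- org[i, ]
      frac <- mean(mask[o[1]:(o[1] + size - 1), o[2]:(o[2] + size - 1),
                        o[3]:(o[3] + size - 1)])
      keep[i] <- frac >= min_mask_frac
    }
  }
  org <- org[keep, , drop = FALSE]
  xs <- lapply(seq_len(nrow(org)), function(i) {
    o <- org[i, ]
    channels[o[1]:(o[1] + size - 1), o[2]:(o[2] + size - 1),
             o[3]:(o[3] + size - 1), , drop = FALSE]
  })
  ys <- if (!is.null(target)) {
    tv <- if (inherits(target, "ms_volume")) target$data else target
    lapply(seq_len(nrow(org)), function(i) {
      o <- org[i, ]
      tv[o[1]:(o[1] + size - 1), o[2]:(o[2] + size - 1), o[3]:(o[3] + size - 1)]
    })
  }
  list(origins = org, x = xs, y = ys, size = size)
}

# strictly positive Hann-like window so every covered voxel has weight
hann_window3 <- function(size) {
  w1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(size) - 0.5) / size)
  outer(outer(w1, w1), w1)
}

#' Reassemble patch predictions into a volume
#'
#' Accumulates windowed patch values and window weights on the full grid and
#' divides; the normalised weights form a partition of unity over the covered
#' volume, so a constant field reassembles to the same constant.
#'
#' @param patches list of 3D arrays (one per origin).
#' @param origins matrix from [patch_origins()].
#' @param dims output grid size.
#' @param window `"hann"` (overlapping tiles) or `"uniform"`.
#' @return 3D array.
#' @export
reassemble_patches <- function(patches, origins, dims, window = c("hann", "uniform")) {
  window <- match.arg(window)
  size <- dim(patches[[1]])[1]
  w <- if (window == "hann") hann_window3(size) else array(1, rep(size, 3))
  acc <- array(0, dims)
  wacc <- array(0, dims)
  for (i in seq_along(patches)) {
    o <- origins[i, ]
    di <- o[1]:(o[1] + size - 1); hi <- o[2]:(o[2] + size - 1); wi <- o[3]:(o[3] + size - 1)
    acc[di, hi, wi] <- acc[di, hi, wi] + patches[[i]] * w
    wacc[di, hi, wi] <- wacc[di, hi, wi] + w
  }
  out <- acc
  pos <- wacc > 0
  out[pos] <- acc[pos] / wacc[pos]
  out
}

# Apply a patchwise network over a whole multi-channel volume with stride-16
# tiling and Hann blending. `fwd1` maps a (size,size,size,C,N) batch to a
# (size,size,size,1,N) prediction.
apply_patchwise <- function(channels, fwd1, size = 32L, stride = 16L,
                            batch = 8L) {
  d <- dim(channels)[1:3]
  C <- dim(channels)[4]
  org <- patch_origins(d, size, stride)
  preds <- vector("list", nrow(org))
  i <- 1L
  while (i <= nrow(org)) {
    j <- min(i + batch - 1L, nrow(org))
    nb <- j - i + 1L
    xb <- array(0, c(size, size, size, C, nb))
    for (k in seq_len(nb)) {
      o <- org[i + k - 1L, ]
      xb[, , , , k] <- channels[o[1]:(o[1] + size - 1), o[2]:(o[2] + size - 1),
                                o[3]:(o[3] + size - 1), , drop = FALSE]
    }
    yb <- fwd1(xb)
    for (k in seq_len(nb)) preds[[i + k - 1L]] <- array(yb[, , , 1, k], rep(size, 3))
    i <- j + 1L
  }
  reassemble_patches(preds, org, d, window = "hann")
}
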
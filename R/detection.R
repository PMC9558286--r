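#' Deformation field
#'
#' A per-voxel displacement vector field in voxel units: channel `a` holds the
#' displacement along grid axis `a`. Warping samples the moving volume at
#' `v + displacement(v)`.
#'
#' @param displacement 4D array `(D, H, W, 3)`.
#' @return An object of class `ms_deform`.
#' @export
deformation_field <- function(displacement) {
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L) stop("displacement must be (D,H,W,3)")
  structure(list(displacement = displacement), class = "ms_deform")
}

#' Warp a volume by a deformation field
#'
#' Output voxel `v` is the trilinear sample of `vol` at `v + displacement(v)`;
#' out-of-field samples are 0.
#'
#' @param vol a [volume()].
#' @param field an [deformation_field()] on the same grid.
#' @return A warped [volume()].
#' @export
warp <- function(vol, field) {
  if (!identical(dim(vol$data), dim(field$displacement)[1:3]))
    stop("grid mismatch between volume and deformation field")
  out <- cpp_warp(vol$data, field$displacement)
  volume(out, spacing = vol$spacing, affine = vol$affine, mask = vol$mask)
}

#' Unsupervised registration loss
#'
#' Masked mean squared intensity difference between the warped baseline and
#' the fixed follow-up, plus `lambda` times the smoothness penalty: the sum
#' over displacement channels and axes of the mean squared forward-difference
#' spatial gradient.
#'
#' @param warped,fixed [volume()]s on the same grid.
#' @param field the [deformation_field()] that produced `warped`.
#' @param lambda smoothness weight (>= 0).
#' @param mask optional binary array; defaults to `fixed`'s mask or full grid.
#' @return Scalar loss with attributes `similarity` and `smoothness`.
#' @export
registration_loss <- function(warped, fixed, field, lambda = 1, mask = NULL) {
  m <- mask %||% fixed$mask %||% array(1, dim(fixed$data))
  if (sum(m) == 0) stop("empty mask")
  sim <- mean(((warped$data - fixed$data)[m > 0])^2)
  disp5 <- array(field$displacement, c(dim(field$displacement), 1))
  smo <- ag_smoothness(ag_const(disp5))$value
  out <- sim + lambda * smo
  attr(out, "similarity") <- sim
  attr(out, "smoothness") <- smo
  out
}

#' Detection model configuration
#'
#' @param modalities character subset of `c("FLAIR", "T1", "T1S")`; FLAIR is
#'   always required. Each modality contributes one registration sub-network
#'   and two segmentation input channels (warped baseline + follow-up).
#' @param patch_size,patch_stride training patch geometry (32 / 16).
#' @param lambda displacement smoothness weight.
#' @param width,depth U-Net width/depth for both sub-networks.
#' @param lesion_weight positive-class weight in the segmentation
#'   cross-entropy (new-lesion voxels are ~0.1% of patch voxels).
#' @param lr Adam learning rate.
#' @param n_steps,batch_size training budget.
#' @param min_mask_frac patch brain-fraction filter.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(modalities = "FLAIR", patch_size = 32L,
                             patch_stride = 16L, lambda = 1, width = 4L,
                             depth = 3L, lesion_weight = 30, lr = 1e-3,
                             n_steps = 300L, batch_size = 2L,
                             min_mask_frac = 0.05) {
  if (!"FLAIR" %in% modalities) stop("FLAIR must be included in modalities")
  if (!all(modalities %in% c("FLAIR", "T1", "T1S"))) stop("unknown modality")
  structure(as.list(environment()), class = "detection_config")
}

#' Build an (untrained) new-lesion detection model
#'
#' Per modality, a 3D U-Net maps the (baseline, follow-up) patch pair to a
#' deformation-field patch; the warped baselines and follow-ups of all
#' modalities are concatenated into a second 3D U-Net producing a 2-class
#' voxel probability map. Both sub-networks share one computation graph, so
#' gradients flow end-to-end. Registration final convolutions are zero-
#' initialized (training starts from the identity deformation).
#'
#' @param cfg a [detection_config()].
#' @param seed initialization seed.
#' @return An object of class `ms_detector`.
#' @export
build_detection_model <- function(cfg, seed = 1L) {
  if (!length(cfg$modalities)) stop("empty modality set")
  regs <- list()
  for (i in seq_along(cfg$modalities))
    regs[[cfg$modalities[i]]] <- unet_init(2L, 3L, cfg$width, cfg$depth,
                                           derive_seed(seed, 10 + i),
                                           zero_final = TRUE)
  seg <- unet_init(2L * length(cfg$modalities), 2L, cfg$width, cfg$depth,
                   derive_seed(seed, 20))
  structure(list(regs = regs, seg = seg, config = cfg, history = NULL,
                 provenance = list(seed = seed)),
            class = "ms_detector")
}

# gather per-case arrays for training/inference
case_arrays <- function(case, modalities) {
  bl <- lapply(modalities, function(m) {
    v <- case$baseline[[m]]
    if (is.null(v)) stop("case ", case$case_id, " lacks baseline ", m)
    v$data
  })
  fu <- lapply(modalities, function(m) {
    v <- case$followup[[m]]
    if (is.null(v)) stop("case ", case$case_id, " lacks follow-up ", m)
    v$data
  })
  names(bl) <- names(fu) <- modalities
  msk <- case$followup[["FLAIR"]]$mask %||% array(1, dim(fu[[1]]))
  les <- if (!is.null(case$new_lesion_mask)) case$new_lesion_mask$data
         else array(0, dim(fu[[1]]))
  list(bl = bl, fu = fu, mask = msk, les = les, dims = dim(fu[[1]]))
}

slice_patch <- function(a, o, s) a[o[1]:(o[1] + s - 1), o[2]:(o[2] + s - 1),
                                   o[3]:(o[3] + s - 1)]

#' Train the new-lesion detector end-to-end
#'
#' Minimizes the sum over modalities of the unsupervised registration loss
#' (masked MSE + `lambda` x displacement smoothness) plus the voxelwise
#' segmentation cross-entropy against the new-lesion ground truth, over
#' 32^3 / stride-16 patches with Adam. Lesion-containing patches are
#' oversampled to 50% of each batch. Fully seeded.
#'
#' @param cases list of preprocessed `ms_case`s with the configured
#'   modalities at both timepoints plus `new_lesion_mask`.
#' @param config a [detection_config()].
#' @param seed master seed.
#' @param model optional pre-built [build_detection_model()] to continue.
#' @return A trained `ms_detector` with a `history` data.frame (per-step
#'   cross-entropy, similarity and smoothness terms).
#' @export
detector_fit <- function(cases, config = detection_config(), seed = 1L,
                         model = NULL) {
  cfg <- config
  model <- model %||% build_detection_model(cfg, derive_seed(seed, 1))
  dat <- lapply(cases, case_arrays, modalities = cfg$modalities)
  s <- cfg$patch_size
  # per-case origin lattices, split by lesion content
  les_org <- list(); bg_org <- list()
  for (ci in seq_along(dat)) {
    org <- patch_origins(dat[[ci]]$dims, s, cfg$patch_stride)
    keep <- vapply(seq_len(nrow(org)), function(i)
      mean(slice_patch(dat[[ci]]$mask, org[i, ], s)) >= cfg$min_mask_frac, logical(1))
    org <- org[keep, , drop = FALSE]
    hasles <- vapply(seq_len(nrow(org)), function(i)
      sum(slice_patch(dat[[ci]]$les, org[i, ], s)) > 0, logical(1))
    les_org[[ci]] <- org[hasles, , drop = FALSE]
    bg_org[[ci]] <- org[!hasles, , drop = FALSE]
  }
  n_les_total <- sum(vapply(les_org, nrow, numeric(1)))
  if (n_les_total == 0)
    warning("no case contains any lesion voxel; training on stable cases only")
  les_tab <- do.call(rbind, lapply(seq_along(les_org), function(ci)
    if (nrow(les_org[[ci]])) cbind(ci, les_org[[ci]])))
  bg_tab <- do.call(rbind, lapply(seq_along(bg_org), function(ci)
    if (nrow(bg_org[[ci]])) cbind(ci, bg_org[[ci]])))
  mods <- cfg$modalities
  nm <- length(mods)
  opt_reg <- lapply(model$regs, function(r) adam_state(r$params))
  opt_seg <- adam_state(model$seg$params)
  hist <- matrix(NA_real_, cfg$n_steps, 3,
                 dimnames = list(NULL, c("ce", "similarity", "smoothness")))
  with_seed(derive_seed(seed, 2), {
    for (step in seq_len(cfg$n_steps)) {
      nles <- if (!is.null(les_tab)) min(ceiling(cfg$batch_size / 2), nrow(les_tab)) else 0L
      nbg <- cfg$batch_size - nles
      pick <- rbind(
        if (nles > 0) les_tab[sample.int(nrow(les_tab), nles, replace = nrow(les_tab) < nles), , drop = FALSE],
        if (nbg > 0 && !is.null(bg_tab)) bg_tab[sample.int(nrow(bg_tab), nbg, replace = nrow(bg_tab) < nbg), , drop = FALSE])
      N <- nrow(pick)
      blb <- lapply(mods, function(m) array(0, c(s, s, s, 1, N)))
      fub <- lapply(mods, function(m) array(0, c(s, s, s, 1, N)))
      names(blb) <- names(fub) <- mods
      mb <- array(0, c(s, s, s, 1, N))
      yb <- array(0, c(s, s, s, 1, N))
      for (j in seq_len(N)) {
        ci <- pick[j, 1]; o <- pick[j, 2:4]
        for (m in mods) {
          blb[[m]][, , , 1, j] <- slice_patch(dat[[ci]]$bl[[m]], o, s)
          fub[[m]][, , , 1, j] <- slice_patch(dat[[ci]]$fu[[m]], o, s)
        }
        mb[, , , 1, j] <- slice_patch(dat[[ci]]$mask, o, s)
        yb[, , , 1, j] <- slice_patch(dat[[ci]]$les, o, s)
      }
      pn_regs <- lapply(model$regs, function(r) wrap_params(r$params))
      pn_seg <- wrap_params(model$seg$params)
      seg_ch <- vector("list", 2 * nm)
      terms <- list()
      sim_v <- 0; smo_v <- 0
      for (i in seq_len(nm)) {
        m <- mods[i]
        xreg <- array(0, c(s, s, s, 2, N))
        xreg[, , , 1, ] <- blb[[m]]
        xreg[, , , 2, ] <- fub[[m]]
        disp <- unet_fwd(model$regs[[m]], pn_regs[[m]], ag_const(xreg), TRUE)
        warped <- ag_warp_batch(blb[[m]], disp)
        sim <- ag_mse_masked(warped, fub[[m]], mb)
        smo <- ag_smoothness(disp)
        terms <- c(terms, list(sim, ag_scale(smo, cfg$lambda)))
        sim_v <- sim_v + sim$value; smo_v <- smo_v + smo$value
        seg_ch[[i]] <- warped
        seg_ch[[nm + i]] <- ag_const(fub[[m]])
      }
      seg_in <- ag_concat(seg_ch)
      logits <- unet_fwd(model$seg, pn_seg, seg_in, TRUE)
      ce <- ag_softmax_ce2(logits, yb, pos_weight = cfg$lesion_weight)
      total <- ag_sum(c(list(ce), terms))
      ag_backward(total)
      for (m in mods) {
        upd <- adam_step(model$regs[[m]]$params, collect_grads(pn_regs[[m]]),
                         opt_reg[[m]], cfg$lr)
        model$regs[[m]]$params <- upd$params; opt_reg[[m]] <- upd$state
      }
      upd <- adam_step(model$seg$params, collect_grads(pn_seg), opt_seg, cfg$lr)
      model$seg$params <- upd$params; opt_seg <- upd$state
      hist[step, ] <- c(ce$value, sim_v, smo_v)
    }
  })
  model$history <- as.data.frame(hist)
  model$provenance$seed <- seed
  model$provenance$n_cases <- length(cases)
  model
}

#' Predict a new-lesion probability map
#'
#' Patch-tiled inference (stride 16, Hann-blended): per modality the
#' registration sub-network deforms the baseline patch onto the follow-up,
#' then the segmentation sub-network scores every voxel; the lesion-class
#' softmax probability is returned on the follow-up grid.
#'
#' @param model a trained `ms_detector`.
#' @param case an `ms_case` supplying the model's modalities (preprocessed).
#' @return A probability [volume()] in `[0, 1]`.
#' @export
predict_new_lesions <- function(model, case) {
  cfg <- model$config
  dat <- case_arrays(case, cfg$modalities)
  s <- cfg$patch_size
  mods <- cfg$modalities
  nm <- length(mods)
  org <- patch_origins(dat$dims, s, 16L)
  preds <- vector("list", nrow(org))
  batch <- 8L
  i <- 1L
  while (i <= nrow(org)) {
    j <- min(i + batch - 1L, nrow(org))
    N <- j - i + 1L
    blb <- lapply(mods, function(m) array(0, c(s, s, s, 1, N)))
    fub <- lapply(mods, function(m) array(0, c(s, s, s, 1, N)))
    names(blb) <- names(fub) <- mods
    for (k in seq_len(N)) {
      o <- org[i + k - 1L, ]
      for (m in mods) {
        blb[[m]][, , , 1, k] <- slice_patch(dat$bl[[m]], o, s)
        fub[[m]][, , , 1, k] <- slice_patch(dat$fu[[m]], o, s)
      }
    }
    seg_ch <- vector("list", 2 * nm)
    for (ii in seq_len(nm)) {
      m <- mods[ii]
      xreg <- array(0, c(s, s, s, 2, N))
      xreg[, , , 1, ] <- blb[[m]]
      xreg[, , , 2, ] <- fub[[m]]
      pn <- wrap_params(model$regs[[m]]$params)
      disp <- unet_fwd(model$regs[[m]], pn, ag_const(xreg), FALSE)
      seg_ch[[ii]] <- ag_warp_batch(blb[[m]], disp)
      seg_ch[[nm + ii]] <- ag_const(fub[[m]])
    }
    pn_seg <- wrap_params(model$seg$params)
    logits <- unet_fwd(model$seg, pn_seg, ag_concat(seg_ch), FALSE)$value
    dz <- logits[, , , 2, , drop = FALSE] - logits[, , , 1, , drop = FALSE]
    p1 <- 1 / (1 + exp(-dz))
    for (k in seq_len(N)) preds[[i + k - 1L]] <- array(p1[, , , 1, k], rep(s, 3))
    i <- j + 1L
  }
  prob <- reassemble_patches(preds, org, dat$dims, window = "hann")
  prob <- pmin(pmax(prob, 0), 1)
  fl <- case$followup[["FLAIR"]]
  volume(prob, spacing = fl$spacing, affine = fl$affine, mask = dat$mask)
}

#' @export
print.ms_detector <- function(x, ...) {
  cat(sprintf("<Detection model: modalities {%s}, width %d, depth %d%s>\n",
              paste(x$config$modalities, collapse = ","), x$config$width,
              x$config$depth,
              if (is.null(x$history)) ", untrained"
              else sprintf(", %d steps", nrow(x$history))))
  if (!is.null(x$history)) {
    ce <- x$history$ce
    cat(sprintf("  cross-entropy: %.4f -> %.4f\n", ce[1], ce[length(ce)]))
  }
  invisible(x)
}

#' @rdname predict_new_lesions
#' @param object a trained `ms_detector`.
#' @param ... ignored.
#' @export
predict.ms_detector <- function(object, case, ...) predict_new_lesions(object, case)

#' Plot detection training history
#'
#' @param x an `ms_detector`.
#' @param ... ignored.
#' @export
plot.ms_detector <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("untrained model")
  graphics::plot(seq_len(nrow(h)), h$ce, type = "l", xlab = "step",
                 ylab = "loss term", main = "detector training")
  graphics::lines(seq_len(nrow(h)), h$similarity, lty = 2)
  graphics::legend("topright", c("cross-entropy", "registration MSE"),
                   lty = 1:2, bty = "n")
  invisible(x)
}

#' Threshold and size-filter a probability map
#'
#' Binarizes at `prob >= threshold` (inclusive), labels 26-connected
#' components, and removes components with fewer than `min_voxels` voxels —
#' the standard inference rule (probability 0.5, minimum lesion size 3
#' voxels; 0.3 is the common alternate operating point).
#'
#' @param prob a probability [volume()] in `[0, 1]`.
#' @param threshold inclusive probability cut (default 0.5).
#' @param min_voxels minimum component size kept (default 3).
#' @return An integer-labeled component [volume()] (labels 1..K) with
#'   attribute `n_components`.
#' @export
postprocess <- function(prob, threshold = 0.5, min_voxels = 3L) {
  p <- if (inherits(prob, "ms_volume")) prob$data else prob
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0,1]")
  bin <- (p >= threshold) * 1
  lab <- cpp_label_components(bin, 26L)
  n <- attr(lab, "n_components")
  out <- array(0L, dim(p))
  kept <- 0L
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    for (k in seq_len(n)) {
      if (sizes[k] >= min_voxels) {
        kept <- kept + 1L
        out[lab == k] <- kept
      }
    }
  }
  v <- volume(array(as.double(out), dim(out)),
              spacing = if (inherits(prob, "ms_volume")) prob$spacing else c(1, 1, 1),
              affine = if (inherits(prob, "ms_volume")) prob$affine else NULL)
  attr(v, "n_components") <- kept
  v
}
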
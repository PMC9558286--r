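#' Synthesis training configuration
#'
#' Defaults follow the pix2pix convention for conditional image-to-image
#' adversarial training: the generator loss is
#' `adv_weight * adversarial + l1_weight * L1` with a 1:100 weight ratio, and
#' one-sided label smoothing replaces the discriminator's real target 1 by
#' `1 - label_smoothing`.
#'
#' @param base_width generator filters at the first level.
#' @param disc_width discriminator filters at the first level.
#' @param patch_size training patch side (32).
#' @param patch_stride lattice step for patch extraction.
#' @param label_smoothing epsilon in `[0, 0.5)`; real targets become 1 - eps.
#' @param adv_weight,l1_weight generator loss weights (>= 0, not both 0).
#' @param lr,lr_disc Adam learning rates.
#' @param n_steps training steps.
#' @param batch_size patches per step.
#' @param min_mask_frac keep patches with at least this brain fraction.
#' @param sampling `"random"` patch sampling or `"exhaustive"` cycling.
#' @param cluster_smoothing mode-filter iterations for the conditioning maps.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(base_width = 8L, disc_width = 8L, patch_size = 32L,
                         patch_stride = 16L, label_smoothing = 0.1,
                         adv_weight = 1, l1_weight = 100, lr = 2e-3,
                         lr_disc = 2e-3, n_steps = 200L, batch_size = 2L,
                         min_mask_frac = 0.05, sampling = c("random", "exhaustive"),
                         cluster_smoothing = 0L) {
  sampling <- match.arg(sampling)
  stopifnot(label_smoothing >= 0, label_smoothing < 0.5,
            adv_weight >= 0, l1_weight >= 0, adv_weight + l1_weight > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Build the synthesis generator
#'
#' A patchwise 3D residual U-Net with 8 residual blocks (4 encoder + 4
#' decoder), 3x3x3 convolutions with batch normalization inside each block,
#' stride-2 2x2x2 downsampling, nearest-neighbour upsampling, skip paths
#' merged by voxelwise summation (1x1x1 projections matching widths), and a
#' single-channel sigmoid output: `(32^3, c)` in, `(32^3, 1)` in `[0,1]` out.
#'
#' @param c number of input (cluster) channels.
#' @param base_width filters at the first level.
#' @param seed initialization seed.
#' @return An object of class `ms_generator`.
#' @export
build_generator <- function(c, base_width = 8L, seed = 1L) {
  net <- generator_init(c, base_width, seed)
  structure(net, class = "ms_generator")
}

#' Build the synthesis discriminator
#'
#' A patchwise 3D residual network: 4 residual blocks each followed by
#' pooling, global average pooling and a linear head producing one real/fake
#' logit per patch.
#'
#' @param base_width filters at the first level.
#' @param seed initialization seed.
#' @return An object of class `ms_discriminator`.
#' @export
build_discriminator <- function(base_width = 8L, seed = 1L) {
  net <- discriminator_init(base_width, seed)
  structure(net, class = "ms_discriminator")
}

#' Run a network forward
#'
#' @param net an `ms_generator` or `ms_discriminator`.
#' @param x input batch `(D,H,W,C,N)`.
#' @param training use batch statistics (TRUE) or running statistics (FALSE).
#' @return Generator: array `(D,H,W,1,N)` in `[0,1]`; discriminator: a `(1,N)`
#'   matrix of logits.
#' @export
network_forward <- function(net, x, training = FALSE) {
  pn <- wrap_params(net$params)
  xn <- ag_const(x)
  if (inherits(net, "ms_generator")) generator_fwd(net, pn, xn, training)$value
  else if (inherits(net, "ms_discriminator")) discriminator_fwd(net, pn, xn, training)$value
  else stop("unknown network")
}

# assemble (onehot, t1, mask) patch pools from training cases
synth_patch_pool <- function(cases, c, cfg, seed) {
  xs <- list(); ys <- list(); ms <- list()
  k <- 0L
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    pairs <- list()
    for (tp in c("followup", "baseline")) {
      mods <- cs[[tp]]
      if (!is.null(mods[["FLAIR"]]) && !is.null(mods[["T1"]]))
        pairs[[length(pairs) + 1L]] <- list(flair = mods[["FLAIR"]], t1 = mods[["T1"]])
    }
    if (!length(pairs)) stop("case ", cs$case_id, " lacks a FLAIR/T1 pair")
    for (pp in pairs) {
      k <- k + 1L
      cm <- cluster_intensities(pp$flair, c, smoothing = cfg$cluster_smoothing,
                                seed = derive_seed(seed, 500 + k))
      ch <- one_hot(cm)
      ep <- extract_patches(ch, pp$t1, size = cfg$patch_size,
                            stride = cfg$patch_stride, mask = pp$flair$mask,
                            min_mask_frac = cfg$min_mask_frac)
      mp <- lapply(seq_len(nrow(ep$origins)), function(i) {
        o <- ep$origins[i, ]; s <- cfg$patch_size
        pp$flair$mask[o[1]:(o[1] + s - 1), o[2]:(o[2] + s - 1), o[3]:(o[3] + s - 1)]
      })
      xs <- c(xs, ep$x); ys <- c(ys, ep$y); ms <- c(ms, mp)
    }
  }
  list(x = xs, y = ys, m = ms)
}

#' Train the cluster-conditioned adversarial synthesizer
#'
#' Alternating adversarial training on 32^3 patches: the discriminator
#' minimizes binary cross-entropy with smoothed real targets `1 - eps` and
#' fake targets 0 on (real T1 patch) vs (generated patch); the generator
#' minimizes `adv_weight` x (fooling term) + `l1_weight` x masked mean
#' absolute error against the real T1 patch. With `adv_weight = 0` the model
#' reduces to pure voxelwise regression (useful for smoke tests and
#' pretraining). Fully seeded and deterministic.
#'
#' @param cases list of `ms_case` objects, each supplying FLAIR (for
#'   clustering) and a real T1 target, preprocessed to `[0, 1]`.
#' @param c cluster count for the conditioning input.
#' @param config a [synth_config()].
#' @param seed master seed.
#' @return An object of class `ms_synth` with elements `gen`, `disc`,
#'   `config`, `c`, `history` (per-step losses) and `provenance`.
#' @export
synth_fit <- function(cases, c = 7L, config = synth_config(), seed = 1L) {
  if (!length(cases)) stop("empty case list")
  cfg <- config
  pool <- synth_patch_pool(cases, c, cfg, seed)
  np <- length(pool$x)
  if (!np) stop("no patches extracted")
  gen <- generator_init(c, cfg$base_width, derive_seed(seed, 1))
  disc <- discriminator_init(cfg$disc_width, derive_seed(seed, 2))
  opt_g <- adam_state(gen$params)
  opt_d <- adam_state(disc$params)
  s <- cfg$patch_size
  hist <- matrix(NA_real_, cfg$n_steps, 3,
                 dimnames = list(NULL, c("d_loss", "g_adv", "g_l1")))
  adversarial <- cfg$adv_weight > 0
  with_seed(derive_seed(seed, 3), {
    cursor <- 0L
    for (step in seq_len(cfg$n_steps)) {
      idx <- if (cfg$sampling == "random") {
        sample.int(np, cfg$batch_size, replace = np < cfg$batch_size)
      } else {
        ix <- ((cursor + seq_len(cfg$batch_size) - 1L) %% np) + 1L
        cursor <- cursor + cfg$batch_size
        ix
      }
      N <- length(idx)
      xb <- array(0, c(s, s, s, c, N))
      yb <- array(0, c(s, s, s, 1, N))
      mb <- array(0, c(s, s, s, 1, N))
      for (j in seq_len(N)) {
        xb[, , , , j] <- pool$x[[idx[j]]]
        yb[, , , 1, j] <- pool$y[[idx[j]]]
        mb[, , , 1, j] <- pool$m[[idx[j]]]
      }
      # generator graph (single forward reused for both updates)
      png <- wrap_params(gen$params)
      fake <- generator_fwd(gen, png, ag_const(xb), TRUE)
      if (adversarial) {
        # discriminator update on detached fake
        pnd <- wrap_params(disc$params)
        lg_real <- discriminator_fwd(disc, pnd, ag_const(yb), TRUE)
        lg_fake <- discriminator_fwd(disc, pnd, ag_const(fake$value), TRUE)
        d_loss <- ag_sum(list(
          ag_bce_logits(lg_real, matrix(1 - cfg$label_smoothing, 1, N)),
          ag_bce_logits(lg_fake, matrix(0, 1, N))))
        ag_backward(d_loss)
        upd <- adam_step(disc$params, collect_grads(pnd), opt_d, cfg$lr_disc)
        disc$params <- upd$params; opt_d <- upd$state
        # generator update: fool the (updated) discriminator + L1
        pnd2 <- wrap_params(disc$params)
        lg_fool <- discriminator_fwd(disc, pnd2, fake, TRUE)
        adv <- ag_bce_logits(lg_fool, matrix(1, 1, N))
        l1 <- ag_l1_masked(fake, yb, mb)
        g_loss <- ag_sum(list(ag_scale(adv, cfg$adv_weight),
                              ag_scale(l1, cfg$l1_weight)))
        ag_backward(g_loss)
        hist[step, ] <- c(d_loss$value, adv$value, l1$value)
      } else {
        l1 <- ag_l1_masked(fake, yb, mb)
        g_loss <- ag_scale(l1, cfg$l1_weight)
        ag_backward(g_loss)
        hist[step, ] <- c(NA, NA, l1$value)
      }
      upd <- adam_step(gen$params, collect_grads(png), opt_g, cfg$lr)
      gen$params <- upd$params; opt_g <- upd$state
    }
  })
  structure(list(gen = gen, disc = disc, c = c, config = cfg,
                 history = as.data.frame(hist),
                 provenance = list(n_cases = length(cases), seed = seed,
                                   n_patches = np)),
            class = "ms_synth")
}

#' Synthesize a T1-weighted volume from FLAIR
#'
#' One-hot cluster channels are tiled into 32^3 patches with stride 16, the
#' generator is applied per patch, and overlapping predictions are blended
#' with a separable Hann window (a partition of unity, so constants are
#' conserved and patch-seam artifacts are avoided). Output is masked to the
#' brain and lies in `[0, 1]`.
#'
#' @param model an `ms_synth` from [synth_fit()].
#' @param flair a preprocessed FLAIR [volume()] with mask.
#' @param cluster_map optional precomputed `ms_clustermap`; computed from
#'   `flair` with the model's `c` when omitted.
#' @param seed seed for the clustering initialization when computed here.
#' @return A synthetic T1 [volume()] (modality "T1S").
#' @export
synthesize_t1 <- function(model, flair, cluster_map = NULL, seed = 1L) {
  if (is.null(cluster_map))
    cluster_map <- cluster_intensities(flair, model$c,
                                       smoothing = model$config$cluster_smoothing,
                                       seed = seed)
  if (cluster_map$c != model$c)
    stop("cluster count mismatch: model expects c=", model$c)
  ch <- one_hot(cluster_map)
  gen <- model$gen
  fwd1 <- function(xb) {
    pn <- wrap_params(gen$params)
    generator_fwd(gen, pn, ag_const(xb), FALSE)$value
  }
  out <- apply_patchwise(ch, fwd1, size = model$config$patch_size, stride = 16L)
  msk <- flair$mask %||% array(1, dim(flair$data))
  out <- pmin(pmax(out, 0), 1) * msk
  volume(out, spacing = flair$spacing, affine = flair$affine, mask = msk)
}

#' @export
print.ms_synth <- function(x, ...) {
  cat(sprintf("<Synthesis model: c=%d clusters, generator width %d, %d steps>\n",
              x$c, x$config$base_width, nrow(x$history)))
  l1 <- x$history$g_l1
  cat(sprintf("  final L1: %.4f (start %.4f)\n", l1[length(l1)], l1[1]))
  invisible(x)
}

#' @rdname synthesize_t1
#' @param object an `ms_synth`.
#' @param ... passed to [synthesize_t1()].
#' @export
predict.ms_synth <- function(object, flair, ...) synthesize_t1(object, flair, ...)

#' Plot synthesis training history
#'
#' @param x an `ms_synth`.
#' @param ... ignored.
#' @export
plot.ms_synth <- function(x, ...) {
  h <- x$history
  graphics::plot(seq_len(nrow(h)), h$g_l1, type = "l", xlab = "step",
                 ylab = "masked L1", main = "synthesis training")
  if (any(is.finite(h$d_loss))) {
    graphics::lines(seq_len(nrow(h)), h$d_loss / max(h$d_loss, na.rm = TRUE) *
                      max(h$g_l1, na.rm = TRUE), lty = 2)
    graphics::legend("topright", c("generator L1", "discriminator (scaled)"),
                     lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Save / load trained models
#'
#' Model files carry a format version and reload to bit-identical inference.
#'
#' @param model an `ms_synth` or `ms_detector`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "msynth-model-v1", model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "msynth-model-v1")) stop("unrecognized model file")
  obj$model
}
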
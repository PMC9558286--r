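# Shared fixtures. Everything is generated in code; heavier objects are
# memoised per session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# a clean (noise-free, unbiased, no partial volume) phantom and FLAIR render
clean_phantom <- function() {
  memo("clean_phantom", {
    sp <- phantom_spec(noise_sd = 0, bias_amplitude = 0, partial_volume = FALSE)
    an <- generate_anatomy(sp, 5)
    fl <- render_modality(an, sp$contrast_flair, 0, 0, seed = 1,
                          partial_volume = FALSE)
    list(spec = sp, anatomy = an, flair = fl)
  })
}

# a realistic phantom (noise + bias + partial volume)
noisy_phantom <- function() {
  memo("noisy_phantom", {
    sp <- phantom_spec()
    an <- generate_anatomy(sp, 5)
    fl <- render_modality(an, sp$contrast_flair, sp$noise_sd, sp$bias_amplitude,
                          seed = 2)
    list(spec = sp, anatomy = an, flair = fl)
  })
}

# two preprocessed longitudinal cases (synthesis training fixture)
synth_cases <- function() {
  memo("synth_cases", {
    sp <- phantom_spec()
    lapply(1:2, function(i) preprocess_case(make_longitudinal_case(sp, 1000 + i)))
  })
}

# a small trained synthesis model (regression mode, 20 steps) and its config
synth_small_cfg <- function() synth_config(base_width = 2L, adv_weight = 0,
                                           n_steps = 20L, batch_size = 2L,
                                           lr = 2e-3)
synth_small <- function() {
  memo("synth_small",
       synth_fit(synth_cases()[1], c = 3L, config = synth_small_cfg(), seed = 5))
}

# a small trained detector (2 steps) and its config
det_small_cfg <- function() detection_config("FLAIR", width = 2L, depth = 2L,
                                             n_steps = 2L, batch_size = 2L)
det_small <- function() {
  memo("det_small",
       detector_fit(synth_cases()[1], config = det_small_cfg(), seed = 7,
                    model = build_detection_model(det_small_cfg(), seed = 7)))
}

# brute-force 3D connected components by BFS flood fill (oracle)
flood_fill_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  idx_all <- which(mask != 0)
  for (start in idx_all) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[li] != 0 && lab[li] == 0) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  attr(lab, "n_components") <- nxt
  lab
}

# brute-force lesion matching oracle: all-pairs voxel-set intersection
match_lesions_oracle <- function(pred_lab, gt_lab) {
  gidx <- split(which(gt_lab != 0), as.vector(gt_lab[gt_lab != 0]))
  pidx <- split(which(pred_lab != 0), as.vector(pred_lab[pred_lab != 0]))
  tp <- 0L; fp <- 0L
  for (g in gidx) {
    hit <- FALSE
    for (p in pidx) if (length(intersect(g, p))) { hit <- TRUE; break }
    if (hit) tp <- tp + 1L
  }
  for (p in pidx) {
    hit <- FALSE
    for (g in gidx) if (length(intersect(g, p))) { hit <- TRUE; break }
    if (!hit) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = length(gidx) - tp)
}

# exhaustive signed-rank enumeration oracle (no ties assumed handled via
# midranks, matching the implementation's definition)
signrank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pless <- mean(vs <= v)
  pgreater <- mean(vs >= v)
  min(1, 2 * min(pless, pgreater))
}

# finite-difference gradient check helper: f(x) must return list(val, grad)
fd_check <- function(f, x, n_probe = 12, eps = 1e-5, seed = 1) {
  g <- f(x)$grad
  set.seed(seed)
  idx <- sample(length(x), min(n_probe, length(x)))
  worst <- 0
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (f(xp)$val - f(xm)$val) / (2 * eps)
    worst <- max(worst, abs(num - g[i]))
  }
  worst
}
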
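#' Longitudinal brain-phantom specification
#'
#' Parameters of the synthetic longitudinal dual-contrast brain phantom:
#' three concentric, randomly deformed ellipsoidal tissue shells (CSF, GM,
#' WM) rendered under a FLAIR-like contrast (lesions hyperintense, CSF
#' suppressed) and a T1-like contrast (lesions hypointense, grey/white
#' contrast inverted), with additive Gaussian noise, a smooth multiplicative
#' bias field, a small random affine misalignment of the baseline, and
#' spherical "new lesions" present only at follow-up.
#'
#' @param dims integer length-3 grid size (default 64^3, minimum 32 per axis).
#' @param contrast_flair,contrast_t1 named per-class mean intensities
#'   (`CSF`, `GM`, `WM`, `LESION`); the FLAIR lesion intensity must exceed
#'   the FLAIR WM intensity and the T1 lesion intensity must be below the
#'   T1 WM intensity.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bias_amplitude peak-to-peak amplitude of the smooth multiplicative
#'   bias field (0 disables it).
#' @param n_new_lesions integer range (min, max) of new lesions per active case.
#' @param lesion_radius_vox radius range in voxels; the minimum must be >= 1
#'   so every lesion component has at least 3 voxels and survives the
#'   minimum-size rule used at inference.
#' @param misalign_translation_vox,misalign_rotation_deg ranges of the random
#'   baseline-to-follow-up misalignment (voxels / degrees).
#' @param partial_volume emulate partial-volume voxels by linear intensity
#'   mixing in a one-voxel band at tissue boundaries.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 64),
                         contrast_flair = c(CSF = 0.10, GM = 0.60, WM = 0.45, LESION = 0.90),
                         contrast_t1 = c(CSF = 0.10, GM = 0.45, WM = 0.70, LESION = 0.35),
                         noise_sd = 0.03,
                         bias_amplitude = 0.2,
                         n_new_lesions = c(2L, 5L),
                         lesion_radius_vox = c(1.2, 3.0),
                         misalign_translation_vox = c(-2, 2),
                         misalign_rotation_deg = c(-2, 2),
                         partial_volume = TRUE) {
  stopifnot(length(dims) == 3, all(dims >= 32))
  need <- c("CSF", "GM", "WM", "LESION")
  stopifnot(all(need %in% names(contrast_flair)), all(need %in% names(contrast_t1)))
  if (contrast_flair[["LESION"]] <= contrast_flair[["WM"]])
    stop("FLAIR lesion intensity must exceed FLAIR WM intensity")
  if (contrast_t1[["LESION"]] >= contrast_t1[["WM"]])
    stop("T1 lesion intensity must be below T1 WM intensity")
  if (lesion_radius_vox[1] < 1)
    stop("minimum lesion radius must be >= 1 voxel (3-voxel minimum size rule)")
  structure(list(dims = as.integer(dims), contrast_flair = contrast_flair,
                 contrast_t1 = contrast_t1, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 n_new_lesions = as.integer(n_new_lesions),
                 lesion_radius_vox = lesion_radius_vox,
                 misalign_translation_vox = misalign_translation_vox,
                 misalign_rotation_deg = misalign_rotation_deg,
                 partial_volume = partial_volume),
            class = "phantom_spec")
}

# tissue label codes used throughout the phantom
PHANTOM_LABELS <- c(BG = 0L, CSF = 1L, GM = 2L, WM = 3L, LESION = 4L)

#' Generate phantom anatomy
#'
#' Concentric deformed-ellipsoid shells labelled CSF (1), GM (2) and WM (3)
#' inside a brain mask (0 = background), deterministic given the seed. The
#' shells share one smooth random radial perturbation so they stay nested.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return A label [volume()] (integer codes stored as doubles) with the brain
#'   mask attached.
#' @export
generate_anatomy <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  if (any(d < 32)) stop("dims too small to host all shells")
  with_seed(seed, {
    ctr <- d / 2 + runif(3, -1, 1)
    R <- min(d) / 2
    scl <- runif(3, 0.9, 1.1)
    r_csf <- 0.88 * R; r_gm <- 0.70 * R; r_wm <- 0.48 * R
    ax <- (seq_len(d[1]) - ctr[1]) / scl[1]
    ay <- (seq_len(d[2]) - ctr[2]) / scl[2]
    az <- (seq_len(d[3]) - ctr[3]) / scl[3]
    rho <- sqrt(outer(outer(ax^2, ay^2, `+`), az^2, `+`))
    coarse <- array(rnorm(125, sd = 0.05 * R), c(5, 5, 5))
    pert <- cpp_trilinear_resize(coarse, as.integer(d))
    rho <- rho + pert
    lab <- array(0, d)
    lab[rho <= r_csf] <- PHANTOM_LABELS[["CSF"]]
    lab[rho <= r_gm] <- PHANTOM_LABELS[["GM"]]
    lab[rho <= r_wm] <- PHANTOM_LABELS[["WM"]]
    volume(lab, mask = (lab > 0) * 1)
  })
}

# 3^3 box mean with zero padding, via shifted-array accumulation
box3_mean <- function(a) {
  d <- dim(a)
  acc <- array(0, d); cnt <- array(0, d)
  pad <- function(x, s, axis) {
    idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst <- idx_src
    if (s == 1) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1) }
    if (s == -1) { idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis] }
    out <- array(0, d)
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  ones <- array(1, d)
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    sh <- a; shc <- ones
    if (sx != 0) { sh <- pad(sh, sx, 1); shc <- pad(shc, sx, 1) }
    if (sy != 0) { sh <- pad(sh, sy, 2); shc <- pad(shc, sy, 2) }
    if (sz != 0) { sh <- pad(sh, sz, 3); shc <- pad(shc, sz, 3) }
    acc <- acc + sh; cnt <- cnt + shc
  }
  acc / cnt
}

#' Render a contrast from a phantom label volume
#'
#' Intensity = class mean x smooth multiplicative bias field + additive
#' Gaussian noise, clipped at 0; the brain mask is copied from the labels.
#' With `partial_volume = TRUE` voxels in a one-voxel band at tissue
#' boundaries take the local linear mixture of the adjacent class means,
#' emulating MR partial-volume effects.
#'
#' @param labels a label [volume()] from [generate_anatomy()] (optionally with
#'   lesion label 4).
#' @param contrast named per-class mean intensities (`CSF`, `GM`, `WM`, and
#'   `LESION` if present in the labels).
#' @param noise_sd,bias_amplitude see [phantom_spec()].
#' @param seed integer seed (noise and bias field).
#' @param partial_volume logical.
#' @return An intensity [volume()] with mask attached.
#' @export
render_modality <- function(labels, contrast, noise_sd = 0, bias_amplitude = 0,
                            seed = 1L, partial_volume = TRUE) {
  lab <- labels$data
  present <- setdiff(sort(unique(as.integer(lab))), 0L)
  lut <- c(BG = 0, contrast[c("CSF", "GM", "WM")],
           LESION = unname(contrast["LESION"]))
  names(lut) <- c("0", "1", "2", "3", "4")
  if (any(!as.character(present) %in% names(lut)) ||
      any(is.na(lut[as.character(present)])))
    stop("missing class in contrast profile")
  img <- array(lut[as.character(as.integer(lab))], dim(lab))
  mask <- (lab > 0) * 1
  if (partial_volume) {
    num <- box3_mean(img * mask)
    den <- box3_mean(mask)
    sm <- ifelse(den > 0, num / pmax(den, 1e-12), 0)
    boundary <- (cpp_minmax_filter(lab, TRUE) != cpp_minmax_filter(lab, FALSE)) & mask > 0
    img[boundary] <- sm[boundary]
  }
  with_seed(seed, {
    if (bias_amplitude > 0) {
      coarse <- array(1 + bias_amplitude * (runif(64) - 0.5), c(4, 4, 4))
      bias <- cpp_trilinear_resize(coarse, dim(lab))
      img <- img * bias
    }
    if (noise_sd > 0) {
      noise <- array(rnorm(length(img), sd = noise_sd), dim(img))
      img <- img + noise * mask
    }
  })
  img[img < 0] <- 0
  img <- img * mask
  volume(img, spacing = labels$spacing, affine = labels$affine, mask = mask)
}

# random small affine (rotation about grid centre + translation), as a 4x4
# voxel-coordinate map (1-based grid handled by the resampler)
random_misalignment <- function(spec) {
  tr <- runif(3, spec$misalign_translation_vox[1], spec$misalign_translation_vox[2])
  ang <- runif(3, spec$misalign_rotation_deg[1], spec$misalign_rotation_deg[2]) * pi / 180
  affine_from_params(c(tr, ang), dof = "rigid", center = (spec$dims - 1) / 2)
}

#' Build one longitudinal phantom case
#'
#' Follow-up anatomy = baseline anatomy plus inserted spherical WM "new
#' lesions"; the ground-truth mask marks exactly the inserted voxels. The
#' baseline volumes are resampled through a random small affine so the two
#' timepoints are misaligned, as clinically acquired pairs are. Both FLAIR
#' and T1 contrasts are rendered for both timepoints.
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer seed; all randomness derives from it.
#' @param case_id identifier (default derived from the seed).
#' @return An `ms_case` (see [longitudinal_case()]) with attributes
#'   `n_lesions` and `true_misalignment`.
#' @export
make_longitudinal_case <- function(spec, case_seed, case_id = NULL) {
  case_id <- case_id %||% sprintf("case_%06d", case_seed %% 1000000L)
  anat <- generate_anatomy(spec, derive_seed(case_seed, 1))
  lab_fu <- anat$data
  les_mask <- array(0, dim(lab_fu))
  n_les <- 0L
  with_seed(derive_seed(case_seed, 2), {
    lo <- spec$n_new_lesions[1]; hi <- spec$n_new_lesions[2]
    n_les <- if (hi <= lo) lo else sample(lo:hi, 1)
    if (n_les > 0) {
      wm_idx <- which(lab_fu == PHANTOM_LABELS[["WM"]])
      d <- dim(lab_fu)
      coords <- arrayInd(wm_idx, d)
      for (j in seq_len(n_les)) {
        r <- runif(1, spec$lesion_radius_vox[1], spec$lesion_radius_vox[2])
        placed <- FALSE
        for (att in seq_len(100)) {
          ctr <- coords[sample.int(nrow(coords), 1), ]
          rr <- ceiling(r)
          rng <- lapply(1:3, function(a) max(1, ctr[a] - rr):min(d[a], ctr[a] + rr))
          sub <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
          dist <- sqrt(rowSums((sweep(sub, 2, ctr))^2))
          ball <- sub[dist <= r, , drop = FALSE]
          if (nrow(ball) < 3) next
          li <- ball[, 1] + d[1] * (ball[, 2] - 1 + d[2] * (ball[, 3] - 1))
          # entire ball (plus nothing outside WM) and no overlap with others
          if (all(lab_fu[li] == PHANTOM_LABELS[["WM"]]) && all(les_mask[li] == 0)) {
            lab_fu[li] <- PHANTOM_LABELS[["LESION"]]
            les_mask[li] <- 1
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("cannot place requested lesion count inside WM without overlap")
      }
    }
  })
  lab_fu_vol <- volume(lab_fu, spacing = anat$spacing, affine = anat$affine,
                       mask = anat$mask)
  fu_flair <- render_modality(lab_fu_vol, spec$contrast_flair, spec$noise_sd,
                              spec$bias_amplitude, derive_seed(case_seed, 3),
                              spec$partial_volume)
  fu_t1 <- render_modality(lab_fu_vol, spec$contrast_t1, spec$noise_sd,
                           spec$bias_amplitude, derive_seed(case_seed, 4),
                           spec$partial_volume)
  bl_flair <- render_modality(anat, spec$contrast_flair, spec$noise_sd,
                              spec$bias_amplitude, derive_seed(case_seed, 5),
                              spec$partial_volume)
  bl_t1 <- render_modality(anat, spec$contrast_t1, spec$noise_sd,
                           spec$bias_amplitude, derive_seed(case_seed, 6),
                           spec$partial_volume)
  mis <- with_seed(derive_seed(case_seed, 7), random_misalignment(spec))
  bl_flair <- resample(bl_flair, mis, bl_flair, interpolation = "linear")
  bl_t1 <- resample(bl_t1, mis, bl_t1, interpolation = "linear")
  cs <- longitudinal_case(case_id,
                          baseline = list(FLAIR = bl_flair, T1 = bl_t1),
                          followup = list(FLAIR = fu_flair, T1 = fu_t1),
                          new_lesion_mask = volume(les_mask, spacing = anat$spacing,
                                                   affine = anat$affine))
  attr(cs, "n_lesions") <- n_les
  attr(cs, "true_misalignment") <- mis
  cs
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` cases (five NIfTI files each plus a brain mask) under
#' `out_dir` and a `manifest.tsv` listing paths, per-case lesion counts and
#' seeds. Case seeds derive deterministically from the master seed.
#'
#' @param n_cases number of cases.
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return The manifest as a data.frame (also written to
#'   `file.path(out_dir, "manifest.tsv")`).
#' @export
make_dataset <- function(n_cases, spec, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cseed <- derive_seed(seed, 100 + i)
    cs <- make_longitudinal_case(spec, cseed, case_id = sprintf("case_%03d", i))
    cdir <- file.path(out_dir, cs$case_id)
    dir.create(cdir, showWarnings = FALSE)
    paths <- c(baseline_flair = "baseline_flair.nii.gz",
               baseline_t1 = "baseline_t1.nii.gz",
               followup_flair = "followup_flair.nii.gz",
               followup_t1 = "followup_t1.nii.gz",
               new_lesions_mask = "new_lesions_mask.nii.gz",
               brain_mask = "brain_mask.nii.gz")
    write_volume(cs$baseline[["FLAIR"]], file.path(cdir, paths["baseline_flair"]))
    write_volume(cs$baseline[["T1"]], file.path(cdir, paths["baseline_t1"]))
    write_volume(cs$followup[["FLAIR"]], file.path(cdir, paths["followup_flair"]))
    write_volume(cs$followup[["T1"]], file.path(cdir, paths["followup_t1"]))
    write_volume(cs$new_lesion_mask, file.path(cdir, paths["new_lesions_mask"]))
    msk <- cs$followup[["FLAIR"]]$mask
    write_volume(volume(msk, spacing = spec$dims * 0 + 1), file.path(cdir, paths["brain_mask"]))
    rows[[i]] <- data.frame(case_id = cs$case_id, dir = cdir,
                            t(paths), n_lesions = attr(cs, "n_lesions"),
                            seed = cseed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a phantom case back from a dataset directory
#'
#' @param case_dir directory written by [make_dataset()].
#' @return An `ms_case` with brain masks attached to every volume.
#' @export
read_case <- function(case_dir) {
  rd <- function(f) read_volume(file.path(case_dir, f))
  msk <- rd("brain_mask.nii.gz")
  attach_mask <- function(v) { v$mask <- (msk$data > 0.5) * 1; v }
  longitudinal_case(basename(case_dir),
                    baseline = list(FLAIR = attach_mask(rd("baseline_flair.nii.gz")),
                                    T1 = attach_mask(rd("baseline_t1.nii.gz"))),
                    followup = list(FLAIR = attach_mask(rd("followup_flair.nii.gz")),
                                    T1 = attach_mask(rd("followup_t1.nii.gz"))),
                    new_lesion_mask = volume((rd("new_lesions_mask.nii.gz")$data > 0.5) * 1))
}
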
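#' Experiment configuration
#'
#' One experimental arm of the detection study: `baseline` trains the
#' detector on original FLAIR + T1, `flair_only` on FLAIR alone, and
#' `synthetic` on FLAIR + T1S (synthetic T1 generated from the same FLAIR).
#' All other settings are held fixed across arms so the comparison is paired.
#'
#' @param arm `"baseline"`, `"flair_only"` or `"synthetic"`.
#' @param manifest path to a dataset `manifest.tsv` (see [make_dataset()]) or
#'   the manifest data.frame itself.
#' @param train_ids,test_ids case ids of the disjoint train/test split.
#' @param out_dir output directory (`NULL` = nothing written).
#' @param seed master seed.
#' @param c cluster count for synthesis conditioning (default 7, the best
#'   detection trade-off).
#' @param threshold,min_voxels inference rules (defaults 0.5 and 3).
#' @param synth_model optional path to (or object of) a trained `ms_synth`;
#'   required for `arm = "synthetic"` unless `train_synth = TRUE`.
#' @param train_synth train the synthesizer on the training cases in-line.
#' @param synth a [synth_config()] for in-line synthesis training.
#' @param detect a [detection_config()]; its `modalities` are overridden by
#'   the arm.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(arm = c("baseline", "flair_only", "synthetic"),
                              manifest, train_ids, test_ids, out_dir = NULL,
                              seed = 1L, c = 7L, threshold = 0.5,
                              min_voxels = 3L, synth_model = NULL,
                              train_synth = FALSE, synth = synth_config(),
                              detect = detection_config()) {
  arm <- match.arg(arm)
  if (arm == "synthetic" && is.null(synth_model) && !train_synth)
    stop("arm=synthetic requires a synthesis model or train_synth=TRUE")
  structure(as.list(environment()), class = "experiment_config")
}

arm_modalities <- function(arm) {
  switch(arm, baseline = c("FLAIR", "T1"), flair_only = "FLAIR",
         synthetic = c("FLAIR", "T1S"))
}

#' Load an experiment configuration from a YAML file
#'
#' Flat key/value schema; unknown keys are rejected by name, defaults are
#' filled (`c = 7`, `threshold = 0.5`, `min_voxels = 3`). Keys prefixed
#' `synth_` / `detect_` set fields of the nested [synth_config()] /
#' [detection_config()].
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top <- c("arm", "manifest", "train_ids", "test_ids", "out_dir", "seed", "c",
           "threshold", "min_voxels", "synth_model", "train_synth")
  synth_keys <- names(formals(synth_config))
  det_keys <- names(formals(detection_config))
  scfg <- synth_config(); dcfg <- detection_config()
  args <- list()
  for (k in names(raw)) {
    if (k %in% top) {
      args[[k]] <- raw[[k]]
    } else if (startsWith(k, "synth_") && substring(k, 7) %in% synth_keys) {
      scfg[[substring(k, 7)]] <- raw[[k]]
    } else if (startsWith(k, "detect_") && substring(k, 8) %in% det_keys) {
      dcfg[[substring(k, 8)]] <- raw[[k]]
    } else {
      stop("unknown configuration key: '", k, "'")
    }
  }
  if (is.null(args$arm) || is.null(args$manifest))
    stop("config must provide 'arm' and 'manifest'")
  args$synth <- scfg; args$detect <- dcfg
  do.call(experiment_config, args)
}

# stage-granularity logging: wall time and the seed driving the stage
stage <- function(label, seed, expr) {
  t0 <- Sys.time()
  out <- force(expr)
  message(sprintf("[%s] %.1f s (seed %s)", label,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  if (is.null(seed)) "-" else seed))
  out
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) read.delim(manifest, stringsAsFactors = FALSE)
  else manifest
}

# load + preprocess the cases named by ids (registration baseline->follow-up,
# skull masks, [0,1] normalization)
load_preprocessed <- function(man, ids) {
  out <- list()
  for (id in ids) {
    row <- man[man$case_id == id, ]
    if (nrow(row) != 1) stop("case id not found in manifest: ", id)
    cs <- read_case(row$dir)
    out[[id]] <- preprocess_case(cs)
  }
  out
}

# attach synthetic T1 (both timepoints) generated from FLAIR to each case
attach_t1s <- function(cases, model, seed) {
  k <- 0L
  for (id in names(cases)) {
    k <- k + 1L
    cases[[id]]$baseline$T1S <-
      synthesize_t1(model, cases[[id]]$baseline$FLAIR, seed = derive_seed(seed, 300 + k))
    cases[[id]]$followup$T1S <-
      synthesize_t1(model, cases[[id]]$followup$FLAIR, seed = derive_seed(seed, 600 + k))
  }
  cases
}

#' Run one experimental arm end-to-end
#'
#' Loads and preprocesses the manifest cases, (for the synthetic arm)
#' clusters and synthesizes T1S for every case including the training cases,
#' trains the detector on the training split, predicts and scores the
#' held-out split under the standard inference rules, and writes
#' `scores.tsv`, trained models and a JSON run record when `out_dir` is set.
#'
#' @param cfg an [experiment_config()].
#' @param cases optional list of already-preprocessed `ms_case`s named by
#'   case id (the output of [preprocess_case()] on every train/test case).
#'   Preprocessing is deterministic, so supplying it only avoids recomputing
#'   the same volumes; [run_arm_comparison()] uses this to preprocess once
#'   for all three arms.
#' @return A list of class `ms_experiment`: per-case `scores` data.frame,
#'   the trained `detector`, the `synth` model (synthetic arm), and the
#'   `run_record`.
#' @export
run_experiment <- function(cfg, cases = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  man <- read_manifest(cfg$manifest)
  train_ids <- as.character(cfg$train_ids)
  test_ids <- as.character(cfg$test_ids)
  leak <- intersect(train_ids, test_ids)
  if (length(leak)) stop("split leakage: case(s) in both train and test: ",
                         paste(leak, collapse = ", "))
  mods <- arm_modalities(cfg$arm)
  if (is.null(cases)) {
    cases <- stage("preprocess", cfg$seed,
                   load_preprocessed(man, c(train_ids, test_ids)))
  } else {
    missing_ids <- setdiff(c(train_ids, test_ids), names(cases))
    if (length(missing_ids)) stop("preprocessed cases missing for: ",
                                  paste(missing_ids, collapse = ", "))
  }
  synth_model <- NULL
  if (cfg$arm == "synthetic") {
    synth_model <- if (!is.null(cfg$synth_model)) {
      if (is.character(cfg$synth_model)) load_model(cfg$synth_model) else cfg$synth_model
    } else {
      stage("synth-train", derive_seed(cfg$seed, 41),
            synth_fit(cases[train_ids], c = cfg$c, config = cfg$synth,
                      seed = derive_seed(cfg$seed, 41)))
    }
    cases <- stage("synthesize", derive_seed(cfg$seed, 42),
                   attach_t1s(cases, synth_model, derive_seed(cfg$seed, 42)))
  }
  dcfg <- cfg$detect
  dcfg$modalities <- mods
  detector <- stage("detect-train", derive_seed(cfg$seed, 43),
                    detector_fit(cases[train_ids], config = dcfg,
                                 seed = derive_seed(cfg$seed, 43)))
  rows <- list()
  for (id in test_ids) {
    prob <- predict_new_lesions(detector, cases[[id]])
    lesions <- postprocess(prob, cfg$threshold, cfg$min_voxels)
    sc <- score_case(lesions, cases[[id]]$new_lesion_mask)
    row <- data.frame(case_id = id, tp = sc$tp, fp = sc$fp, fn = sc$fn,
                      sensitivity = sc$sensitivity, fdr = sc$fdr,
                      precision = sc$precision)
    if (cfg$arm == "synthetic") {
      fu <- cases[[id]]$followup
      row$ssim <- ssim(fu$T1, fu$T1S)
      row$mae <- mae(fu$T1, fu$T1S)
    }
    rows[[id]] <- row
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  record <- list(arm = cfg$arm, modalities = mods, seed = cfg$seed, c = cfg$c,
                 threshold = cfg$threshold, min_voxels = cfg$min_voxels,
                 train_ids = train_ids, test_ids = test_ids,
                 detect = unclass(dcfg),
                 synth = if (cfg$arm == "synthetic") unclass(cfg$synth),
                 manifest_hash = if (is.character(cfg$manifest))
                   unname(tools::md5sum(cfg$manifest)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores(scores, file.path(cfg$out_dir, "scores.tsv"))
    save_model(detector, file.path(cfg$out_dir, "detector.rds"))
    if (!is.null(synth_model))
      save_model(synth_model, file.path(cfg$out_dir, "synth.rds"))
    jsonlite::write_json(record, file.path(cfg$out_dir, "run_record.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(scores = scores, detector = detector, synth = synth_model,
                 run_record = record), class = "ms_experiment")
}

# fixed-format TSV so identical runs are byte-identical
write_scores <- function(scores, path) {
  fmt <- scores
  for (cl in names(fmt))
    if (is.double(fmt[[cl]])) fmt[[cl]] <- sprintf("%.6f", fmt[[cl]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ms_experiment <- function(x, ...) {
  cat(sprintf("<Experiment arm=%s, %d test cases>\n", x$run_record$arm,
              nrow(x$scores)))
  print(x$scores)
  invisible(x)
}

#' Run and compare the three experimental arms
#'
#' Runs `baseline`, `flair_only` and `synthetic` with one shared split, seed,
#' settings and preprocessing pass (preprocessing is deterministic, so it is
#' computed once and shared), then compares every pair of arms per metric
#' with the paired
#' two-sided Wilcoxon signed-rank test (undefined per-case values dropped
#' pairwise).
#'
#' @param manifest dataset manifest (path or data.frame).
#' @param train_ids,test_ids shared case split.
#' @param seed master seed.
#' @param arms arms to run (default all three).
#' @param metrics score columns to compare.
#' @param ... passed to [experiment_config()] (e.g. `synth`, `detect`,
#'   `train_synth`, `out_dir`, `c`).
#' @return A list of class `ms_arm_comparison`: `experiments` (per arm),
#'   `summary` (mean scores per arm) and `wilcoxon` (pairwise p-values).
#' @export
run_arm_comparison <- function(manifest, train_ids, test_ids, seed = 1L,
                               arms = c("baseline", "flair_only", "synthetic"),
                               metrics = c("sensitivity", "fdr", "precision"),
                               ...) {
  dots <- list(...)
  man <- read_manifest(manifest)
  cases <- stage("preprocess", seed,
                 load_preprocessed(man, c(as.character(train_ids),
                                          as.character(test_ids))))
  exps <- list()
  for (arm in arms) {
    args <- c(list(arm = arm, manifest = manifest, train_ids = train_ids,
                   test_ids = test_ids, seed = seed,
                   train_synth = arm == "synthetic"), dots)
    if (!is.null(dots$out_dir)) args$out_dir <- file.path(dots$out_dir, arm)
    cfg <- do.call(experiment_config, args)
    exps[[arm]] <- run_experiment(cfg, cases = cases)
  }
  summ <- do.call(rbind, lapply(names(exps), function(a) {
    s <- exps[[a]]$scores
    data.frame(arm = a, n = nrow(s),
               sensitivity = mean(s$sensitivity, na.rm = TRUE),
               fdr = mean(s$fdr, na.rm = TRUE),
               precision = mean(s$precision, na.rm = TRUE))
  }))
  pairs <- utils::combn(names(exps), 2, simplify = FALSE)
  wil <- list()
  for (metric in metrics) {
    for (pr in pairs) {
      a <- exps[[pr[1]]]$scores[[metric]]
      b <- exps[[pr[2]]]$scores[[metric]]
      p <- tryCatch(as.numeric(compare_models(a, b, min_pairs = 2L)),
                    error = function(e) NA_real_)
      wil[[length(wil) + 1]] <- data.frame(metric = metric, arm_a = pr[1],
                                           arm_b = pr[2], p_value = p)
    }
  }
  structure(list(experiments = exps, summary = summ,
                 wilcoxon = do.call(rbind, wil)),
            class = "ms_arm_comparison")
}

#' @export
print.ms_arm_comparison <- function(x, ...) {
  cat("Arm summary:\n"); print(x$summary)
  cat("\nPaired Wilcoxon (two-sided):\n"); print(x$wilcoxon)
  invisible(x)
}
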
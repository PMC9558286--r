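test_that("arm definitions map to the intended modality sets", {
  expect_equal(msynth:::arm_modalities("baseline"), c("FLAIR", "T1"))
  expect_equal(msynth:::arm_modalities("flair_only"), "FLAIR")
  expect_equal(msynth:::arm_modalities("synthetic"), c("FLAIR", "T1S"))
})

test_that("experiment configuration guards", {
  expect_error(experiment_config("nonsense", manifest = "m.tsv",
                                 train_ids = "a", test_ids = "b"))
  expect_error(experiment_config("synthetic", manifest = "m.tsv",
                                 train_ids = "a", test_ids = "b"),
               "synthesis model|train_synth")
  cfg <- experiment_config("synthetic", manifest = "m.tsv", train_ids = "a",
                           test_ids = "b", train_synth = TRUE)
  expect_s3_class(cfg, "experiment_config")
})

test_that("YAML configuration: defaults, nested keys, unknown-key rejection", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("arm: flair_only", "manifest: m.tsv",
               "train_ids: [c1, c2]", "test_ids: [c3]",
               "detect_n_steps: 10", "synth_base_width: 4"), path)
  cfg <- load_config(path)
  expect_equal(cfg$arm, "flair_only")
  expect_equal(cfg$c, 7L)                  # default cluster count
  expect_equal(cfg$threshold, 0.5)
  expect_equal(cfg$min_voxels, 3L)
  expect_equal(cfg$detect$n_steps, 10)
  expect_equal(cfg$synth$base_width, 4)
  # a misspelled key is rejected by name, not silently ignored
  writeLines(c("arm: baseline", "manifest: m.tsv", "train_ids: [c1]",
               "test_ids: [c2]", "treshold: 0.4"), path)
  expect_error(load_config(path), "treshold")
  writeLines("threshold: 0.4", path)
  expect_error(load_config(path), "arm")
})

test_that("train/test leakage is a hard error", {
  man <- data.frame(case_id = c("c1", "c2"), dir = c("d1", "d2"),
                    stringsAsFactors = FALSE)
  cfg <- experiment_config("flair_only", manifest = man,
                           train_ids = c("c1", "c2"), test_ids = "c2")
  expect_error(run_experiment(cfg), "leakage")
})

test_that("score tables are written in a byte-stable format", {
  s <- data.frame(case_id = c("a", "b"), tp = c(1L, 2L),
                  sensitivity = c(1 / 3, 0.5), fdr = c(0, NA))
  p1 <- tempfile(); p2 <- tempfile()
  msynth:::write_scores(s, p1)
  msynth:::write_scores(s, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[2], "0\\.333333")
})

test_that("a miniature single-arm experiment runs and is deterministic", {
  root <- tempfile("ds")
  sp <- phantom_spec(dims = c(48, 48, 48), n_new_lesions = c(2, 3))
  man <- make_dataset(2, sp, out_dir = root, seed = 77)
  expect_equal(nrow(man), 2)
  dcfg <- detection_config("FLAIR", width = 2L, depth = 2L, n_steps = 3L,
                           batch_size = 2L)
  out1 <- file.path(root, "run1"); out2 <- file.path(root, "run2")
  run1 <- run_experiment(experiment_config(
    "flair_only", manifest = man, train_ids = man$case_id[1],
    test_ids = man$case_id[2], seed = 5, detect = dcfg, out_dir = out1))
  expect_s3_class(run1, "ms_experiment")
  expect_equal(nrow(run1$scores), 1)
  expect_true(all(c("tp", "fp", "fn", "sensitivity", "fdr", "precision")
                  %in% names(run1$scores)))
  expect_true(file.exists(file.path(out1, "scores.tsv")))
  expect_true(file.exists(file.path(out1, "detector.rds")))
  expect_true(file.exists(file.path(out1, "run_record.json")))
  run2 <- run_experiment(experiment_config(
    "flair_only", manifest = man, train_ids = man$case_id[1],
    test_ids = man$case_id[2], seed = 5, detect = dcfg, out_dir = out2))
  expect_identical(readLines(file.path(out1, "scores.tsv")),
                   readLines(file.path(out2, "scores.tsv")))
  expect_identical(run1$scores, run2$scores)
  unlink(root, recursive = TRUE)
})
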
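test_that("median absolute error identities and oracle equivalence", {
  set.seed(1)
  y <- array(runif(1000), c(10, 10, 10))
  expect_equal(mae(y, y), 0)
  expect_equal(mae(y, pmin(y + 0.2, Inf)), 0.2)
  yhat <- array(runif(1000), c(10, 10, 10))
  # sort-based median oracle
  d <- sort(abs(as.vector(y) - as.vector(yhat)))
  oracle <- (d[500] + d[501]) / 2
  expect_identical(mae(y, yhat), oracle)
  m <- array(0, c(10, 10, 10)); m[1:3, , ] <- 1
  expect_equal(mae(y, yhat, mask = m), median(abs(y[1:3, , ] - yhat[1:3, , ])))
  expect_error(mae(y, yhat[1:5, , , drop = FALSE]), "grid")
})

test_that("SSIM: identity, symmetry, anti-correlation, factor oracle", {
  set.seed(2)
  y <- array(runif(1000), c(10, 10, 10))
  yhat <- array(runif(1000), c(10, 10, 10))
  expect_equal(ssim(y, y), 1, tolerance = 1e-9)
  expect_equal(ssim(y, yhat), ssim(yhat, y), tolerance = 1e-12)
  expect_lt(ssim(y, 1 - y), 0) # negative structure correlation
  expect_lte(ssim(y, yhat), 1)
  # independent evaluation of the three factors
  k <- ssim_constants()
  my <- mean(y); mh <- mean(yhat)
  sy <- sd(as.vector(y)); sh <- sd(as.vector(yhat))
  cv <- stats::cov(as.vector(y), as.vector(yhat))
  oracle <- ((2 * my * mh + k$c1) / (my^2 + mh^2 + k$c1)) *
    ((2 * sy * sh + k$c2) / (sy^2 + sh^2 + k$c2)) *
    ((cv + k$c3) / (sy * sh + k$c3))
  expect_equal(ssim(y, yhat), oracle, tolerance = 1e-12)
  # windowed cross-check stays in a sane range
  expect_lt(abs(ssim(y, yhat, windowed = 5)), 1)
  expect_error(ssim_constants(c1 = 0))
})

test_that("lesion matching agrees with the brute-force oracle on random masks", {
  # a light spot-check here; the full 200-trial criterion runs in
  # test-acceptance.R
  set.seed(3)
  mismatches <- 0L
  for (trial in 1:40) {
    d <- c(16, 16, 16)
    pred <- array(rbinom(prod(d), 1, 0.06), d)
    gt <- array(rbinom(prod(d), 1, 0.06), d)
    pl <- msynth:::cpp_label_components(pred, 26L)
    gl <- msynth:::cpp_label_components(gt, 26L)
    got <- match_lesions(pl, gl)
    want <- match_lesions_oracle(pl, gl)
    if (!identical(got[c("tp", "fp", "fn")], want[c("tp", "fp", "fn")]))
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("component labelling agrees with flood fill (26 and 6 connectivity)", {
  set.seed(4)
  for (trial in 1:30) {
    m <- array(rbinom(16^3, 1, 0.15), c(16, 16, 16))
    for (conn in c(26L, 6L)) {
      got <- msynth:::cpp_label_components(m, conn)
      want <- flood_fill_label(m, conn)
      expect_identical(attr(got, "n_components"), attr(want, "n_components"))
      # same partition up to label names: co-membership must match
      expect_true(all(tapply(want[want > 0], got[got > 0],
                             function(v) length(unique(v))) == 1))
    }
  }
})

test_that("matching is invariant to component relabelling", {
  set.seed(5)
  d <- c(12, 12, 12)
  pred <- array(rbinom(prod(d), 1, 0.08), d)
  gt <- array(rbinom(prod(d), 1, 0.08), d)
  pl <- msynth:::cpp_label_components(pred, 26L)
  gl <- msynth:::cpp_label_components(gt, 26L)
  n <- attr(pl, "n_components")
  perm <- c(0, sample(n))
  pl2 <- array(perm[pl + 1], d)
  expect_identical(match_lesions(pl, gl), match_lesions(pl2, gl))
})

test_that("one-voxel overlap suffices for a true positive", {
  d <- c(12, 12, 12)
  gt <- array(0, d); gt[4:6, 4:6, 4:6] <- 1
  pred <- array(0, d); pred[6:8, 6:8, 6:8] <- 1 # touches gt only at (6,6,6)
  m <- match_lesions(pred, gt)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
})

test_that("detection score formulas and the precision/FDR identity", {
  s <- detection_scores(3, 0, 1)
  expect_equal(s$sensitivity, 0.75)
  s2 <- detection_scores(3, 1, 0)
  expect_equal(s2$fdr, 0.25)
  expect_equal(s2$precision, 0.75)
  expect_equal(s2$precision + s2$fdr, 1)
  s3 <- detection_scores(0, 0, 0) # stable case, empty prediction
  expect_true(is.na(s3$sensitivity) && is.na(s3$fdr) && is.na(s3$precision))
  set.seed(6)
  for (i in 1:50) {
    tp <- rpois(1, 3); fp <- rpois(1, 1); fn <- rpois(1, 1)
    s <- detection_scores(tp, fp, fn)
    if (tp + fp > 0) expect_equal(s$precision + s$fdr, 1)
  }
})

test_that("stable-case FP counting uses nearest-integer percent", {
  mk <- function(fp) detection_scores(0, fp, 0)
  sc <- c(lapply(rep(0, 25), mk), lapply(c(1, 2, 3), mk))
  expect_equal(fp_case_count(sc), list(count = 3L, percent = 11L))  # 3/28
  sc4 <- c(lapply(rep(0, 24), mk), lapply(c(1, 1, 2, 5), mk))
  expect_equal(fp_case_count(sc4), list(count = 4L, percent = 14L)) # 4/28
  expect_equal(fp_case_count(lapply(rep(0, 5), mk)),
               list(count = 0L, percent = 0L))
  expect_error(fp_case_count(list()), "empty")
  expect_error(fp_case_count(list(detection_scores(1, 0, 0))), "stable")
})

test_that("Wilcoxon comparison matches exhaustive enumeration (n <= 12)", {
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(6:12, 1)
    a <- runif(n)
    b <- a + rnorm(n, sd = 0.3)
    p <- compare_models(a, b)
    expect_equal(as.numeric(p), signrank_enum_p(a - b), tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test when ties are absent", {
  set.seed(8)
  for (trial in 1:20) {
    n <- sample(8:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    p <- as.numeric(compare_models(a, b))
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p, ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles constant shifts, identity and NA pairs", {
  a <- runif(10)
  expect_equal(as.numeric(compare_models(a, a + 1)), 2 / 2^10,
               tolerance = 1e-12)
  p <- compare_models(a, a)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  # undefined scores dropped pairwise
  b <- a + c(NA, rep(1, 9))
  p2 <- compare_models(a, b)
  expect_equal(attr(p2, "n_effective"), 9L)
  expect_error(compare_models(a, runif(9)), "length")
  expect_error(compare_models(runif(3), runif(3)), "at least")
  # large-sample path: sane p-values against the normal approximation
  set.seed(9)
  a <- rnorm(40); b <- a + 0.5
  expect_lt(as.numeric(compare_models(a, b)), 0.01)
})
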
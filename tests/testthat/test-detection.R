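test_that("warping: zero field is the identity, integer fields shift exactly", {
  set.seed(40)
  d <- c(12, 12, 12)
  v <- volume(array(runif(prod(d)), d))
  zf <- deformation_field(array(0, c(d, 3)))
  expect_equal(warp(v, zf)$data, v$data, tolerance = 1e-12)
  # displacement +2 along the first axis pulls intensity from i+2
  f <- array(0, c(d, 3)); f[, , , 1] <- 2
  w <- warp(v, deformation_field(f))
  expect_equal(w$data[1:10, , ], v$data[3:12, , ], tolerance = 1e-12)
  expect_true(all(w$data[11:12, , ] == 0)) # out of field
  expect_error(deformation_field(array(0, c(d, 2))), "D,H,W,3")
  expect_error(warp(volume(array(0, c(6, 6, 6))), zf), "mismatch")
})

test_that("registration loss: exact decomposition and the linear-field value", {
  set.seed(41)
  d <- c(8, 8, 8)
  v <- volume(array(runif(prod(d)), d))
  zf <- deformation_field(array(0, c(d, 3)))
  l0 <- registration_loss(v, v, zf, lambda = 1)
  expect_equal(as.numeric(l0), 0)
  # linear displacement d_i = alpha * coord_i scores 3 alpha^2
  alpha <- 0.2
  lin <- array(0, c(d, 3))
  for (i in 1:8) { lin[i, , , 1] <- alpha * i; lin[, i, , 2] <- alpha * i
                   lin[, , i, 3] <- alpha * i }
  fl <- deformation_field(lin)
  u <- volume(array(runif(prod(d)), d))
  for (lam in c(0.5, 2)) {
    l <- registration_loss(u, v, fl, lambda = lam)
    expect_equal(attr(l, "smoothness"), 3 * alpha^2, tolerance = 1e-12)
    expect_equal(as.numeric(l),
                 attr(l, "similarity") + lam * attr(l, "smoothness"),
                 tolerance = 1e-12)
    expect_equal(attr(l, "similarity"), mean((u$data - v$data)^2),
                 tolerance = 1e-12)
  }
})

test_that("channel accounting follows the modality set", {
  m1 <- build_detection_model(detection_config("FLAIR", width = 2L, depth = 2L))
  expect_named(m1$regs, "FLAIR")
  expect_equal(m1$seg$in_ch, 2L)
  m2 <- build_detection_model(detection_config(c("FLAIR", "T1"),
                                               width = 2L, depth = 2L))
  expect_named(m2$regs, c("FLAIR", "T1"))
  expect_equal(m2$seg$in_ch, 4L)
  expect_equal(m2$regs$FLAIR$out_ch, 3L) # displacement channels
  expect_error(detection_config("T1"), "FLAIR")
  expect_error(detection_config(c("FLAIR", "T2")), "unknown")
})

test_that("zero-initialized registration heads start at the identity deformation", {
  cfg <- detection_config("FLAIR", width = 2L, depth = 2L)
  m <- build_detection_model(cfg, seed = 3)
  expect_true(all(m$regs$FLAIR$params$out.w == 0))
  x <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  pn <- msynth:::wrap_params(m$regs$FLAIR$params)
  disp <- msynth:::unet_fwd(m$regs$FLAIR, pn, msynth:::ag_const(x), FALSE)
  expect_true(all(disp$value == 0))
})

test_that("two training steps update both sub-networks and stay finite", {
  cases <- synth_cases()
  cfg <- det_small_cfg()
  m0 <- build_detection_model(cfg, seed = 7)
  m <- det_small()
  expect_true(all(is.finite(as.matrix(m$history))))
  expect_equal(nrow(m$history), 2)
  # end-to-end gradients reached the registration net (through the warp) and
  # the segmentation net
  reg_moved <- !identical(m$regs$FLAIR$params, m0$regs$FLAIR$params)
  seg_moved <- !identical(m$seg$params, m0$seg$params)
  expect_true(reg_moved)
  expect_true(seg_moved)
  # determinism under the seed
  m2 <- detector_fit(cases[1], config = cfg, seed = 7,
                     model = build_detection_model(cfg, seed = 7))
  expect_identical(m$seg$params, m2$seg$params)
  expect_identical(m$regs$FLAIR$params, m2$regs$FLAIR$params)
})

test_that("inference yields a probability volume on the follow-up grid", {
  cases <- synth_cases()
  m <- det_small()
  prob <- predict_new_lesions(m, cases[[1]])
  expect_s3_class(prob, "ms_volume")
  expect_identical(dim(prob$data), dim(cases[[1]]$followup$FLAIR$data))
  expect_true(all(prob$data >= 0 & prob$data <= 1))
  expect_identical(predict(m, cases[[1]])$data, prob$data)
})

test_that("postprocess: inclusive threshold, size filter, consecutive labels", {
  d <- c(16, 16, 16)
  p <- array(0, d)
  p[2:4, 2, 2] <- 0.9        # size 3 -> kept
  p[8, 8, 8] <- 0.8          # size 1 -> removed
  p[12:13, 12, 12] <- 0.7    # size 2 -> removed
  p[10:13, 2, 2] <- 0.5      # size 4 exactly at the threshold -> kept (inclusive)
  p[2:4, 12, 12] <- 0.4      # below 0.5, above 0.3
  out <- postprocess(volume(p), threshold = 0.5, min_voxels = 3L)
  expect_equal(attr(out, "n_components"), 2L)
  expect_equal(sort(unique(as.vector(out$data))), c(0, 1, 2))
  expect_true(all(out$data[2:4, 2, 2] > 0))
  expect_true(all(out$data[10:13, 2, 2] > 0))
  expect_equal(out$data[8, 8, 8], 0)
  # the 0.3 operating point detects a superset of the 0.5 components
  out3 <- postprocess(volume(p), threshold = 0.3, min_voxels = 3L)
  expect_gte(attr(out3, "n_components"), attr(out, "n_components"))
  expect_true(all(out3$data[out$data > 0] > 0))
  expect_error(postprocess(volume(p * 3)), "\\[0,1\\]")
})
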
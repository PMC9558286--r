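test_that("affine composition is associative, identity-neutral and invertible", {
  t1 <- msynth:::affine_from_params(c(3, 0, 0), "translation")
  t2 <- msynth:::affine_from_params(c(-3, 0, 0), "translation")
  id <- affine_transform(diag(4))
  expect_equal(compose(t1, id)$matrix, t1$matrix)
  expect_equal(compose(t1, t2)$matrix, diag(4))
  t3 <- msynth:::affine_from_params(c(1, 2, 0.5, 0.02, -0.01, 0.03), "rigid",
                                    center = c(16, 16, 16))
  lhs <- compose(compose(t1, t2), t3)$matrix
  rhs <- compose(t1, compose(t2, t3))$matrix
  expect_equal(lhs, rhs, tolerance = 1e-12)
  a <- affine_transform(diag(4), from = "A", to = "B")
  b <- affine_transform(diag(4), from = "C", to = "D")
  expect_error(compose(a, b), "space mismatch")
  expect_error(affine_transform(matrix(0, 4, 4)), "last row")
})

test_that("resampling: identity, exact integer shifts, label preservation", {
  ph <- noisy_phantom()
  fl <- ph$flair
  id <- affine_transform(diag(4))
  same <- resample(fl, id, fl)
  expect_equal(same$data, fl$data, tolerance = 1e-12)
  # integer-voxel translation with linear interpolation is an exact shift
  tr <- msynth:::affine_from_params(c(2, 0, 0), "translation")
  sh <- resample(fl, tr, fl)
  expect_equal(sh$data[3:64, , ], fl$data[1:62, , ], tolerance = 1e-12)
  # nearest-neighbour keeps the label set
  lab <- ph$anatomy
  shl <- resample(lab, tr, lab, interpolation = "nearest")
  expect_true(all(unique(as.vector(shl$data)) %in% unique(as.vector(lab$data))))
})

test_that("resampling through a composition matches resampling twice", {
  ph <- noisy_phantom()
  fl <- ph$flair
  a <- msynth:::affine_from_params(c(1.5, -1, 0.5), "translation")
  b <- msynth:::affine_from_params(c(0.5, 2, -1.5), "translation")
  once <- resample(fl, compose(a, b), fl)
  twice <- resample(resample(fl, a, fl), b, fl)
  sel <- ph$anatomy$data == 3 # interior, away from out-of-field borders
  # the two-step path interpolates twice, so allow one extra blur of the
  # noise (sd 0.03): agreement to well under one noise sd
  expect_lt(median(abs(once$data[sel] - twice$data[sel])), 0.02)
})

test_that("translation registration recovers a known 3-voxel shift", {
  ph <- noisy_phantom()
  fl <- ph$flair
  tr <- msynth:::affine_from_params(c(3, 0, 0), "translation")
  moved <- resample(fl, tr, fl)
  reg <- affine_register(moved, fl, dof = "translation")
  expect_lt(max(abs(attr(reg, "params") - c(-3, 0, 0))), 0.5)
  expect_lt(attr(reg, "objective_after"), attr(reg, "objective_before"))
})

test_that("self-registration is the identity within 0.1 voxel", {
  ph <- noisy_phantom()
  reg <- affine_register(ph$flair, ph$flair, dof = "rigid")
  p <- attr(reg, "params")
  expect_lt(max(abs(p[1:3])), 0.1)             # voxels
  expect_lt(max(abs(p[4:6])) * 180 / pi, 0.1)  # degrees
})

test_that("disjoint masks are rejected", {
  d <- c(32, 32, 32)
  m1 <- array(0, d); m1[1:8, , ] <- 1
  m2 <- array(0, d); m2[24:32, , ] <- 1
  v1 <- volume(array(runif(prod(d)), d), mask = m1)
  v2 <- volume(array(runif(prod(d)), d), mask = m2)
  expect_error(affine_register(v1, v2), "overlap")
})

test_that("skull stripping recovers the phantom brain mask", {
  ph <- noisy_phantom()
  m <- skull_strip(ph$flair)
  inter <- sum(m$data * ph$anatomy$mask)
  dice <- 2 * inter / (sum(m$data) + sum(ph$anatomy$mask))
  expect_gt(dice, 0.95)
  expect_error(skull_strip(volume(array(0, c(16, 16, 16)))), "empty mask")
  # plug-in mask is returned verbatim
  pre <- volume(ph$anatomy$mask)
  expect_identical(skull_strip(ph$flair, mask = pre), pre)
})

test_that("normalize01 maps to [0,1], is idempotent, rejects constants", {
  ph <- noisy_phantom()
  nv <- normalize01(ph$flair)
  inm <- nv$data[nv$mask > 0]
  expect_gte(min(inm), 0)
  expect_lte(max(inm), 1)
  expect_equal(min(inm), 0)
  expect_equal(max(inm), 1)
  again <- normalize01(nv)
  expect_lt(max(abs(again$data - nv$data)), 0.02) # idempotent up to clipping
  const <- volume(array(1, c(8, 8, 8)), mask = array(1, c(8, 8, 8)))
  expect_error(normalize01(const), "constant")
  nomask <- volume(array(runif(512), c(8, 8, 8)))
  expect_error(normalize01(nomask), "mask")
})

test_that("preprocessing reduces baseline-to-follow-up misalignment", {
  cs <- make_longitudinal_case(phantom_spec(), 99)
  pp <- preprocess_case(cs)
  t <- attr(pp, "transforms")$baseline_to_followup
  expect_lt(attr(t, "objective_after"), attr(t, "objective_before"))
  # all outputs normalized
  for (v in c(pp$baseline, pp$followup))
    expect_true(min(v$data) >= 0 && max(v$data) <= 1)
})
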
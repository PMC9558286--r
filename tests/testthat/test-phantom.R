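test_that("anatomy has all three nested tissue shells and is deterministic", {
  sp <- phantom_spec()
  an <- generate_anatomy(sp, 1)
  expect_setequal(sort(unique(as.vector(an$data))), 0:3)
  an2 <- generate_anatomy(sp, 1)
  expect_identical(an$data, an2$data)
  # WM is innermost: the centre voxel of the brain lies in WM
  ctr <- round(dim(an$data) / 2)
  expect_equal(an$data[ctr[1], ctr[2], ctr[3]], 3)
  # brain fills a plausible fraction of the grid
  frac <- mean(an$mask)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.9)
  expect_error(phantom_spec(dims = c(16, 16, 16)))
})

test_that("noise-free render is piecewise constant at the class means", {
  ph <- clean_phantom()
  img <- ph$flair$data
  lab <- ph$anatomy$data
  for (code in 1:3) {
    mu <- ph$spec$contrast_flair[[c("CSF", "GM", "WM")[code]]]
    expect_equal(unique(as.vector(img[lab == code])), mu)
  }
  # determinism of the noisy render
  r1 <- render_modality(ph$anatomy, ph$spec$contrast_flair, 0.05, 0.2, seed = 9)
  r2 <- render_modality(ph$anatomy, ph$spec$contrast_flair, 0.05, 0.2, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_true(all(r1$data >= 0))
  # unknown label must be rejected
  bad <- ph$anatomy
  bad$data[1] <- 9
  expect_error(render_modality(bad, ph$spec$contrast_flair), "missing class")
})

test_that("in-mask intensity modes sit near the class means", {
  ph <- noisy_phantom()
  x <- ph$flair$data[ph$flair$mask > 0]
  dens <- stats::density(x, bw = 0.01)
  # local maxima of the kernel density estimate
  yi <- dens$y
  pk <- dens$x[which(diff(sign(diff(yi))) == -2) + 1]
  for (mu in ph$spec$contrast_flair[c("CSF", "GM", "WM")])
    expect_true(min(abs(pk - mu)) < ph$spec$noise_sd,
                label = sprintf("mode near %.2f", mu))
})

test_that("longitudinal cases carry well-formed new lesions", {
  sp <- phantom_spec(n_new_lesions = c(2L, 4L))
  cs <- make_longitudinal_case(sp, 42)
  lab <- msynth:::cpp_label_components(cs$new_lesion_mask$data, 26L)
  ncomp <- attr(lab, "n_components")
  expect_gte(ncomp, 2)
  expect_lte(ncomp, 4)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  expect_true(all(sizes >= 3)) # survives the minimum-size inference rule
  # lesion voxels lie strictly inside follow-up WM: FLAIR render of lesions is
  # brighter than WM mean, T1 darker (noise-free check on a dedicated case)
  sp0 <- phantom_spec(noise_sd = 0, bias_amplitude = 0)
  cs0 <- make_longitudinal_case(sp0, 43)
  les <- cs0$new_lesion_mask$data > 0
  expect_true(all(cs0$followup$FLAIR$data[les] >
                    sp0$contrast_flair[["WM"]]))
  expect_true(all(cs0$followup$T1$data[les] < sp0$contrast_t1[["WM"]]))
  # stable case
  st <- make_longitudinal_case(phantom_spec(n_new_lesions = c(0L, 0L)), 7)
  expect_equal(sum(st$new_lesion_mask$data), 0)
})

test_that("dataset generation writes a reproducible manifest", {
  sp <- phantom_spec(dims = c(32, 32, 32), n_new_lesions = c(1L, 2L),
                     lesion_radius_vox = c(1, 1.5))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- make_dataset(3, sp, d1, seed = 9)
  m2 <- make_dataset(3, sp, d2, seed = 9)
  expect_equal(nrow(m1), 3)
  expect_true(all(file.exists(file.path(m1$dir, m1$followup_flair))))
  expect_identical(m1$n_lesions, m2$n_lesions)
  expect_identical(m1$seed, m2$seed)
  # manifests byte-identical up to the directory prefix
  t1 <- readLines(file.path(d1, "manifest.tsv"))
  t2 <- readLines(file.path(d2, "manifest.tsv"))
  expect_identical(gsub("ds1", "ds2", t1), t2)
  # cases round trip from disk
  cs <- read_case(m1$dir[1])
  expect_s3_class(cs, "ms_case")
  expect_equal(dim(cs$followup$FLAIR$data), c(32L, 32L, 32L))
})
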
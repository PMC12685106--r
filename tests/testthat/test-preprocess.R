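test_that("peaks 4 ppm apart merge and peaks 25 ppm apart split", {
  close_pair <- match_peaks(list(spec(700.0000), spec(700.0028)),
                            max_shift_ppm = 8, mz_window = NULL)
  expect_length(close_pair$mz, 1)
  far_pair <- match_peaks(list(spec(700.0000), spec(700.0175)),
                          max_shift_ppm = 8, mz_window = NULL)
  expect_length(far_pair$mz, 2)
})

test_that("consensus m/z is the intensity-weighted member mean", {
  pm <- match_peaks(list(spec(700.0000, 30), spec(700.0028, 10)),
                    mz_window = NULL)
  expect_equal(pm$mz, (700.0000 * 30 + 700.0028 * 10) / 40)
})

test_that("peaks outside the m/z window are discarded", {
  pm <- match_peaks(list(spec(c(550, 700, 1100), c(1, 2, 3))))
  expect_equal(pm$mz, 700)
  expect_equal(unname(pm$intensities[1, 1]), 2)
})

test_that("matching is invariant to the order of the input spectra", {
  set.seed(8)
  spectra <- lapply(1:6, function(i) {
    spec(runif(20, 600, 1000) * (1 + rnorm(20, 0, 3e-6)), runif(20, 1, 100))
  })
  a <- match_peaks(spectra)
  perm <- c(4, 1, 6, 2, 5, 3)
  b <- match_peaks(spectra[perm])
  expect_equal(a$mz, b$mz)
  expect_equal(unname(a$intensities[perm, ]), unname(b$intensities))
})

test_that("every member lies within the window of its consensus", {
  for (sd_seed in 1:5) {
    set.seed(sd_seed)
    centers <- runif(15, 600, 1000)
    spectra <- lapply(1:8, function(i) {
      mz <- centers * (1 + rnorm(15, 0, 2.5e-6))
      spec(mz, runif(15, 1, 50))
    })
    pm <- match_peaks(spectra, max_shift_ppm = 8, keep_members = TRUE)
    mem <- pm$members
    for (f in unique(mem$feature)) {
      g <- mem[mem$feature == f, ]
      cons <- pm$mz[f]
      expect_true(all(abs(g$mz - cons) / cons * 1e6 <= 8))
      expect_lte((max(g$mz) - min(g$mz)) / cons * 1e6, 16)
      expect_false(anyDuplicated(g$spectrum) > 0)
    }
  }
})

test_that("non-ascending spectra are rejected", {
  bad <- list(mz = c(700, 650), intensity = c(1, 1))
  expect_error(match_peaks(list(bad)), "ascending")
})

test_that("ROI averaging returns the single pixel unchanged and means pairs", {
  img <- msi_image("pA", data.frame(x = 0:2, y = 0L), list(
    spec(c(650, 700), c(10, 4)),
    spec(c(650, 700), c(10, 4)),
    spec(650, 10)
  ))
  mask1 <- roi_mask(data.frame(x = 0L, y = 0L, label = "cancer_tissue"))
  one <- average_roi(img, mask1, "cancer_tissue")
  expect_equal(one$mz, c(650, 700))
  expect_equal(one$intensity, c(10, 4))
  mask2 <- roi_mask(data.frame(x = 0:1, y = 0L,
                               label = rep("cancer_tissue", 2)))
  two <- average_roi(img, mask2, "cancer_tissue")
  expect_equal(two$intensity, c(10, 4)) # identical pixels: idempotent
  mask3 <- roi_mask(data.frame(x = c(1L, 2L), y = 0L,
                               label = rep("cancer_tissue", 2)))
  mixed <- average_roi(img, mask3, "cancer_tissue")
  expect_equal(mixed$intensity[mixed$mz == 700], 2) # (4 + 0) / 2
  expect_error(average_roi(img, mask1, "benign_tissue"), "pA")
})

test_that("PQN removes multiplicative per-sample scale", {
  set.seed(2)
  base <- runif(12, 10, 100)
  x <- rbind(A = base, B = 3 * base, C = 0.25 * base)
  pm <- peak_matrix(x, sort(runif(12, 600, 1000)))
  out <- pqn_normalize(pm)
  expect_equal(unname(out$intensities["A", ]), unname(out$intensities["B", ]))
  expect_equal(unname(out$intensities["A", ]), unname(out$intensities["C", ]))
  expect_equal(unname(out$pqn_factors["B"] / out$pqn_factors["A"]), 3)
})

test_that("PQN is idempotent and a single sample gets factor 1", {
  set.seed(3)
  # rows that differ only by scale: re-normalization is exactly the identity
  base <- runif(20, 1, 50)
  x <- outer(c(1, 2.5, 0.4), base)
  pm <- peak_matrix(x, sort(runif(20, 600, 1000)))
  once <- pqn_normalize(pm)
  twice <- pqn_normalize(once)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-12)
  expect_equal(unname(twice$pqn_factors), rep(1, 3), tolerance = 1e-12)
  # noisy rows: the second-pass factors concentrate at 1 as features grow
  xn <- matrix(rlnorm(8 * 300, 0, 0.3), 8, 300) * runif(8, 0.5, 2)
  pmn <- pqn_normalize(peak_matrix(xn, sort(runif(300, 600, 1000))))
  again <- pqn_normalize(pmn)
  expect_equal(unname(again$pqn_factors), rep(1, 8), tolerance = 0.05)
  single <- pqn_normalize(peak_matrix(x[1, , drop = FALSE],
                                      sort(runif(20, 600, 1000))))
  expect_equal(unname(single$pqn_factors), 1)
})

test_that("all-zero samples and the mean-quotient variant are handled", {
  x <- rbind(S1 = c(1, 2, 3), S2 = c(0, 0, 0))
  pm <- peak_matrix(x, c(650, 700, 750))
  expect_error(pqn_normalize(pm), "S2")
  x2 <- rbind(S1 = c(2, 4), S2 = c(1, 8))
  pm2 <- peak_matrix(x2, c(650, 700))
  out <- pqn_normalize(pm2, quotient = "mean")
  ref <- colMeans(x2)
  expect_equal(unname(out$pqn_factors["S2"]), mean(c(1 / ref[1], 8 / ref[2])),
               ignore_attr = TRUE)
})

test_that("a synthetic cohort yields exactly the planted + background features", {
  cfg <- msi_sim_config(n_cancer = 8L, n_benign = 6L, image_shape = c(10L, 10L),
                        n_background_peaks = 200L, seed = 17)
  co <- generate_cohort(cfg)
  pm <- patient_profiles(co$images, co$masks, co$meta)
  expect_length(pm$mz, 207)
  for (m in default_planted_features()$mz) {
    expect_lt(min(abs(pm$mz - m)) / m * 1e6, 8)
  }
})

test_that("PQN recovers the planted fold change under TIC scaling", {
  cfg <- msi_sim_config(n_cancer = 60L, n_benign = 60L, image_shape = c(8L, 8L),
                        n_background_peaks = 40L, tic_scale_range = c(0.5, 2),
                        seed = 19)
  co <- generate_cohort(cfg)
  pm <- patient_profiles(co$images, co$masks, co$meta)
  j <- which.min(abs(pm$mz - 688.4921))
  is_c <- co$meta$diagnosis == "cancer"
  ratio <- mean(pm$intensities[is_c, j]) / mean(pm$intensities[!is_c, j])
  expect_lt(abs(ratio - 1.24) / 1.24, 0.05)
})
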
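test_that("identical configurations generate identical cohorts and proteins", {
  cfg <- tiny_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$images, b$images)
  expect_identical(a$masks, b$masks)
  expect_identical(generate_protein_table(cfg, a), generate_protein_table(cfg, b))
})

test_that("null configuration yields equal class intensities through the pipeline", {
  pf <- default_planted_features()
  pf$fold_change <- 1
  pf$cv <- 0
  cfg <- tiny_config(seed = 3, planted_features = pf, n_background_peaks = 0L,
                     ppm_jitter_sd = 0, patient_cv = 0)
  co <- generate_cohort(cfg)
  # with no intensity noise and fold 1, PQN removes the per-pixel TIC scale
  # and every planted feature is identical across patients
  pm <- patient_profiles(co$images, co$masks, co$meta)
  planted_cols <- vapply(pf$mz, function(m) which.min(abs(pm$mz - m)), integer(1))
  for (j in planted_cols) {
    expect_lt(diff(range(pm$intensities[, j])) / mean(pm$intensities[, j]), 1e-6)
  }
})

test_that("empirical class-mean ratio converges to the configured fold change", {
  cfg <- msi_sim_config(n_cancer = 150L, n_benign = 150L,
                        image_shape = c(6L, 6L), n_background_peaks = 20L,
                        seed = 5)
  co <- generate_cohort(cfg)
  feat_mz <- co$truth$features$mz
  j <- which.min(abs(feat_mz - 688.4921))
  tissue <- co$masks[[1]]$label != "background"
  mean_at <- function(img) {
    mean(vapply(img$spectra[tissue], function(s) s$intensity[j], numeric(1)))
  }
  m <- vapply(co$images, mean_at, numeric(1))
  ratio <- mean(m[co$meta$diagnosis == "cancer"]) /
    mean(m[co$meta$diagnosis == "benign"])
  expect_lt(abs(ratio - 1.24) / 1.24, 0.05)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(tiny_config(n_cancer = 0), "n_cancer")
  expect_error(tiny_config(tic_scale_range = c(2, 0.5)), "tic_scale_range")
  expect_error(tiny_config(mz_range = c(700, 650)), "mz_range")
  expect_error(tiny_config(n_proteins = 5L, n_differential_proteins = 10L),
               "n_differential_proteins")
  pf <- default_planted_features(); pf$mz[1] <- 100
  expect_error(tiny_config(planted_features = pf), "planted_features")
  qf <- default_phenotype_features(); qf$cohort[1] <- "other"
  expect_error(tiny_config(phenotype_features = qf), "phenotype_features")
})

test_that("phenotype features shift high- vs low-risk patients of their cohort only", {
  qf <- data.frame(mz = 753.5636, fold_change = 4, cohort = "benign")
  cfg <- msi_sim_config(n_cancer = 40L, n_benign = 40L,
                        image_shape = c(6L, 6L), n_background_peaks = 10L,
                        phenotype_features = qf, patient_cv = 0,
                        fraction_high_risk_benign = 0.5,
                        fraction_high_risk_cancer = 0.5, seed = 9)
  co <- generate_cohort(cfg)
  j <- which.min(abs(co$truth$features$mz - 753.5636))
  tissue <- co$masks[[1]]$label != "background"
  m <- vapply(co$images, function(img) {
    mean(vapply(img$spectra[tissue], function(s) s$intensity[j], numeric(1)))
  }, numeric(1))
  grp <- interaction(co$meta$diagnosis, co$meta$phenotype)
  mg <- tapply(m, grp, mean)
  # high/low ratio ~ 4 within benign, ~ 1 within cancer
  expect_lt(abs(mg[["benign.high_risk"]] / mg[["benign.low_risk"]] - 4) / 4, 0.1)
  expect_lt(abs(mg[["cancer.high_risk"]] / mg[["cancer.low_risk"]] - 1), 0.1)
  # the contrast preserves the benign class mean: cancer/benign ratio stays ~1
  expect_lt(abs(mean(m[co$meta$diagnosis == "cancer"]) /
                  mean(m[co$meta$diagnosis == "benign"]) - 1), 0.1)
})

test_that("protein table is reproducible and encodes the planted structure", {
  cfg <- tiny_config(seed = 21)
  co <- generate_cohort(cfg)
  pt <- generate_protein_table(cfg, co)
  expect_equal(dim(pt), c(10L, 40L))
  expect_identical(rownames(pt), co$meta$patient_id)
  expect_length(attr(pt, "differential"), 10L)
  expect_equal(nrow(attr(pt, "correlated_with")), 2L)
  # zero effect size leaves classes exchangeable in expectation
  cfg0 <- tiny_config(seed = 21, protein_effect_size = 0,
                      n_cancer = 60L, n_benign = 60L, image_shape = c(4L, 4L))
  co0 <- generate_cohort(cfg0)
  pt0 <- generate_protein_table(cfg0, co0)
  is_c <- co0$meta$diagnosis == "cancer"
  dmax <- max(abs(colMeans(pt0[is_c, ]) - colMeans(pt0[!is_c, ])))
  expect_lt(dmax, 0.2) # ~ 4 SE of a mean difference at n = 60/60, sd 0.2
})

test_that("lipid-correlated proteins track the planted lipid latents", {
  cfg <- msi_sim_config(n_cancer = 120L, n_benign = 120L,
                        image_shape = c(4L, 4L), n_background_peaks = 5L,
                        n_proteins = 20L, n_differential_proteins = 5L,
                        n_correlated_proteins = 2L, protein_lipid_cor = 0.9,
                        seed = 13)
  co <- generate_cohort(cfg)
  pt <- generate_protein_table(cfg, co)
  link <- attr(pt, "correlated_with")
  is_b <- co$meta$diagnosis == "benign"
  for (i in seq_len(nrow(link))) {
    # within one class the differential shift is constant, so the
    # protein-lipid correlation is the configured coefficient
    lz <- log(co$truth$latent[is_b, sprintf("%.4f", link$lipid_mz[i])])
    r <- abs(cor(pt[is_b, link$protein[i]], lz))
    expect_gt(r, 0.8)
  }
  # an unlinked protein is uncorrelated
  r0 <- abs(cor(pt[, "protein_020"], log(co$truth$latent[, 1])))
  expect_lt(r0, 0.25)
})
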
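#' Default planted discriminatory lipid features
#'
#' The seven glycerophospholipid features elevated in cancer tissue that the
#' cohort generator plants by default: PE 32:1 (m/z 688.49), PA 36:2 (699.50),
#' PE 34:2 (714.51), PE 36:3 (740.52), PS 42:5 (864.57), PI 40:4 (913.58) and
#' PI 40:3 (915.59), with cancer/benign fold changes between 1.23 and 1.28.
#'
#' @param base_intensity baseline expected peak intensity (arbitrary units).
#' @param cv per-pixel coefficient of variation of the intensity law.
#' @return data.frame with columns `mz`, `fold_change`, `base_intensity`, `cv`.
#' @export
default_planted_features <- function(base_intensity = 100, cv = 0.3) {
  data.frame(
    mz = c(688.4921, 699.5014, 714.5123, 740.5229, 864.5707, 913.5778, 915.5901),
    fold_change = c(1.24, 1.27, 1.28, 1.27, 1.24, 1.23, 1.27),
    base_intensity = base_intensity,
    cv = cv
  )
}

#' Default phenotype-linked features
#'
#' Features whose intensity depends on the high-/low-risk metabolic phenotype
#' (obesity and/or diabetes) within one diagnostic cohort. In the benign
#' cohort four species are elevated in high-risk patients (fold changes
#' 4.03-10.97); in the cancer cohort three species are elevated in the
#' low-risk group, encoded here as fold changes below 1 applied to high-risk
#' patients.
#'
#' @return data.frame with columns `mz`, `fold_change`, `cohort`.
#' @export
default_phenotype_features <- function() {
  data.frame(
    mz = c(753.5636, 813.5425, 839.5628, 890.5829, 714.5123, 740.5229, 753.5636),
    fold_change = c(4.03, 3.09, 10.97, 5.06, 1 / 1.84, 1 / 1.63, 1 / 1.69),
    cohort = c(rep("benign", 4), rep("cancer", 3))
  )
}

#' Configuration for the synthetic DESI-MSI cohort generator
#'
#' Defines a two-class tissue cohort (default 50 cancer / 14 benign patients)
#' whose cancer spectra carry elevated intensity at the planted lipid
#' features. Per-pixel intensities follow a log-normal law with the stated
#' coefficient of variation, each whole pixel spectrum is multiplied by a
#' uniform total-ion-current scale (exercising PQN), and every peak m/z is
#' jittered by Gaussian ppm noise (exercising the 8-ppm peak matcher).
#' A per-patient multiplicative log-normal effect (`patient_cv`) models
#' between-patient biological variability that pixel averaging cannot remove.
#'
#' @param n_cancer,n_benign patient counts per class.
#' @param image_shape `(rows, cols)` of the pixel grid per patient.
#' @param planted_features data.frame of class-discriminatory features
#'   (`mz`, `fold_change`, `base_intensity`, `cv`); expected cancer-tissue
#'   intensity is `base_intensity * fold_change`, benign is `base_intensity`.
#' @param n_background_peaks number of non-discriminatory peaks, placed
#'   uniformly in `mz_range` at least 50 ppm from every other feature.
#' @param mz_range analysed m/z window in Da.
#' @param ppm_jitter_sd per-pixel, per-peak Gaussian m/z jitter SD in ppm.
#' @param tic_scale_range range of the per-pixel uniform multiplicative
#'   intensity factor.
#' @param patient_cv coefficient of variation of the per-patient, per-feature
#'   multiplicative biological effect (0 disables it).
#' @param fraction_high_risk_cancer,fraction_high_risk_benign proportion of
#'   high-risk (obesity and/or diabetes) phenotypes per cohort; defaults
#'   26/50 and 5/14.
#' @param phenotype_features data.frame (`mz`, `fold_change`, `cohort`) of
#'   features elevated (fold > 1) or depleted (fold < 1) in high-risk
#'   patients of the stated cohort only, or `NULL` (default) for none;
#'   [default_phenotype_features()] supplies the subgroup-analysis set. The
#'   contrast is mean-preserving within the cohort, so class-level fold
#'   changes are unaffected.
#' @param n_proteins,n_differential_proteins size of the protein panel and
#'   number of proteins with a true class effect.
#' @param protein_effect_size standardized mean difference (cancer - benign)
#'   of differential proteins.
#' @param n_correlated_proteins how many differential proteins are generated
#'   correlated with planted lipid features (taken in order).
#' @param protein_lipid_cor correlation coefficient of those protein-lipid
#'   pairs.
#' @param seed integer RNG seed; identical configurations generate identical
#'   cohorts.
#' @return object of class `msi_sim_config`.
#' @export
msi_sim_config <- function(n_cancer = 50L, n_benign = 14L,
                           image_shape = c(20L, 20L),
                           planted_features = default_planted_features(),
                           n_background_peaks = 200L,
                           mz_range = c(600, 1000),
                           ppm_jitter_sd = 2,
                           tic_scale_range = c(0.5, 2),
                           patient_cv = 0.1,
                           fraction_high_risk_cancer = 26 / 50,
                           fraction_high_risk_benign = 5 / 14,
                           phenotype_features = NULL,
                           n_proteins = 282L,
                           n_differential_proteins = 104L,
                           protein_effect_size = 1.5,
                           n_correlated_proteins = 4L,
                           protein_lipid_cor = 0.9,
                           seed = 1L) {
  cfg <- list(
    n_cancer = as.integer(n_cancer), n_benign = as.integer(n_benign),
    image_shape = as.integer(image_shape),
    planted_features = planted_features,
    n_background_peaks = as.integer(n_background_peaks),
    mz_range = as.numeric(mz_range),
    ppm_jitter_sd = as.numeric(ppm_jitter_sd),
    tic_scale_range = as.numeric(tic_scale_range),
    patient_cv = as.numeric(patient_cv),
    fraction_high_risk_cancer = as.numeric(fraction_high_risk_cancer),
    fraction_high_risk_benign = as.numeric(fraction_high_risk_benign),
    phenotype_features = phenotype_features,
    n_proteins = as.integer(n_proteins),
    n_differential_proteins = as.integer(n_differential_proteins),
    protein_effect_size = as.numeric(protein_effect_size),
    n_correlated_proteins = as.integer(n_correlated_proteins),
    protein_lipid_cor = as.numeric(protein_lipid_cor),
    seed = as.integer(seed)
  )
  class(cfg) <- "msi_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_cancer) || cfg$n_cancer < 1) stop_field("n_cancer", "must be a count >= 1")
  if (!is_count(cfg$n_benign) || cfg$n_benign < 1) stop_field("n_benign", "must be a count >= 1")
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 1)) {
    stop_field("image_shape", "must be (rows, cols) with both >= 1")
  }
  if (length(cfg$mz_range) != 2L || cfg$mz_range[1] >= cfg$mz_range[2]) {
    stop_field("mz_range", "must be (low, high) with low < high")
  }
  pf <- cfg$planted_features
  if (!is.data.frame(pf) || !all(c("mz", "fold_change", "base_intensity", "cv") %in% names(pf))) {
    stop_field("planted_features", "needs columns mz, fold_change, base_intensity, cv")
  }
  if (any(pf$mz < cfg$mz_range[1] | pf$mz > cfg$mz_range[2])) {
    stop_field("planted_features", "every planted mz must lie within mz_range")
  }
  if (any(pf$fold_change <= 0)) stop_field("planted_features", "fold_change must be > 0")
  if (any(pf$cv < 0)) stop_field("planted_features", "cv must be >= 0")
  if (!is.null(cfg$phenotype_features)) {
    qf <- cfg$phenotype_features
    if (!is.data.frame(qf) || !all(c("mz", "fold_change", "cohort") %in% names(qf))) {
      stop_field("phenotype_features", "needs columns mz, fold_change, cohort")
    }
    if (!all(qf$cohort %in% c("benign", "cancer"))) {
      stop_field("phenotype_features", "cohort must be 'benign' or 'cancer'")
    }
    if (any(qf$fold_change <= 0)) stop_field("phenotype_features", "fold_change must be > 0")
    if (any(qf$mz < cfg$mz_range[1] | qf$mz > cfg$mz_range[2])) {
      stop_field("phenotype_features", "every mz must lie within mz_range")
    }
  }
  if (!is_count(cfg$n_background_peaks)) stop_field("n_background_peaks", "must be a count")
  if (!is_number(cfg$ppm_jitter_sd) || cfg$ppm_jitter_sd < 0) {
    stop_field("ppm_jitter_sd", "must be a non-negative number")
  }
  if (length(cfg$tic_scale_range) != 2L || cfg$tic_scale_range[1] >= cfg$tic_scale_range[2] ||
      cfg$tic_scale_range[1] <= 0) {
    stop_field("tic_scale_range", "must be (low, high) with 0 < low < high")
  }
  if (!is_number(cfg$patient_cv) || cfg$patient_cv < 0) stop_field("patient_cv", "must be >= 0")
  for (f in c("fraction_high_risk_cancer", "fraction_high_risk_benign")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0, 1]")
  }
  if (!is_count(cfg$n_proteins)) stop_field("n_proteins", "must be a count")
  if (!is_count(cfg$n_differential_proteins)) stop_field("n_differential_proteins", "must be a count")
  if (cfg$n_differential_proteins > cfg$n_proteins) {
    stop_field("n_differential_proteins", "cannot exceed n_proteins")
  }
  if (cfg$n_correlated_proteins > cfg$n_differential_proteins) {
    stop_field("n_correlated_proteins", "cannot exceed n_differential_proteins")
  }
  if (!is_number(cfg$protein_lipid_cor) || abs(cfg$protein_lipid_cor) > 1) {
    stop_field("protein_lipid_cor", "must be in [-1, 1]")
  }
  if (!is_count(abs(cfg$seed))) stop_field("seed", "must be an integer")
  invisible(cfg)
}

# Internal: full feature table for a configuration. Planted class features
# first, then phenotype-only features, then background peaks (drawn with
# >= 50 ppm separation from every other feature and each other).
# Consumes RNG: background m/z, then background base intensities.
build_feature_table <- function(cfg) {
  pf <- cfg$planted_features
  feat <- data.frame(
    mz = pf$mz, base = pf$base_intensity, cv = pf$cv,
    class_fold = pf$fold_change, role = "planted"
  )
  if (!is.null(cfg$phenotype_features)) {
    extra_mz <- setdiff(unique(cfg$phenotype_features$mz), feat$mz)
    if (length(extra_mz)) {
      feat <- rbind(feat, data.frame(
        mz = extra_mz, base = 100, cv = 0.3, class_fold = 1, role = "phenotype"
      ))
    }
  }
  n_bg <- cfg$n_background_peaks
  if (n_bg > 0) {
    bg <- numeric(0)
    guard <- 0L
    while (length(bg) < n_bg) {
      cand <- stats::runif(n_bg, cfg$mz_range[1], cfg$mz_range[2])
      for (m in cand) {
        others <- c(feat$mz, bg)
        if (all(abs(m - others) / others * 1e6 >= 50)) bg <- c(bg, m)
        if (length(bg) == n_bg) break
      }
      guard <- guard + 1L
      if (guard > 1000L) stop("could not place background peaks with 50 ppm separation")
    }
    bg_base <- exp(stats::runif(n_bg, log(20), log(200)))
    feat <- rbind(feat, data.frame(
      mz = bg, base = bg_base, cv = 0.3, class_fold = 1, role = "background"
    ))
  }
  feat[order(feat$mz), , drop = FALSE]
}

# Internal: patient metadata. Consumes RNG: phenotype assignment, grades,
# stages. Grade/stage frequencies follow the study cohort (grades 1:2:3
# roughly balanced, most cancers stage I).
build_patient_meta <- function(cfg) {
  n <- cfg$n_cancer + cfg$n_benign
  ids <- sprintf("P%03d", seq_len(n))
  diagnosis <- c(rep("cancer", cfg$n_cancer), rep("benign", cfg$n_benign))
  phenotype <- rep("low_risk", n)
  k_c <- round(cfg$fraction_high_risk_cancer * cfg$n_cancer)
  k_b <- round(cfg$fraction_high_risk_benign * cfg$n_benign)
  if (k_c > 0) phenotype[sample(which(diagnosis == "cancer"), k_c)] <- "high_risk"
  if (k_b > 0) phenotype[sample(which(diagnosis == "benign"), k_b)] <- "high_risk"
  grade <- rep(NA_character_, n)
  stage <- rep(NA_character_, n)
  ic <- which(diagnosis == "cancer")
  grade[ic] <- sample(c("1", "2", "3", "unknown"), length(ic), replace = TRUE,
                      prob = c(0.30, 0.38, 0.30, 0.02))
  stage[ic] <- sample(c("IA", "IB", "II", "III", "IV"), length(ic), replace = TRUE,
                      prob = c(0.40, 0.32, 0.08, 0.16, 0.04))
  data.frame(patient_id = ids, diagnosis = diagnosis, grade = grade,
             stage = stage, phenotype = phenotype)
}

#' Generate a synthetic DESI-MSI cohort
#'
#' Produces one mass spectrometry image, region-of-interest mask and metadata
#' record per patient. Each image is a `rows x cols` pixel grid with a
#' circular tissue region; tissue pixels carry all planted, phenotype and
#' background peaks with log-normal intensity noise, a per-pixel uniform
#' total-ion-current scale and Gaussian ppm m/z jitter; off-tissue pixels
#' carry the same peaks at ~1% intensity. The RNG stream is consumed in a
#' fixed documented order (background features, metadata, patient effects,
#' then per-patient pixel draws), so a configuration reproduces its cohort
#' exactly.
#'
#' @param config an [msi_sim_config()] object.
#' @return object of class `msi_cohort`: list with elements `images` (list of
#'   `msi_image`), `masks` (list of `roi_mask`), `meta` (data.frame), and
#'   `truth` (generator ground truth: feature table and per-patient latent
#'   effects at the planted features, used by [generate_protein_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "msi_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  feat <- build_feature_table(config)
  meta <- build_patient_meta(config)
  n_pat <- nrow(meta)
  n_feat <- nrow(feat)

  # per-patient multiplicative biological effect, one per patient x feature
  if (config$patient_cv > 0) {
    latent <- matrix(
      stats::rlnorm(n_pat * n_feat, lnorm_meanlog(config$patient_cv),
                    lnorm_sdlog(config$patient_cv)),
      n_pat, n_feat
    )
  } else {
    latent <- matrix(1, n_pat, n_feat)
  }
  rownames(latent) <- meta$patient_id
  colnames(latent) <- sprintf("%.4f", feat$mz)

  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  xy <- expand.grid(x = seq_len(cols) - 1L, y = seq_len(rows) - 1L)
  cx <- (cols - 1) / 2; cy <- (rows - 1) / 2
  radius <- 0.8 * min(rows, cols) / 2
  tissue <- (xy$x - cx)^2 + (xy$y - cy)^2 <= radius^2
  if (!any(tissue)) tissue[1] <- TRUE
  npix <- nrow(xy)

  images <- vector("list", n_pat)
  masks <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    is_cancer <- meta$diagnosis[i] == "cancer"
    expected <- feat$base * latent[i, ]
    if (is_cancer) expected <- expected * feat$class_fold
    if (!is.null(config$phenotype_features)) {
      # mean-preserving phenotype contrast: high-risk patients of the stated
      # cohort are scaled by f/(p*f + 1 - p) and low-risk by 1/(p*f + 1 - p),
      # where p is the cohort's high-risk fraction, so the high/low intensity
      # ratio equals f while the cohort's class mean (and hence the
      # cancer-vs-benign fold change) is unchanged
      qf <- config$phenotype_features[config$phenotype_features$cohort == meta$diagnosis[i], ]
      p_hr <- if (is_cancer) config$fraction_high_risk_cancer else config$fraction_high_risk_benign
      for (j in seq_len(nrow(qf))) {
        idx <- which(abs(feat$mz - qf$mz[j]) < 1e-9)
        f <- qf$fold_change[j]
        denom <- p_hr * f + (1 - p_hr)
        mult <- if (meta$phenotype[i] == "high_risk") f / denom else 1 / denom
        expected[idx] <- expected[idx] * mult
      }
    }
    # RNG per patient: tic scales, intensities, jitter (fixed order)
    tic <- stats::runif(npix, config$tic_scale_range[1], config$tic_scale_range[2])
    noise <- matrix(
      stats::rlnorm(n_feat * npix, lnorm_meanlog(feat$cv), lnorm_sdlog(feat$cv)),
      n_feat, npix
    )
    # jitter truncated at 3.5 SD so the within-feature ppm spread stays
    # below the default 8-ppm matching window (2 ppm * 3.5 = 7 ppm)
    jit <- matrix(pmin(pmax(stats::rnorm(n_feat * npix), -3.5), 3.5) *
                    config$ppm_jitter_sd, n_feat, npix)
    inten <- expected * noise
    inten[, !tissue] <- inten[, !tissue, drop = FALSE] * 0.01
    inten <- sweep(inten, 2, tic, `*`)
    mzmat <- feat$mz * (1 + jit * 1e-6)

    spectra <- vector("list", npix)
    for (p in seq_len(npix)) {
      o <- order(mzmat[, p])
      spectra[[p]] <- list(mz = mzmat[o, p], intensity = inten[o, p])
    }
    images[[i]] <- msi_image(
      patient_id = meta$patient_id[i],
      coords = xy,
      spectra = spectra,
      mode = "processed",
      spatial_resolution = 100
    )
    lab <- ifelse(tissue, if (is_cancer) "cancer_tissue" else "benign_tissue", "background")
    masks[[i]] <- roi_mask(data.frame(x = xy$x, y = xy$y, label = lab))
  }

  out <- list(
    images = images, masks = masks, meta = meta,
    truth = list(
      features = feat,
      latent = latent[, feat$role == "planted", drop = FALSE],
      tissue_pixels = sum(tissue)
    )
  )
  class(out) <- "msi_cohort"
  out
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic DESI-MSI cohort: %d patients (%d cancer / %d benign), %d features\n",
    nrow(x$meta), sum(x$meta$diagnosis == "cancer"), sum(x$meta$diagnosis == "benign"),
    nrow(x$truth$features)
  ))
  invisible(x)
}

#' Generate a synthetic protein expression table
#'
#' Emulates a reverse phase protein array panel for the cohort's patients.
#' Expression is drawn around a baseline of 1 with SD 0.2; the first
#' `n_differential_proteins` carry a class-mean difference of
#' `protein_effect_size` standardized units (direction random per protein),
#' and the first `n_correlated_proteins` of those are generated correlated
#' (coefficient `protein_lipid_cor`) with the patient-level latent effects of
#' the planted lipid features, to exercise the lipid-protein integration.
#'
#' @param config an [msi_sim_config()] object.
#' @param cohort the `msi_cohort` the proteins belong to (its `meta` and
#'   generator ground truth are used). A bare metadata data.frame is accepted
#'   when no lipid correlation is requested.
#' @return numeric matrix (patients x proteins) of class `protein_table`,
#'   with attributes `differential` (protein names with a true effect),
#'   `direction` (+1/-1 per differential protein) and `correlated_with`
#'   (data.frame protein, lipid_mz, rho).
#' @export
generate_protein_table <- function(config, cohort) {
  stopifnot(inherits(config, "msi_sim_config"))
  if (inherits(cohort, "msi_cohort")) {
    meta <- cohort$meta
    latent <- cohort$truth$latent
  } else {
    meta <- cohort
    latent <- NULL
  }
  if (!is.data.frame(meta) || nrow(meta) == 0L) stop("patient metadata must be non-empty")
  if (config$n_correlated_proteins > 0 && is.null(latent)) {
    stop("lipid-correlated proteins require the full msi_cohort object")
  }
  set.seed(config$seed + 1L)
  n <- nrow(meta)
  p <- config$n_proteins
  nd <- config$n_differential_proteins
  base_sd <- 0.2
  z <- matrix(stats::rnorm(n * p), n, p)
  direction <- if (nd > 0) sample(c(-1, 1), nd, replace = TRUE) else numeric(0)

  nc <- config$n_correlated_proteins
  corr_map <- NULL
  if (nc > 0) {
    rho <- config$protein_lipid_cor
    k <- min(nc, ncol(latent))
    lip_z <- scale(log(latent[, seq_len(k), drop = FALSE]))
    for (j in seq_len(nc)) {
      lz <- lip_z[, ((j - 1) %% k) + 1]
      z[, j] <- rho * lz + sqrt(1 - rho^2) * z[, j]
    }
    corr_map <- data.frame(
      protein = sprintf("protein_%03d", seq_len(nc)),
      lipid_mz = as.numeric(colnames(latent))[((seq_len(nc) - 1) %% k) + 1],
      rho = rho
    )
  }

  values <- 1 + base_sd * z
  if (nd > 0) {
    shift <- base_sd * config$protein_effect_size
    is_cancer <- meta$diagnosis == "cancer"
    for (j in seq_len(nd)) {
      values[is_cancer, j] <- values[is_cancer, j] + direction[j] * shift
    }
  }
  dimnames(values) <- list(meta$patient_id, sprintf("protein_%03d", seq_len(p)))
  structure(values,
    class = c("protein_table", "matrix", "array"),
    differential = colnames(values)[seq_len(nd)],
    direction = direction,
    correlated_with = corr_map
  )
}
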
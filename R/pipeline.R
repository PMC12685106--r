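# End-to-end orchestration: simulate -> preprocess -> classify -> stats ->
# annotate -> rppa -> integrate, with every stage reading its inputs from
# and writing its outputs to files under the run directory, plus a manifest
# recording parameters, seed and per-stage wall time.

#' Read / write a peak matrix as TSV (+ JSON sidecar)
#'
#' Rows are samples, columns are consensus m/z printed to 4 decimals; the
#' sidecar (`<path>.json`) records the normalization state and PQN factors.
#'
#' @param pm a [peak_matrix()].
#' @param path TSV path.
#' @return `read_peak_matrix` returns a `peak_matrix`.
#' @export
write_peak_matrix <- function(pm, path) {
  df <- data.frame(sample_id = pm$sample_ids, pm$intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(normalization = pm$normalization, mz = pm$mz)
  if (!is.null(pm$pqn_factors)) {
    side$pqn_factors <- as.list(stats::setNames(pm$pqn_factors, pm$sample_ids))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  factors <- side$pqn_factors
  if (!is.null(factors)) factors <- unlist(factors)[df$sample_id]
  peak_matrix(m, as.numeric(side$mz), df$sample_id,
              normalization = side$normalization, pqn_factors = factors)
}

#' Pipeline run configuration
#'
#' Collects the tunable parameters of every stage. Either supply input paths
#' (`imzml_dir` containing `<patient_id>.imzML` files, `masks_dir` with
#' `<patient_id>_mask.tsv`, `metadata`, `protein_table` TSVs) or set
#' `simulate = TRUE` to generate a synthetic cohort into the run directory
#' first.
#'
#' @param out_dir run directory (created if needed).
#' @param simulate generate a synthetic cohort as the input data.
#' @param sim_config an [msi_sim_config()] when simulating.
#' @param imzml_dir,masks_dir,metadata,protein_table input paths when not
#'   simulating.
#' @param lipid_table reference table TSV (`NULL` for the bundled table).
#' @param mz_window,max_shift_ppm,pqn_quotient preprocessing parameters.
#' @param k,standardize,positive classification parameters.
#' @param q_threshold FDR threshold used by the stats and rppa stages.
#' @param tol_ppm,max_isotope annotation parameters.
#' @param linkage integration dendrogram linkage.
#' @param n_integration_proteins cap on the `q < q_threshold` proteins
#'   carried into the integration stage (most significant first).
#' @param seed RNG seed for the simulated cohort.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, sim_config = NULL,
                            imzml_dir = NULL, masks_dir = NULL,
                            metadata = NULL, protein_table = NULL,
                            lipid_table = NULL,
                            mz_window = c(600, 1000), max_shift_ppm = 8,
                            pqn_quotient = "median", k = 1,
                            standardize = FALSE, positive = "cancer",
                            q_threshold = 0.05, tol_ppm = 10, max_isotope = 1,
                            linkage = "average",
                            n_integration_proteins = 23, seed = 1L) {
  if (!simulate) {
    for (p in c(imzml_dir, masks_dir, metadata, protein_table)) {
      if (is.null(p) || !file.exists(p)) {
        stop(sprintf("input path missing or not found: %s",
                     if (is.null(p)) "(unset)" else p), call. = FALSE)
      }
    }
  }
  cfg <- list(out_dir = out_dir, simulate = simulate,
              sim_config = sim_config %||% msi_sim_config(seed = seed),
              imzml_dir = imzml_dir, masks_dir = masks_dir,
              metadata = metadata, protein_table = protein_table,
              lipid_table = lipid_table, mz_window = mz_window,
              max_shift_ppm = max_shift_ppm, pqn_quotient = pqn_quotient,
              k = k, standardize = standardize, positive = positive,
              q_threshold = q_threshold, tol_ppm = tol_ppm,
              max_isotope = max_isotope, linkage = linkage,
              n_integration_proteins = n_integration_proteins,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Flat key-value file whose keys mirror the arguments of
#' [pipeline_config()]; unknown keys are rejected.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(out_dir)) vals$out_dir <- out_dir
  sim_keys <- intersect(names(vals), names(formals(msi_sim_config)))
  cfg_keys <- setdiff(names(vals), sim_keys)
  unknown <- setdiff(cfg_keys, names(formals(pipeline_config)))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(sim_keys)) {
    if (!is.null(vals$seed) && !"seed" %in% sim_keys) sim_keys <- c(sim_keys, "seed")
    vals$sim_config <- do.call(msi_sim_config, vals[sim_keys])
    vals <- vals[setdiff(names(vals), setdiff(sim_keys, "seed"))]
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, each stage reading the previous stage's
#' written artifacts: cohort simulation (optional), per-patient profile
#' construction (ROI averaging, peak matching, PQN), RMMC-LDA with
#' leave-one-patient-out cross-validation, univariate feature statistics,
#' lipid annotation, per-protein logistic regression, and cosine-distance
#' lipid-protein integration. A `manifest.json` records parameters, seed,
#' package version and per-stage wall time. On stage failure, partial
#' results and the manifest are preserved and the error names the stage.
#'
#' @param config a [pipeline_config()].
#' @return run report (list of stage outputs) invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "desimsi",
    version = as.character(utils::packageVersion("desimsi")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim_config"))],
    stages = list()
  )
  report <- list()
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  input_dir <- file.path(out, "input")
  if (config$simulate) {
    report$simulate <- t_stage("simulate", function() {
      dir.create(input_dir, showWarnings = FALSE)
      cohort <- generate_cohort(config$sim_config)
      for (i in seq_along(cohort$images)) {
        id <- cohort$meta$patient_id[i]
        write_imzml(cohort$images[[i]], file.path(input_dir, paste0(id, ".imzML")))
        write_mask(cohort$masks[[i]], file.path(input_dir, paste0(id, "_mask.tsv")))
      }
      write_metadata(cohort$meta, file.path(input_dir, "metadata.tsv"))
      prot <- generate_protein_table(config$sim_config, cohort)
      write_protein_table(prot, file.path(input_dir, "proteins.tsv"))
      list(n_patients = nrow(cohort$meta))
    })
    config$imzml_dir <- input_dir
    config$masks_dir <- input_dir
    config$metadata <- file.path(input_dir, "metadata.tsv")
    config$protein_table <- file.path(input_dir, "proteins.tsv")
  }

  meta <- read_metadata(config$metadata)
  pm_path <- file.path(out, "peak_matrix.tsv")

  report$preprocess <- t_stage("preprocess", function() {
    files <- file.path(config$imzml_dir, paste0(meta$patient_id, ".imzML"))
    missing <- !file.exists(files)
    if (any(missing)) {
      stop(sprintf("imzML file not found: %s", files[which(missing)[1]]))
    }
    images <- lapply(files, read_imzml)
    masks <- lapply(file.path(config$masks_dir,
                              paste0(meta$patient_id, "_mask.tsv")), read_mask)
    pm <- patient_profiles(images, masks, meta, mz_window = config$mz_window,
                           max_shift_ppm = config$max_shift_ppm,
                           quotient = config$pqn_quotient)
    write_peak_matrix(pm, pm_path)
    list(n_features = length(pm$mz))
  })

  report$classify <- t_stage("classify", function() {
    pm <- read_peak_matrix(pm_path)
    labels <- meta$diagnosis[match(pm$sample_ids, meta$patient_id)]
    cv <- lopo_cv(pm$intensities, labels, pm$sample_ids, k = config$k,
                  standardize = config$standardize, positive = config$positive)
    m <- metrics(cv)
    jsonlite::write_json(
      list(confusion = cv$confusion[c("tp", "fn", "tn", "fp")],
           positive = cv$positive, metrics = as.list(m)),
      file.path(out, "classification.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(cv$predictions, file.path(out, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cv
  })

  report$stats <- t_stage("stats", function() {
    pm <- read_peak_matrix(pm_path)
    labels <- meta$diagnosis[match(pm$sample_ids, meta$patient_id)]
    st <- feature_stats(pm, factor(labels, levels = c(config$positive,
                                                      setdiff(unique(labels),
                                                              config$positive))))
    utils::write.table(st, file.path(out, "feature_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    st
  })

  report$annotate <- t_stage("annotate", function() {
    pm <- read_peak_matrix(pm_path)
    st <- utils::read.delim(file.path(out, "feature_stats.tsv"))
    tab <- if (is.null(config$lipid_table)) lipid_reference()
           else read_lipid_table(config$lipid_table)
    ann <- annotate_matrix(pm, tab, tol_ppm = config$tol_ppm,
                           max_isotope = config$max_isotope, stats = st)
    utils::write.table(ann, file.path(out, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ann
  })

  report$rppa <- t_stage("rppa", function() {
    prot <- read_protein_table(config$protein_table)
    rp <- rppa_pipeline(prot, meta, positive = config$positive,
                        q_threshold = config$q_threshold)
    utils::write.table(rp, file.path(out, "protein_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rp
  })

  report$integrate <- t_stage("integrate", function() {
    pm <- read_peak_matrix(pm_path)
    st <- utils::read.delim(file.path(out, "feature_stats.tsv"))
    rp <- utils::read.delim(file.path(out, "protein_stats.tsv"))
    prot <- read_protein_table(config$protein_table)
    sel_lip <- select_discriminatory(st, config$q_threshold)
    if (nrow(sel_lip) == 0) stop("no discriminatory lipid features to integrate")
    lip_cols <- match(sprintf("%.4f", sel_lip$mz), colnames(pm$intensities))
    sig <- rp[!is.na(rp$q_value) & rp$q_value < config$q_threshold, , drop = FALSE]
    sig <- sig[order(sig$q_value, sig$p_value), , drop = FALSE]
    keep_prot <- utils::head(sig$protein, config$n_integration_proteins)
    if (length(keep_prot) == 0) stop("no significant proteins to integrate")
    shared <- intersect(pm$sample_ids, rownames(prot))
    lipm <- pm$intensities[shared, lip_cols, drop = FALSE]
    protm <- prot[shared, keep_prot, drop = FALSE]
    nm <- normalize_modalities(lipm, protm)
    cc <- cosine_distance_matrix(nm)
    cl <- hierarchical_cluster(cc, linkage = config$linkage)
    utils::write.table(
      data.frame(species = cc$species_names, modality = cc$modality,
                 cc$similarity_matrix, check.names = FALSE),
      file.path(out, "similarity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_newick(cl, file.path(out, "dendrogram.nwk"))
    list(cross_corr = cc, clustering = cl)
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
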
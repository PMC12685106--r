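# Spectral preprocessing: ROI averaging, ppm-constrained peak matching and
# probabilistic quotient normalization.

#' Construct a peak matrix
#'
#' Samples x consensus-feature intensity matrix produced by [match_peaks()].
#'
#' @param intensities numeric matrix, rows = samples, columns = features.
#' @param mz numeric vector of consensus m/z values, strictly ascending.
#' @param sample_ids character vector of row identifiers.
#' @param normalization `"raw"` or `"pqn"`.
#' @param pqn_factors per-sample positive scale factors (present iff pqn).
#' @return object of class `peak_matrix`.
#' @export
peak_matrix <- function(intensities, mz, sample_ids = rownames(intensities),
                        normalization = "raw", pqn_factors = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  if (length(mz) != ncol(intensities)) stop("mz length must equal feature count", call. = FALSE)
  if (length(mz) > 1 && any(diff(mz) <= 0)) stop("consensus m/z must be strictly ascending", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.null(pqn_factors) && any(pqn_factors <= 0)) stop("pqn_factors must be > 0", call. = FALSE)
  dimnames(intensities) <- list(sample_ids, sprintf("%.4f", mz))
  structure(
    list(sample_ids = sample_ids, mz = as.numeric(mz), intensities = intensities,
         normalization = normalization, pqn_factors = pqn_factors),
    class = "peak_matrix"
  )
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("Peak matrix: %d samples x %d features (%s), m/z %.4f-%.4f\n",
              nrow(x$intensities), ncol(x$intensities), x$normalization,
              min(x$mz), max(x$mz)))
  invisible(x)
}

check_spectrum <- function(sp, what = "spectrum") {
  if (length(sp$mz) > 1 && any(diff(sp$mz) <= 0)) {
    stop(sprintf("%s: m/z values not strictly ascending", what), call. = FALSE)
  }
  invisible(sp)
}

# Internal single-linkage-style sweep: pooled peaks sorted by m/z are
# chained left to right; a feature closes when the gap from the last member
# to the next peak exceeds max_shift_ppm evaluated at the running
# intensity-weighted consensus. Returns a cluster id per pooled peak.
# Vectorized approximation-free form: the chaining decision depends on the
# adjacent gap and the running consensus, so it is computed in one pass.
sweep_cluster <- function(mz, intensity, max_shift_ppm) {
  n <- length(mz)
  cl <- integer(n)
  if (n == 0L) return(cl)
  cur <- 1L
  sum_w <- intensity[1]
  sum_wm <- intensity[1] * mz[1]
  cnt <- 1L
  sum_m <- mz[1]
  cl[1] <- cur
  for (i in seq_len(n)[-1]) {
    consensus <- if (sum_w > 0) sum_wm / sum_w else sum_m / cnt
    if ((mz[i] - mz[i - 1]) <= max_shift_ppm * consensus * 1e-6) {
      cl[i] <- cur
      sum_w <- sum_w + intensity[i]
      sum_wm <- sum_wm + intensity[i] * mz[i]
      cnt <- cnt + 1L
      sum_m <- sum_m + mz[i]
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      sum_w <- intensity[i]
      sum_wm <- intensity[i] * mz[i]
      cnt <- 1L
      sum_m <- mz[i]
    }
  }
  cl
}

consensus_of <- function(mz, intensity) {
  if (sum(intensity) > 0) sum(mz * intensity) / sum(intensity) else mean(mz)
}

#' Match peaks across spectra into consensus features
#'
#' Clusters the pooled peaks of all spectra into consensus features such
#' that every member peak lies within `max_shift_ppm` of the feature's
#' intensity-weighted consensus m/z. Each spectrum contributes at most one
#' peak per feature: when several of a spectrum's peaks fall into one
#' cluster, the nearest in ppm wins (ties toward the higher-intensity peak)
#' and the losers are re-clustered into features of their own. Peaks outside
#' `mz_window` are discarded; features a spectrum lacks are recorded as 0.
#' The result is invariant to the order of the input spectra.
#'
#' @param spectra list of spectra, each `list(mz =, intensity =)` with
#'   ascending m/z.
#' @param max_shift_ppm maximum peak shift in ppm (default 8).
#' @param mz_window `(low, high)` analysis window in Da (default 600-1000);
#'   `NULL` keeps the full range.
#' @param sample_ids optional row identifiers.
#' @param keep_members also return the per-peak feature assignment (element
#'   `members`: data.frame with `spectrum`, `mz`, `intensity`, `feature`).
#' @return a [peak_matrix()].
#' @export
match_peaks <- function(spectra, max_shift_ppm = 8, mz_window = c(600, 1000),
                        sample_ids = NULL, keep_members = FALSE) {
  if (length(spectra) < 1L) stop("need at least one spectrum", call. = FALSE)
  if (!is_number(max_shift_ppm) || max_shift_ppm <= 0) {
    stop("max_shift_ppm must be > 0", call. = FALSE)
  }
  for (i in seq_along(spectra)) check_spectrum(spectra[[i]], sprintf("spectrum %d", i))

  mz <- unlist(lapply(spectra, `[[`, "mz"), use.names = FALSE)
  intensity <- unlist(lapply(spectra, `[[`, "intensity"), use.names = FALSE)
  sid <- rep(seq_along(spectra), vapply(spectra, function(s) length(s$mz), integer(1)))
  if (!is.null(mz_window)) {
    keep <- mz >= mz_window[1] & mz <= mz_window[2]
    mz <- mz[keep]; intensity <- intensity[keep]; sid <- sid[keep]
  }
  n_samp <- length(spectra)
  ids <- sample_ids %||% sprintf("S%03d", seq_len(n_samp))
  if (length(mz) == 0L) {
    return(peak_matrix(matrix(0, n_samp, 0), numeric(0), ids))
  }

  o <- order(mz, intensity)
  mz <- mz[o]; intensity <- intensity[o]; sid <- sid[o]

  cl <- sweep_cluster(mz, intensity, max_shift_ppm)
  # enforce per-spectrum uniqueness: nearest-ppm wins, loser re-clustered
  res_mz <- numeric(0); res_int <- numeric(0); res_sid <- integer(0)
  res_consensus <- numeric(0); res_cl <- integer(0)
  next_cl <- 0L
  pend_mz <- mz; pend_int <- intensity; pend_sid <- sid; pend_cl <- cl
  guard <- 0L
  while (length(pend_mz) > 0L) {
    guard <- guard + 1L
    if (guard > 100L) stop("peak matching failed to converge", call. = FALSE)
    lose <- logical(length(pend_mz))
    cons <- numeric(length(pend_mz))
    for (g in split(seq_along(pend_mz), pend_cl)) {
      cstar <- consensus_of(pend_mz[g], pend_int[g])
      cons[g] <- cstar
      # enforce the member window: chained outliers beyond max_shift_ppm of
      # the consensus are split off and re-clustered
      out <- g[abs(pend_mz[g] - cstar) / cstar * 1e6 > max_shift_ppm]
      if (length(out) < length(g)) lose[out] <- TRUE
      dup <- split(setdiff(g, out), pend_sid[setdiff(g, out)])
      for (d in dup) {
        if (length(d) > 1L) {
          ppm <- abs(pend_mz[d] - cstar) / cstar * 1e6
          best <- d[order(ppm, -pend_int[d], pend_mz[d])][1]
          lose[setdiff(d, best)] <- TRUE
        }
      }
    }
    keep <- !lose
    shift <- max(c(0L, res_cl))
    res_mz <- c(res_mz, pend_mz[keep])
    res_int <- c(res_int, pend_int[keep])
    res_sid <- c(res_sid, pend_sid[keep])
    res_cl <- c(res_cl, pend_cl[keep] + shift - min(pend_cl) + 1L)
    if (!any(lose)) break
    pend_mz <- pend_mz[lose]; pend_int <- pend_int[lose]
    pend_sid <- pend_sid[lose]
    pend_cl <- sweep_cluster(pend_mz, pend_int, max_shift_ppm)
  }

  cons_mz <- vapply(split(seq_along(res_mz), res_cl),
                    function(g) consensus_of(res_mz[g], res_int[g]), numeric(1))
  ord <- order(cons_mz)
  rank_of <- integer(length(cons_mz)); rank_of[ord] <- seq_along(ord)
  feat_idx <- rank_of[match(res_cl, as.integer(names(cons_mz)))]
  cons_mz <- cons_mz[ord]

  m <- matrix(0, n_samp, length(cons_mz))
  m[cbind(res_sid, feat_idx)] <- res_int
  pm <- peak_matrix(m, cons_mz, ids)
  if (keep_members) {
    pm$members <- data.frame(spectrum = res_sid, mz = res_mz,
                             intensity = res_int, feature = feat_idx)
  }
  pm
}

#' Average spectra over a region of interest
#'
#' Pools the peak lists of all pixels carrying `label`, matches them into
#' consensus features (no m/z window restriction at this stage), and returns
#' the mean spectrum: each feature's intensity is the sum over contributing
#' pixels divided by the number of labelled pixels (absent peaks count as 0).
#'
#' @param img an [msi_image()].
#' @param mask an [roi_mask()] aligned to the image.
#' @param label tissue class to average (`"benign_tissue"` or
#'   `"cancer_tissue"`).
#' @param max_shift_ppm ppm window used to pool pixel peaks.
#' @return `list(mz =, intensity =)`, the averaged spectrum.
#' @export
average_roi <- function(img, mask, label, max_shift_ppm = 8) {
  validate_mask(img, mask)
  sel <- mask[mask$label == label, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop(sprintf("patient '%s': no pixel labelled '%s'", img$patient_id, label),
         call. = FALSE)
  }
  key_img <- paste(img$coords$x, img$coords$y)
  idx <- match(paste(sel$x, sel$y), key_img)
  spectra <- img$spectra[idx]
  pm <- match_peaks(spectra, max_shift_ppm = max_shift_ppm, mz_window = NULL)
  list(mz = pm$mz,
       intensity = unname(colSums(pm$intensities)) / length(spectra))
}

#' Probabilistic quotient normalization
#'
#' Scales each sample of a raw peak matrix by a robust summary of its
#' intensity quotients against the element-wise mean reference spectrum:
#' quotients are computed over features with a positive reference, the
#' per-sample factor is their median (or mean, for the mean-quotient
#' variant), and the sample is divided by its factor. Multiplicative
#' per-sample intensity differences are removed; applying PQN twice is the
#' identity.
#'
#' @param matrix a raw [peak_matrix()].
#' @param quotient `"median"` (default, standard PQN) or `"mean"`.
#' @return a normalized `peak_matrix` with `pqn_factors` recorded.
#' @export
pqn_normalize <- function(matrix, quotient = c("median", "mean")) {
  stopifnot(inherits(matrix, "peak_matrix"))
  quotient <- match.arg(quotient)
  X <- matrix$intensities
  all_zero <- rowSums(X) == 0
  if (any(all_zero)) {
    stop(sprintf("sample '%s' has no positive feature", matrix$sample_ids[which(all_zero)[1]]),
         call. = FALSE)
  }
  ref <- colMeans(X)
  pos <- ref > 0
  if (!any(pos)) stop("reference spectrum is all zero", call. = FALSE)
  stat <- if (quotient == "median") stats::median else mean
  factors <- apply(X[, pos, drop = FALSE], 1, function(x) stat(x / ref[pos]))
  bad <- !is.finite(factors) | factors <= 0
  if (any(bad)) {
    stop(sprintf("sample '%s': non-positive quotient summary", matrix$sample_ids[which(bad)[1]]),
         call. = FALSE)
  }
  peak_matrix(X / factors, matrix$mz, matrix$sample_ids,
              normalization = "pqn", pqn_factors = factors)
}

#' Build the per-patient profile matrix from a cohort
#'
#' Convenience wrapper over [average_roi()], [match_peaks()] and
#' [pqn_normalize()]: averages each patient's tissue pixels (label taken
#' from the diagnosis), matches the averaged spectra across patients within
#' the analysis window, and PQN-normalizes the result. The unit of analysis
#' is one averaged spectrum per patient per tissue class.
#'
#' @param images list of [msi_image()].
#' @param masks list of [roi_mask()] parallel to `images`.
#' @param meta patient metadata data.frame (`patient_id`, `diagnosis`).
#' @param mz_window analysis window in Da.
#' @param max_shift_ppm peak matching window in ppm.
#' @param quotient PQN quotient variant, `"median"` or `"mean"`.
#' @param normalize set `FALSE` to return the raw matched matrix.
#' @return a [peak_matrix()] with one row per patient.
#' @export
patient_profiles <- function(images, masks, meta, mz_window = c(600, 1000),
                             max_shift_ppm = 8, quotient = "median",
                             normalize = TRUE) {
  ids <- vapply(images, `[[`, character(1), "patient_id")
  stopifnot(length(images) == length(masks), all(ids %in% meta$patient_id))
  labels <- ifelse(meta$diagnosis[match(ids, meta$patient_id)] == "cancer",
                   "cancer_tissue", "benign_tissue")
  avg <- vector("list", length(images))
  for (i in seq_along(images)) {
    avg[[i]] <- average_roi(images[[i]], masks[[i]], labels[i], max_shift_ppm)
  }
  pm <- match_peaks(avg, max_shift_ppm = max_shift_ppm, mz_window = mz_window,
                    sample_ids = ids)
  if (normalize) pqn_normalize(pm, quotient) else pm
}
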
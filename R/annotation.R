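# Lipid annotation against an accurate-mass reference table, with
# deprotonated [M-H]- adducts and carbon-13 isotopologue handling.

# Mass difference between 13C and 12C, in Da.
C13_DELTA <- 1.0033548

#' Relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`; reported to 4 decimals in
#' output tables.
#'
#' @param observed_mz,theoretical_mz m/z values in Da (vectorized).
#' @return ppm error (signed).
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical_mz must be > 0", call. = FALSE)
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' m/z of a carbon-13 isotopologue
#'
#' Shifts a monoisotopic m/z by `k` times the 13C-12C mass difference
#' (1.0033548 Da).
#'
#' @param mono_mz monoisotopic m/z in Da.
#' @param k number of 13C substitutions (integer >= 0).
#' @return the isotopologue m/z.
#' @export
isotope_mz <- function(mono_mz, k) {
  if (any(k < 0) || any(k != round(k))) stop("k must be an integer >= 0", call. = FALSE)
  mono_mz + k * C13_DELTA
}

#' Bundled lipid reference table
#'
#' The package's built-in reference of deprotonated glycerophospholipid ions
#' (PE, PA, PS, PI and ether-linked PE classes) with monoisotopic
#' theoretical [M-H]- masses and opaque MS/MS annotation strings. User
#' tables in the same TSV format can be loaded with [read_lipid_table()].
#'
#' @return data.frame with columns `name`, `lipid_class`, `adduct`,
#'   `theoretical_mz`, `msms_note`.
#' @export
lipid_reference <- function() {
  read_lipid_table(system.file("extdata", "lipid_reference.tsv",
                               package = "desimsi", mustWork = TRUE))
}

#' Read a lipid reference table
#'
#' @param path TSV with columns `name`, `lipid_class`, `adduct`,
#'   `theoretical_mz`, `msms_note`; `(name, adduct)` pairs must be unique
#'   and theoretical masses positive.
#' @return the validated data.frame.
#' @export
read_lipid_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "lipid_class", "adduct", "theoretical_mz")
  if (!all(need %in% names(tab))) {
    stop(sprintf("lipid table needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"msms_note" %in% names(tab)) tab$msms_note <- ""
  if (any(tab$theoretical_mz <= 0)) stop("theoretical_mz must be > 0", call. = FALSE)
  if (anyDuplicated(tab[c("name", "adduct")])) {
    stop("(name, adduct) pairs must be unique", call. = FALSE)
  }
  tab
}

#' Annotate one observed m/z
#'
#' Tests every reference record at isotopologue offsets `0..max_isotope`
#' and keeps the combinations whose matched theoretical m/z lies within
#' `tol_ppm` of the observation, ranked by absolute ppm error (ties broken
#' by lower isotope offset, then name).
#'
#' @param observed_mz observed m/z in Da.
#' @param table lipid reference data.frame (default the bundled table).
#' @param tol_ppm match tolerance in ppm (default 10).
#' @param max_isotope largest 13C offset considered (default 1).
#' @return data.frame of hits: `observed_mz`, `name`, `lipid_class`,
#'   `adduct`, `isotope_offset`, `matched_theoretical_mz`, `ppm_error`,
#'   `msms_note`, `rank`. Empty (zero rows) when nothing matches.
#' @export
annotate_feature <- function(observed_mz, table = lipid_reference(),
                             tol_ppm = 10, max_isotope = 1) {
  if (nrow(table) == 0) stop("reference table is empty", call. = FALSE)
  if (!is_number(tol_ppm) || tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  combos <- expand.grid(record = seq_len(nrow(table)),
                        isotope_offset = 0:max_isotope)
  matched <- isotope_mz(table$theoretical_mz[combos$record], combos$isotope_offset)
  err <- ppm_error(observed_mz, matched)
  keep <- abs(err) <= tol_ppm
  hits <- data.frame(
    observed_mz = rep(observed_mz, sum(keep)),
    name = table$name[combos$record[keep]],
    lipid_class = table$lipid_class[combos$record[keep]],
    adduct = table$adduct[combos$record[keep]],
    isotope_offset = combos$isotope_offset[keep],
    matched_theoretical_mz = matched[keep],
    ppm_error = round(err[keep], 4),
    msms_note = table$msms_note[combos$record[keep]],
    stringsAsFactors = FALSE
  )
  hits <- hits[order(abs(hits$ppm_error), hits$isotope_offset, hits$name), , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Annotate every feature of a peak matrix
#'
#' Applies [annotate_feature()] to each consensus m/z and reports the top
#' hit per feature (one row per feature, unmatched features included with
#' `NA` annotation), optionally joined with univariate feature statistics.
#'
#' @param matrix a [peak_matrix()].
#' @param table lipid reference data.frame.
#' @param tol_ppm,max_isotope passed to [annotate_feature()].
#' @param stats optional [feature_stats()] result aligned to the matrix
#'   features; its `p_value`, `q_value` and `fold_change` columns are joined.
#' @return data.frame with one row per feature.
#' @export
annotate_matrix <- function(matrix, table = lipid_reference(), tol_ppm = 10,
                            max_isotope = 1, stats = NULL) {
  stopifnot(inherits(matrix, "peak_matrix"))
  if (length(matrix$mz) == 0) {
    return(data.frame(observed_mz = numeric(0), name = character(0),
                      lipid_class = character(0), adduct = character(0),
                      isotope_offset = integer(0),
                      matched_theoretical_mz = numeric(0),
                      ppm_error = numeric(0), msms_note = character(0),
                      n_hits = integer(0)))
  }
  rows <- lapply(matrix$mz, function(m) {
    hits <- annotate_feature(m, table, tol_ppm, max_isotope)
    if (nrow(hits) == 0) {
      data.frame(observed_mz = m, name = NA_character_,
                 lipid_class = NA_character_, adduct = NA_character_,
                 isotope_offset = NA_integer_,
                 matched_theoretical_mz = NA_real_, ppm_error = NA_real_,
                 msms_note = NA_character_, n_hits = 0L,
                 stringsAsFactors = FALSE)
    } else {
      cbind(hits[1, setdiff(names(hits), "rank"), drop = FALSE],
            n_hits = nrow(hits))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(stats)) {
    stopifnot(nrow(stats) == nrow(out))
    out <- cbind(out, stats[, intersect(c("p_value", "q_value", "fold_change",
                                          "direction"), names(stats)),
                            drop = FALSE])
  }
  out
}
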
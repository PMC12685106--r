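# Joint lipid-protein correlation: modality-specific normalization, pairwise
# cosine distances across all species, and hierarchical clustering.

#' Modality-specific normalization for integration
#'
#' Lipids are normalized by each patient's total lipid intensity (row sums);
#' proteins by each antibody's maximum across patients (column maxima, so
#' every antibody lands on `[0, 1]` for positive data).
#'
#' @param lipid_matrix patients x lipids numeric matrix.
#' @param protein_matrix patients x proteins numeric matrix with the same
#'   patient ordering.
#' @return `list(lipids =, proteins =)` of normalized matrices.
#' @export
normalize_modalities <- function(lipid_matrix, protein_matrix) {
  lipid_matrix <- as.matrix(lipid_matrix)
  protein_matrix <- as.matrix(protein_matrix)
  if (nrow(lipid_matrix) != nrow(protein_matrix)) {
    stop("matrices must share the patient ordering", call. = FALSE)
  }
  totals <- rowSums(lipid_matrix)
  if (any(totals <= 0)) {
    bad <- rownames(lipid_matrix)[which(totals <= 0)[1]] %||% which(totals <= 0)[1]
    stop(sprintf("patient '%s' has non-positive total lipid intensity", bad),
         call. = FALSE)
  }
  maxima <- apply(protein_matrix, 2, max)
  if (any(maxima <= 0)) {
    bad <- colnames(protein_matrix)[which(maxima <= 0)[1]] %||% which(maxima <= 0)[1]
    stop(sprintf("protein '%s' has non-positive maximum", bad), call. = FALSE)
  }
  list(lipids = lipid_matrix / totals,
       proteins = sweep(protein_matrix, 2, maxima, `/`))
}

#' Pairwise cosine distances across lipid and protein species
#'
#' Treats each species (lipid feature or protein) as a vector across the
#' shared patients and computes `1 - cos` for every pair over the combined
#' species set, covering the lipid-lipid, protein-protein and lipid-protein
#' blocks of the joint heatmap.
#'
#' @param normalized `list(lipids =, proteins =)` from
#'   [normalize_modalities()].
#' @param lipids,proteins optional character (or index) subsets of species.
#' @return object of class `cross_corr`: `species_names`, `modality`
#'   (per-species `"lipid"`/`"protein"` tag), `similarity_matrix` and
#'   `distance_matrix` (symmetric, zero diagonal, distances in `[0, 2]`).
#' @export
cosine_distance_matrix <- function(normalized, lipids = NULL, proteins = NULL) {
  L <- normalized$lipids
  P <- normalized$proteins
  if (!is.null(lipids)) L <- L[, lipids, drop = FALSE]
  if (!is.null(proteins)) P <- P[, proteins, drop = FALSE]
  V <- cbind(L, P)
  modality <- rep(c("lipid", "protein"), c(ncol(L), ncol(P)))
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) {
    bad <- colnames(V)[which(nrm == 0)[1]] %||% which(nrm == 0)[1]
    stop(sprintf("species '%s' has zero norm across patients", bad), call. = FALSE)
  }
  U <- sweep(V, 2, nrm, `/`)
  sim <- crossprod(U)
  sim <- (sim + t(sim)) / 2
  sim[sim > 1] <- 1; sim[sim < -1] <- -1
  diag(sim) <- 1
  dist_m <- 1 - sim
  structure(
    list(species_names = colnames(V), modality = modality,
         similarity_matrix = sim, distance_matrix = dist_m),
    class = "cross_corr"
  )
}

#' @export
print.cross_corr <- function(x, ...) {
  cat(sprintf("Cosine cross-correlation: %d lipids + %d proteins\n",
              sum(x$modality == "lipid"), sum(x$modality == "protein")))
  invisible(x)
}

#' Hierarchical clustering of a species distance matrix
#'
#' Agglomerative clustering (average linkage by default; complete and
#' centroid offered) of a symmetric distance matrix, returning the merge
#' tree, a deterministic leaf order, and a Newick export helper.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal (or a
#'   `cross_corr` object, whose distance matrix is used).
#' @param linkage `"average"`, `"complete"` or `"centroid"`.
#' @return list with `hclust` (the [stats::hclust()] tree), `leaf_order`
#'   (species names in dendrogram order), `heights` and `linkage`.
#' @export
hierarchical_cluster <- function(distance_matrix,
                                 linkage = c("average", "complete", "centroid")) {
  linkage <- match.arg(linkage)
  if (inherits(distance_matrix, "cross_corr")) {
    distance_matrix <- distance_matrix$distance_matrix
  }
  distance_matrix <- as.matrix(distance_matrix)
  if (nrow(distance_matrix) != ncol(distance_matrix) ||
      any(abs(distance_matrix - t(distance_matrix)) > 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(distance_matrix)) > 1e-8)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(distance_matrix))) {
    rownames(distance_matrix) <- colnames(distance_matrix) <-
      sprintf("species_%02d", seq_len(nrow(distance_matrix)))
  }
  # sort labels so the agglomeration (and its tie-breaks) never depends on
  # input column order
  ord <- order(rownames(distance_matrix))
  dm <- distance_matrix[ord, ord, drop = FALSE]
  if (nrow(dm) == 1) {
    return(list(hclust = NULL, leaf_order = rownames(dm),
                heights = numeric(0), linkage = linkage))
  }
  hc <- stats::hclust(stats::as.dist(dm),
                      method = if (linkage == "centroid") "centroid" else linkage)
  list(hclust = hc, leaf_order = hc$labels[hc$order], heights = hc$height,
       linkage = linkage)
}

#' Export a clustering as a Newick tree
#'
#' @param clustering result of [hierarchical_cluster()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(clustering, path) {
  if (is.null(clustering$hclust)) {
    writeLines(sprintf("(%s);", clustering$leaf_order), path)
  } else {
    ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  }
  invisible(path)
}
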
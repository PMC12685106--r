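test_that("modality normalization scales lipids by totals and proteins by maxima", {
  lip <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), c("l1", "l2")))
  pro <- matrix(c(2, 10, 4, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), c("a", "b")))
  nm <- normalize_modalities(lip, pro)
  expect_equal(nm$lipids, lip) # rows already sum to 1
  expect_equal(unname(apply(nm$proteins, 2, max)), c(1, 1))
  # scale invariance: doubling a patient's raw lipid row changes nothing
  lip2 <- lip; lip2["P1", ] <- 2 * lip2["P1", ]
  expect_equal(normalize_modalities(lip2, pro)$lipids, nm$lipids)
})

test_that("zero totals and maxima produce targeted errors", {
  lip <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), NULL))
  pro <- matrix(1, 2, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  expect_error(normalize_modalities(lip, pro), "P2")
  pro0 <- pro; pro0[, 2] <- 0
  lip1 <- matrix(1, 2, 2, dimnames = list(c("P1", "P2"), NULL))
  expect_error(normalize_modalities(lip1, pro0), "b")
})

test_that("cosine distances satisfy their metric identities", {
  set.seed(1)
  u <- runif(10, 0, 5)
  lip <- cbind(l1 = u, l2 = 3 * u, l3 = runif(10))
  pro <- cbind(p1 = c(1, rep(0, 9)), p2 = c(0, 1, rep(0, 8)))
  rownames(lip) <- rownames(pro) <- sprintf("P%02d", 1:10)
  cc <- cosine_distance_matrix(list(lipids = lip, proteins = pro))
  d <- cc$distance_matrix
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 2))
  expect_true(all(cc$similarity_matrix >= -1 & cc$similarity_matrix <= 1))
  expect_equal(d["l1", "l2"], 0)            # scale invariance of cosine
  expect_equal(d["p1", "p2"], 1)            # orthogonal indicators
  expect_equal(cc$modality, c(rep("lipid", 3), rep("protein", 2)))
  # invariant under patient reordering
  perm <- sample(10)
  cc2 <- cosine_distance_matrix(list(lipids = lip[perm, ], proteins = pro[perm, ]))
  expect_equal(cc2$distance_matrix, d)
  pro_bad <- cbind(p1 = rep(0, 10))
  rownames(pro_bad) <- rownames(pro)
  expect_error(cosine_distance_matrix(list(lipids = lip, proteins = pro_bad)),
               "p1")
})

test_that("a generated protein-lipid pair with correlation 0.9 is the most similar cross pair", {
  cfg <- msi_sim_config(n_cancer = 40L, n_benign = 24L, image_shape = c(6L, 6L),
                        n_background_peaks = 10L, n_proteins = 20L,
                        n_differential_proteins = 4L, n_correlated_proteins = 1L,
                        protein_lipid_cor = 0.9, seed = 41)
  co <- generate_cohort(cfg)
  pm <- patient_profiles(co$images, co$masks, co$meta)
  pt <- generate_protein_table(cfg, co)
  link <- attr(pt, "correlated_with")
  lip_cols <- vapply(default_planted_features()$mz,
                     function(m) which.min(abs(pm$mz - m)), integer(1))
  lipm <- pm$intensities[, lip_cols]
  colnames(lipm) <- sprintf("mz_%.4f", pm$mz[lip_cols])
  nm <- normalize_modalities(lipm, unclass(pt))
  cc <- cosine_distance_matrix(nm)
  cross <- cc$similarity_matrix[grep("^mz_", cc$species_names),
                                grep("^protein", cc$species_names)]
  linked_lip <- sprintf("mz_%.4f", pm$mz[which.min(abs(pm$mz - link$lipid_mz))])
  expect_equal(unname(which.max(cross[linked_lip, ])),
               match(link$protein, colnames(cross)))
})

test_that("clustering merges identical species first and keeps heights monotone", {
  d <- matrix(c(0, 0, 0.9, 0, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- hierarchical_cluster(d)
  expect_equal(cl$heights[1], 0)
  first_merge <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first_merge, c("a", "b"))
  for (linkage in c("average", "complete")) {
    set.seed(5)
    x <- matrix(runif(60), 10, 6)
    dm <- as.matrix(dist(t(x)))
    cl2 <- hierarchical_cluster(dm, linkage)
    expect_true(all(diff(cl2$heights) >= -1e-12))
  }
})

test_that("two tight pairs form the first two merges", {
  # 4 points: {a,b} at distance 0.1, {c,d} at 0.2, cross distances ~1
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.2
  cl <- hierarchical_cluster(d)
  merges <- cl$hclust$merge
  expect_true(all(merges[1, ] < 0) && all(merges[2, ] < 0))
  first_two <- lapply(1:2, function(i) sort(cl$hclust$labels[-merges[i, ]]))
  expect_equal(first_two, list(c("a", "b"), c("c", "d")))
})

test_that("degenerate clustering inputs are handled", {
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  bad_diag <- matrix(c(0.5, 1, 1, 0.5), 2, 2)
  expect_error(hierarchical_cluster(bad_diag), "diagonal")
  single <- matrix(0, 1, 1, dimnames = list("only", "only"))
  cl <- hierarchical_cluster(single)
  expect_equal(cl$leaf_order, "only")
  p <- file.path(tempdir(), "single.nwk")
  write_newick(cl, p)
  expect_match(readLines(p), "only")
})

test_that("dendrograms export as valid Newick", {
  set.seed(6)
  x <- matrix(runif(50), 10, 5,
              dimnames = list(NULL, c("s1", "s2", "s3", "s4", "s5")))
  dm <- as.matrix(dist(t(x)))
  cl <- hierarchical_cluster(dm)
  p <- file.path(tempdir(), "tree.nwk")
  write_newick(cl, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, colnames(dm))
})
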
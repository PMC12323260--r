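test_that("featurization flattens the upper-triangle distances", {
  tri <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  f <- featurize_distances(list(tri))
  expect_equal(drop(f$vectors), c(1, 1, sqrt(2)))
  expect_equal(f$pair_index, data.frame(i = c(1L, 1L, 2L),
                                        j = c(2L, 3L, 3L)))
  # n = 2 -> m = 1
  duo <- conformation(rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(ncol(featurize_distances(list(duo))$vectors), 1L)
  # permuting the ensemble permutes rows only
  quad <- conformation(rbind(c(0, 0, 0), c(1.4, 0, 0), c(1.4, 1.4, 0)))
  f2 <- featurize_distances(list(tri, quad))
  f2r <- featurize_distances(list(quad, tri))
  expect_equal(f2$vectors[1, ], f2r$vectors[2, ])
  expect_equal(f2$vectors[2, ], f2r$vectors[1, ])
  expect_error(featurize_distances(list(tri, duo)), "same atom count")
})

test_that("k-means separates well-separated geometric modes", {
  ens <- make_two_mode_ensemble(two_mode_specs(), M = 80, torsion_sd = 3,
                                seed = 11)
  truth <- attr(ens, "mode")
  f <- featurize_distances(ens)
  labels <- cluster_conformers(f, 2, seed = 11)
  agree <- max(mean((labels == 1) == (truth == 1)),
               mean((labels == 2) == (truth == 1)))
  expect_equal(agree, 1)
  # single cluster collapses all labels
  expect_equal(cluster_conformers(f, 1), rep(1L, 80))
  # deterministic given the seed
  expect_identical(labels, cluster_conformers(f, 2, seed = 11))
  expect_error(cluster_conformers(f, 0), "at least 1")
  expect_error(cluster_conformers(f, 81), "more clusters")
})

test_that("significance equals |cluster mean - global mean|", {
  # two equal-size synthetic clusters differing only in pair (1, 5)
  base <- build_chain(rep(1.5, 4), rep(112, 3), c(180, 180))
  short <- shake_project(base,
                         constraint_set(distance_constraint(1, 5, 3.0)),
                         tol = 1e-9)$conformation
  long <- shake_project(base,
                        constraint_set(distance_constraint(1, 5, 4.0)),
                        tol = 1e-9)$conformation
  ens <- c(replicate(10, short, simplify = FALSE),
           replicate(10, long, simplify = FALSE))
  f <- featurize_distances(ens)
  labels <- rep(c(1L, 2L), each = 10)
  rep_ <- constraint_significance(f, labels)
  col15 <- which(f$pair_index$i == 1 & f$pair_index$j == 5)
  expect_equal(rep_$global_mean[col15], 3.5, tolerance = 1e-6)
  expect_equal(rep_$significance[1, col15], 0.5, tolerance = 1e-6)
  expect_equal(rep_$significance[2, col15], 0.5, tolerance = 1e-6)
  # identical conformers: all significances vanish
  same <- constraint_significance(featurize_distances(
    replicate(6, base, simplify = FALSE)), rep(1:2, 3))
  expect_true(all(same$significance < 1e-12))
  # scaling coordinates scales significance linearly
  ens2 <- lapply(ens, function(cf) conformation(cf$coordinates * 2))
  rep2 <- constraint_significance(featurize_distances(ens2), labels)
  expect_equal(rep2$significance, rep_$significance * 2,
               tolerance = 1e-9)
  expect_error(constraint_significance(f, rep(c(1L, 3L), each = 10)),
               "empty cluster")
})

test_that("top constraints rank by significance with lexicographic ties", {
  base <- build_chain(rep(1.5, 4), rep(112, 3), c(180, 180))
  short <- shake_project(base,
                         constraint_set(distance_constraint(1, 5, 3.0)),
                         tol = 1e-9)$conformation
  long <- shake_project(base,
                        constraint_set(distance_constraint(1, 5, 4.0)),
                        tol = 1e-9)$conformation
  ens <- c(replicate(10, short, simplify = FALSE),
           replicate(10, long, simplify = FALSE))
  f <- featurize_distances(ens)
  rep_ <- constraint_significance(f, rep(c(1L, 2L), each = 10))
  top <- top_constraints(rep_, 1, 2)
  expect_equal(top[[1]]$atoms, c(1L, 5L))
  expect_equal(top[[1]]$target, 4.0, tolerance = 1e-6)
  # T = m returns all pairs ordered by significance
  all_ <- top_constraints(rep_, ncol(f$vectors), 1)
  expect_length(all_, ncol(f$vectors))
  sig <- rep_$significance[1, ]
  ord_sig <- vapply(unclass(all_), function(cst) {
    sig[which(f$pair_index$i == cst$atoms[1] &
                f$pair_index$j == cst$atoms[2])]
  }, numeric(1))
  expect_true(all(diff(ord_sig) <= 1e-12))
  # all-equal significance: lexicographic pair order
  flat <- constraint_significance(featurize_distances(
    replicate(6, base, simplify = FALSE)), rep(1:2, 3))
  lex <- top_constraints(flat, 3, 1)
  expect_equal(lapply(unclass(lex), `[[`, "atoms"),
               list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  expect_error(top_constraints(rep_, 1, 5), "invalid cluster")
  # bounded mode carries the within-cluster spread
  bnd <- top_constraints(rep_, 1, 2, bounded = TRUE)
  expect_equal(bnd[[1]]$lower_final,
               bnd[[1]]$target - rep_$cluster_sd[2, which(
                 f$pair_index$i == 1 & f$pair_index$j == 5)])
})

test_that("PCA loadings identify the varying pair and reconstruct exactly", {
  # variance in a single pair column: that pair dominates PC1
  base <- build_chain(rep(1.5, 3), rep(112, 2), 180)
  ens <- lapply(seq(-0.3, 0.3, length.out = 12), function(d) {
    shake_project(base,
                  constraint_set(distance_constraint(1, 4, 3.8 + d)),
                  tol = 1e-10)$conformation
  })
  f <- featurize_distances(ens)
  pl <- pca_constraint_loadings(f, n_components = 2, top_t = 3)
  expect_equal(unlist(pl$components[[1]]$pairs[1, c("i", "j")],
                      use.names = FALSE), c(1L, 4L))
  # centered features reconstruct from the full component basis
  pc <- stats::prcomp(f$vectors, center = TRUE)
  recon <- pc$x %*% t(pc$rotation)
  centered <- sweep(f$vectors, 2, colMeans(f$vectors))
  expect_lt(max(abs(recon - centered)), 1e-8)
  # ranking is invariant to component sign flips
  flipped <- -pl$loadings[, 1]
  expect_equal(order(-abs(flipped)), order(-abs(pl$loadings[, 1])))
})

test_that("mining recovers planted pairs and feeds feasible constraints", {
  specs <- two_mode_specs()
  # the two modes differ in the torsion-dependent long-range pairs;
  # identify the truly differing pairs from the noiseless templates
  t_a <- build_chain(specs[[1]]$bond_lengths, specs[[1]]$bond_angles,
                     specs[[1]]$torsions)
  t_b <- build_chain(specs[[2]]$bond_lengths, specs[[2]]$bond_angles,
                     specs[[2]]$torsions)
  ft <- featurize_distances(list(t_a, t_b))
  diff_cols <- which(abs(ft$vectors[1, ] - ft$vectors[2, ]) > 0.3)
  ens <- make_two_mode_ensemble(specs, M = 60, torsion_sd = 3, seed = 5)
  f <- featurize_distances(ens)
  labels <- cluster_conformers(f, 2, seed = 5)
  rep_ <- constraint_significance(f, labels)
  top <- top_constraints(rep_, length(diff_cols), 1)
  mined_cols <- vapply(unclass(top), function(cst) {
    which(f$pair_index$i == cst$atoms[1] & f$pair_index$j == cst$atoms[2])
  }, integer(1))
  expect_setequal(mined_cols, diff_cols)
  # consistency: a cluster conformer projects onto its mined constraints
  member <- ens[[which(labels == 1)[1]]]
  pr <- shake_project(member, top, tol = 0.003, max_iter = 10)
  expect_true(pr$converged)
  expect_lte(pr$iterations_used, 10)
})

test_that("silhouette helper prefers the true number of modes", {
  ens <- make_two_mode_ensemble(two_mode_specs(), M = 40, torsion_sd = 3,
                                seed = 3)
  sil <- suggest_n_clusters(featurize_distances(ens), k_range = 2:4,
                            seed = 3)
  expect_equal(sil$k[which.max(sil$mean_silhouette)], 2)
})
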
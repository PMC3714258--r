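test_that("venn regions partition the union", {
  counts <- venn_regions(list(A = c("a", "b", "c"), B = c("b", "c"), C = "c"))
  expect_equal(unname(counts[c("A", "A&B", "A&B&C")]), c(1, 1, 1))
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts["B"]), 0)

  empty <- venn_regions(list(A = character(), B = character()))
  expect_true(all(empty == 0))

  same <- venn_regions(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  expect_equal(unname(same["A&B&C"]), 2)
  expect_equal(sum(same), 2)

  set.seed(12)
  for (i in 1:10) {
    pool <- paste0("g", 1:30)
    sets <- list(A = sample(pool, 12), B = sample(pool, 8), C = sample(pool, 20))
    counts <- venn_regions(sets)
    expect_equal(sum(counts), length(unique(unlist(sets))))
  }
})

test_that("trajectory classes take the finest magnitude", {
  cls <- classify_trajectory(
    status = c("up", "down", "up", "steady", "untestable", "exclusive"),
    magnitude = c("x10", "x2", "x2", "none", NA, NA)
  )
  expect_equal(as.character(cls),
               c("up_x10", "down_x2", "up_x2", "steady", "steady", "steady"))
})

test_that("trajectory cross-tabs tally and roll up like printed tables", {
  # a planted induction row: 125 down-regulated genes whose formation-stage
  # partition is 25 down (1 drastic), 40 up (12 drastic), 60 steady
  induction <- rep("down_x2", 125)
  formation <- c(rep("down_x2", 24), "down_x10",
                 rep("up_x2", 28), rep("up_x10", 12), rep("steady", 60))
  roll <- crosstab_trajectories(induction, formation, rollup = TRUE)
  expect_equal(unname(roll["down_x2", c("down_x2", "up_x2", "steady")]),
               c(25, 40, 60))
  expect_equal(unname(roll["down_x2", "total"]), 125)

  # exclusive cells sum to the gene count; x10 rows never exceed x2 rows
  tab <- crosstab_trajectories(induction, formation)
  expect_equal(sum(tab), 125)
  expect_true(all(roll["up_x10", 1:5] <= roll["up_x2", 1:5]))
  expect_true(all(roll["down_x10", 1:5] <= roll["down_x2", 1:5]))

  empty <- crosstab_trajectories(character(), character())
  expect_true(all(empty == 0))

  set.seed(3)
  ind <- sample(c("up_x2", "up_x10", "down_x2", "down_x10", "steady"), 50,
                replace = TRUE)
  form <- sample(c("up_x2", "up_x10", "down_x2", "down_x10", "steady"), 50,
                 replace = TRUE)
  tab <- crosstab_trajectories(ind, form)
  for (r in rownames(tab)) {
    for (cc in colnames(tab)) {
      expect_equal(tab[r, cc], sum(ind == r & form == cc))
    }
  }
})

test_that("the SE-specific classifier reproduces worked patterns and precedence", {
  # drastically up in the embryogenic culture, steady in the mutant -> ii
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, emb_5d0d = "up", emb_5d10d = "up",
    mut_5d0d = "steady", mut_5d10d = "steady")), "ii")

  # down in embryogenic, strongly up in the mutant -> iii_b
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, emb_5d0d = "down", emb_5d10d = "down",
    mut_5d0d = "up", mut_5d10d = "down")), "iii_b")

  # expressed only in the embryogenic culture -> i, beating everything else
  expect_equal(as.character(classify_se_specific(
    TRUE, FALSE, emb_5d0d = "up", emb_5d10d = "steady",
    mut_5d0d = "untestable", mut_5d10d = "untestable")), "i")

  # down in both cultures -> iv
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, emb_5d0d = "down", emb_5d10d = "steady",
    mut_5d0d = "down", mut_5d10d = "steady")), "iv")

  # opposite directions beat one-sided steadiness (iii over ii/iv)
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, emb_5d0d = "up", emb_5d10d = "steady",
    mut_5d0d = "down", mut_5d10d = "steady")), "iii_a")

  # up in both cultures is not SE-specific
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, emb_5d0d = "up", emb_5d10d = "steady",
    mut_5d0d = "up", mut_5d10d = "steady")), "none")

  # steady embryogenic culture with a steady mutant is nothing
  expect_equal(as.character(classify_se_specific(
    TRUE, TRUE, "steady", "steady", "steady", "steady")), "none")

  expect_true(is.na(classify_se_specific(
    NA, TRUE, "up", "steady", "steady", "steady")))
})

test_that("every gene receives exactly one SE group from the full pipeline", {
  cfg <- generator_config(n_genes = 150, seed = 21)
  d <- generate_dataset(cfg)
  calls <- run_comparison_modes(d$ct)
  se <- se_specific_classes(calls)
  expect_equal(nrow(se), 150)
  expect_false(any(is.na(se$se_group)))
  expect_setequal(se$gene_id, d$truth$gene_id)
})

test_that("k-means recovers fully separated archetypes deterministically", {
  set.seed(55)
  archetypes <- rbind(
    up_early = c(28, 36, 36),
    up_sustained = c(28, 32, 36),
    down = c(34, 28, 26),
    flat = c(31, 31, 31)
  )
  labels <- rep(rownames(archetypes), each = 40)
  profiles <- archetypes[labels, ] + matrix(rnorm(480, 0, 0.3), ncol = 3)
  rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))

  fit <- kmeans_patterns(profiles, k = 4, seed = 2)
  expect_equal(adjusted_rand_index(fit$cluster, labels), 1)

  # determinism: same seed, same assignment
  fit2 <- kmeans_patterns(profiles, k = 4, seed = 2)
  expect_identical(fit$cluster, fit2$cluster)

  # clusters are renumbered by descending centroid mean
  expect_true(all(diff(rowMeans(fit$centers)) <= 0))

  # every point sits with its nearest final centroid
  d2 <- as.matrix(dist(rbind(fit$centers, profiles)))[-(1:4), 1:4]
  expect_equal(unname(apply(d2, 1, which.min)), unname(fit$cluster))

  one <- kmeans_patterns(profiles, k = 1)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(profiles)))
  expect_true(all(one$cluster == 1))

  expect_error(kmeans_patterns(profiles[1:3, ], k = 4),
               class = "seqpcr_parameter_error")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("sample PCA conserves variance and reconstructs the data", {
  set.seed(14)
  # rank-1 structure: one direction carries all variance
  base <- matrix(rnorm(6), ncol = 6)
  mat1 <- matrix(seq(1, 2, length.out = 5), ncol = 1) %*% base
  res1 <- pca_samples(mat1)
  expect_equal(res1$variance_fractions[1], 1, tolerance = 1e-12)

  mat <- matrix(rnorm(8 * 20), nrow = 8)
  res <- pca_samples(mat)
  expect_equal(sum(res$variance_fractions), 1, tolerance = 1e-12)

  centred <- scale(mat, center = TRUE, scale = FALSE)
  recon <- res$scores %*% t(res$loadings)
  expect_equal(unname(recon), unname(centred[, , drop = TRUE]),
               tolerance = 1e-10, ignore_attr = TRUE)

  # sign convention: the largest loading of each component is positive
  for (j in seq_len(ncol(res$loadings))) {
    l <- res$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }

  withzero <- cbind(mat, 0)
  expect_message(res0 <- pca_samples(withzero), "zero-variance")
  expect_equal(length(res0$dropped), 1)

  expect_error(pca_samples(mat[1, , drop = FALSE]),
               class = "seqpcr_parameter_error")
})

test_that("biological groups separate and replicates co-locate in PC1-PC2", {
  # Planted effects are ~10x the replicate noise. Three sample groups carry
  # genuinely different expression profiles: fresh explants (both genotypes
  # share baselines at day 0), the embryogenic culture (5 d and 10 d), and
  # the non-embryogenic culture. Within a group, samples differ by replicate
  # noise only, so each sample's nearest neighbours must be its group mates.
  cfg <- generator_config(n_genes = 120, noise_sd = 0.25,
                          effect_sizes = c(x2 = 2.5, x10 = 4), seed = 33)
  d <- generate_dataset(cfg)
  norm <- compute_delta_ct(d$ct)
  wide <- norm |>
    dplyr::mutate(sample = paste(genotype, time_point, replicate, sep = "_"),
                  group = ifelse(time_point == 0, "explant",
                                 paste0(genotype, "_culture"))) |>
    dplyr::select(sample, group, gene_id, expression_index)
  group_of <- unique(wide[, c("sample", "group")])
  mat <- wide |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "gene_id",
                       values_from = "expression_index")
  m <- as.matrix(mat[, -1])
  rownames(m) <- mat$sample

  res <- pca_samples(m)
  xy <- res$scores[, 1:2]
  dd <- as.matrix(dist(xy))
  diag(dd) <- Inf
  for (s in rownames(m)) {
    nearest <- names(sort(dd[s, ]))[1:5]
    own <- group_of$group[group_of$sample == s]
    expect_equal(group_of$group[match(nearest, group_of$sample)],
                 rep(own, 5))
  }
})
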
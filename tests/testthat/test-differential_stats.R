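test_that("one-way ANOVA matches hand-worked and degenerate cases", {
  fit <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(fit$statistic, 1.5)          # SSB = 1.5, SSW = 4, df (1, 4)
  expect_equal(fit$df_between, 1)
  expect_equal(fit$df_within, 4)

  # identical means, nonzero variance -> F = 0, p = 1
  flat <- one_way_anova(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # zero within-group variance with unequal means
  sep <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(sep$p_value, 0)
  expect_equal(sep$degenerate, "zero_variance")

  # all values identical -> untestable
  const <- one_way_anova(list(c(2, 2), c(2, 2)))
  expect_true(is.na(const$statistic))
  expect_equal(const$degenerate, "constant")

  expect_error(one_way_anova(list(c(1, 2))), class = "seqpcr_parameter_error")
  expect_error(one_way_anova(list(1, c(1, 2))), class = "seqpcr_parameter_error")
})

test_that("ANOVA F equals the sums-of-squares oracle on random designs", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:5, 1), mean = j / 2))
    fit <- one_way_anova(groups)
    expect_equal(fit$statistic, anova_f_oracle(groups), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up oracle and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "seqpcr_value_error")

  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # order invariance: permuting the input permutes the output identically
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("the pairwise t-test matches closed forms and handles constants", {
  fit <- two_sample_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(fit$statistic, -1.224745, tolerance = 1e-6)  # pooled sd = 1
  expect_equal(fit$df, 4)
  expect_equal(fit$p_value, 0.2878641, tolerance = 1e-6)

  same <- two_sample_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- two_sample_t_test(c(1, 1), c(2, 2))
  expect_equal(sep$p_value, 0)
  expect_equal(sep$degenerate, "zero_variance")

  welch <- two_sample_t_test(c(1, 2, 3), c(2, 4, 9), variant = "welch")
  ref <- t.test(c(1, 2, 3), c(2, 4, 9))
  expect_equal(welch$p_value, ref$p.value)
})

test_that("t-test p-values track a full permutation enumeration", {
  set.seed(9)
  picks <- utils::combn(12, 6, simplify = FALSE)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(6, mean = 1)
    pooled <- c(a, b)
    t_obs <- abs(two_sample_t_test(a, b)$statistic)
    t_perm <- vapply(picks, function(idx) {
      abs(two_sample_t_test(pooled[idx], pooled[-idx])$statistic)
    }, numeric(1))
    p_perm <- mean(t_perm >= t_obs - 1e-12)
    p_student <- two_sample_t_test(a, b)$p_value
    expect_lt(abs(p_perm - p_student), 0.1)
  }
})

test_that("status calls respect all three gates and inclusive thresholds", {
  # a drastic up-regulation passing both gates
  call <- call_gene_status(30.06, anova_fdr = 0.001, t_p = 0.004)
  expect_equal(call$status, "up")
  expect_equal(call$magnitude, "x10")

  call2 <- call_gene_status(2.5, 0.01, 0.01)
  expect_equal(call2$status, "up")
  expect_equal(call2$magnitude, "x2")

  # fails the FDR gate despite an 8-fold change
  call3 <- call_gene_status(8, anova_fdr = 0.2, t_p = 0.01)
  expect_equal(call3$status, "steady")
  expect_equal(call3$magnitude, "none")

  # thresholds are inclusive; untestable ANOVA means steady
  expect_equal(call_gene_status(c(2, 10, -10), 0.01, 0.01)$magnitude,
               c("x2", "x10", "x10"))
  expect_equal(call_gene_status(4, NA, 0.01)$status, "steady")
  expect_equal(call_gene_status(-4, 0.01, 0.01)$status, "down")
})

test_that("planted modulation is recovered in both comparison modes", {
  # one gene 8-fold up at 5 d in Col-0 only, one steady gene
  profiles <- list(
    UP5 = function(g, t) if (g == "Col-0" && t >= 5) 5 else 8,
    FLAT = function(g, t) 6
  )
  ct <- plant_profiles(profiles)
  # jitter one replicate so within-group variance is nonzero
  ct$records$ct <- ct$records$ct + rep_len(c(-0.01, 0, 0.01), nrow(ct$records))
  calls <- run_comparison_modes(ct)

  ind <- calls[calls$mode == 1 & calls$genotype == "Col-0" &
                 calls$comparison == "5d-0d", ]
  expect_equal(ind$status[ind$gene_id == "UP5"], "up")
  expect_equal(ind$signed_fc[ind$gene_id == "UP5"], 8, tolerance = 0.05)
  expect_equal(ind$status[ind$gene_id == "FLAT"], "steady")

  m2 <- calls[calls$mode == 2 & calls$comparison == "5d", ]
  expect_equal(m2$status[m2$gene_id == "UP5"], "up")

  # the steady gene stays steady in every contrast of both modes
  expect_true(all(calls$status[calls$gene_id == "FLAT"] == "steady"))

  # mutant trajectory of UP5 is flat
  mut <- calls[calls$mode == 1 & calls$genotype == "tan1-2" &
                 calls$gene_id == "UP5", ]
  expect_true(all(mut$status == "steady"))
})

test_that("conditions with a single replicate mark contrasts untestable", {
  ct <- plant_profiles(list(G = function(g, t) 6))
  keep <- !(ct$records$genotype == "Col-0" & ct$records$time_point == 0 &
              ct$records$replicate > 1)
  ct$records <- ct$records[keep, ]
  calls <- run_comparison_modes(ct)
  aff <- calls[calls$mode == 1 & calls$genotype == "Col-0" &
                 calls$comparison %in% c("5d-0d", "10d-0d"), ]
  expect_true(all(aff$status == "untestable"))
  unaff <- calls[calls$mode == 1 & calls$genotype == "Col-0" &
                   calls$comparison == "10d-5d", ]
  expect_false(any(unaff$status == "untestable"))
})
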
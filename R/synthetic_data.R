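#' Configuration for the synthetic Ct-data generator
#'
#' Describes a two-genotype, three-time-point, three-replicate qRT-PCR
#' profiling experiment with planted expression classes. Defaults emulate the
#' reference design: Gaussian Ct noise of 0.25 cycles, baseline delta-Ct of
#' 8 +/- 2 cycles against a reference gene at Ct ~22, four reference wells
#' per run, a 40-cycle detection ceiling, and planted log2 effects of 1.5 for
#' moderate (2-to-10-fold) classes and 3.5 for drastic (at least 10-fold)
#' classes — both safely beyond their gating thresholds of 1 and
#' log2(10) ~ 3.32 so that threshold-edge behaviour is opt-in, not default.
#'
#' Class fractions cover trajectory classes planted identically in both
#' genotypes (`up_x2`, `up_x10`, `down_x2`, `down_x10`, `steady`,
#' `unexpressed`) and SE-specific classes that differ between the genotypes
#' (`se_i` exclusive to the embryogenic culture, `se_ii` modulated only
#' there, `se_iii_a`/`se_iii_b` opposite directions, `se_iv` down-regulated
#' in the non-embryogenic culture). Default fractions echo study-scale
#' proportions: ~6% never expressed, ~35% modulated with up-regulation
#' dominating ~4:1 and roughly half of the changes drastic, ~8% SE-specific.
#'
#' @param n_genes Number of genes. Default 1880.
#' @param class_fractions Named fractions summing to 1 over the classes
#'   listed above.
#' @param effect_sizes Named log2 effects `c(x2 = , x10 = )`; the `x10`
#'   effect must be at least `log2(10)`.
#' @param noise_sd Gaussian Ct noise, cycles. Default 0.25.
#' @param baseline_mean,baseline_sd Per-gene baseline delta-Ct distribution.
#'   Defaults 8 and 2.
#' @param reference_mean,reference_sd Reference-well Ct distribution per
#'   well. Defaults 22 and 0.2.
#' @param wells_per_run Reference wells per PCR run. Default 4.
#' @param ceiling Detection ceiling, cycles. Default 40.
#' @param n_replicates Biological replicates per condition. Default 3.
#' @param time_points Integer days. Default `c(0, 5, 10)`.
#' @param genotypes Two labels, embryogenic first.
#'   Default `c("Col-0", "tan1-2")`.
#' @param split_runs_by_replicate One PCR run per replicate instead of one
#'   per condition (stresses the per-run reference logic). Default `FALSE`.
#' @param seed Integer seed. Default 1.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 1880,
                             class_fractions = c(
                               up_x2 = 0.15, up_x10 = 0.14,
                               down_x2 = 0.04, down_x10 = 0.02,
                               steady = 0.51, unexpressed = 0.06,
                               se_i = 0.002, se_ii = 0.04,
                               se_iii_a = 0.018, se_iii_b = 0.006,
                               se_iv = 0.014),
                             effect_sizes = c(x2 = 1.5, x10 = 3.5),
                             noise_sd = 0.25,
                             baseline_mean = 8, baseline_sd = 2,
                             reference_mean = 22, reference_sd = 0.2,
                             wells_per_run = 4, ceiling = 40,
                             n_replicates = 3,
                             time_points = c(0, 5, 10),
                             genotypes = c("Col-0", "tan1-2"),
                             split_runs_by_replicate = FALSE,
                             seed = 1) {
  known <- c("up_x2", "up_x10", "down_x2", "down_x10", "steady",
             "unexpressed", "se_i", "se_ii", "se_iii_a", "se_iii_b", "se_iv")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% known)) {
    stop_seqpcr(paste0("class_fractions names must be among: ",
                       paste(known, collapse = ", ")),
                class = "seqpcr_config_error")
  }
  full <- stats::setNames(rep(0, length(known)), known)
  full[names(class_fractions)] <- class_fractions
  if (abs(sum(full) - 1) > 1e-9) {
    stop_seqpcr(sprintf("class fractions sum to %.6f, not 1", sum(full)),
                class = "seqpcr_config_error")
  }
  if (effect_sizes[["x10"]] < log2(10)) {
    stop_seqpcr("x10 effect size must be at least log2(10) to keep planted truth consistent with the drastic threshold",
                class = "seqpcr_config_error")
  }
  if (length(genotypes) != 2 || length(time_points) < 3) {
    stop_seqpcr("generator needs 2 genotypes and at least 3 time points",
                class = "seqpcr_config_error")
  }
  structure(
    list(n_genes = as.integer(n_genes), class_fractions = full,
         effect_sizes = effect_sizes, noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         reference_mean = reference_mean, reference_sd = reference_sd,
         wells_per_run = as.integer(wells_per_run), ceiling = ceiling,
         n_replicates = as.integer(n_replicates),
         time_points = as.integer(sort(time_points)), genotypes = genotypes,
         split_runs_by_replicate = isTRUE(split_runs_by_replicate),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Largest-remainder apportionment: counts match fractions exactly and are
# independent of the seed.
allocate_classes <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

# Planted per-genotype log2 effects for one class: induction (second vs first
# time point) and formation (third vs second) phases.
class_effects <- function(class, e2, e10) {
  z <- c(emb_ind = 0, emb_form = 0, mut_ind = 0, mut_form = 0)
  set <- function(...) { z[names(c(...))] <- c(...); z }
  switch(class,
    up_x2 = set(emb_ind = e2, mut_ind = e2),
    up_x10 = set(emb_ind = e10, mut_ind = e10),
    down_x2 = set(emb_ind = -e2, mut_ind = -e2),
    down_x10 = set(emb_ind = -e10, mut_ind = -e10),
    steady = z,
    unexpressed = z,
    se_i = set(emb_ind = e10),
    se_ii = set(emb_ind = e10),
    se_iii_a = set(emb_ind = e2, mut_ind = -e2),
    se_iii_b = set(emb_ind = -e2, mut_ind = e2),
    se_iv = set(emb_ind = -e2, mut_ind = -e2)
  )
}

effect_to_class <- function(effect) {
  ifelse(abs(effect) >= log2(10), ifelse(effect > 0, "up_x10", "down_x10"),
         ifelse(abs(effect) >= 1, ifelse(effect > 0, "up_x2", "down_x2"),
                "steady"))
}

effect_to_status <- function(effect) {
  ifelse(abs(effect) >= 1, ifelse(effect > 0, "up", "down"), "steady")
}

#' Generate a synthetic Ct dataset with full ground truth
#'
#' Builds a complete Ct table the analysis pipeline can consume, plus the
#' per-gene truth it should recover. Class counts are apportioned by largest
#' remainder (exactly matching the configured fractions), class labels are
#' shuffled over gene ids with the configured seed, and each measurement is
#' assembled as `Ct = planted delta-Ct + run reference Ct + N(0, noise_sd)`,
#' censored at the ceiling. Unexpressed cells sit exactly at the ceiling.
#' Reference wells are drawn per run; the run reference is their median, so
#' with zero Ct noise the pipeline recovers planted effects exactly (the
#' reference cancels).
#'
#' The ground-truth SE-specific group is derived from the planted
#' per-genotype trajectories with the same group logic the classifier
#' implements (see [classify_se_specific()]); note that a gene planted as
#' down-regulated in both cultures is therefore truthfully labelled group iv.
#'
#' @param config A [generator_config()].
#' @return List with elements `ct` (a [ct_table()]) and `truth` (tibble:
#'   `gene_id`, `class`, per-genotype expression flags, planted log2 effects
#'   and trajectory classes, `se_group`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  counts <- allocate_classes(cf$class_fractions, cf$n_genes)
  gene_ids <- sprintf("TF%05d", seq_len(cf$n_genes))
  emb <- cf$genotypes[1]; mut <- cf$genotypes[2]
  e2 <- cf$effect_sizes[["x2"]]; e10 <- cf$effect_sizes[["x10"]]
  times <- cf$time_points

  eff <- t(vapply(names(counts), class_effects, numeric(4), e2 = e2, e10 = e10))

  design <- expand.grid(genotype = cf$genotypes, time_point = times,
                        replicate = seq_len(cf$n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$run_id <- if (cf$split_runs_by_replicate) {
    sprintf("run_%s_%02dd_r%d", design$genotype, design$time_point,
            design$replicate)
  } else {
    sprintf("run_%s_%02dd", design$genotype, design$time_point)
  }
  runs <- unique(design$run_id)

  withr::with_seed(cf$seed, {
    classes <- sample(rep(names(counts), counts))
    wells <- tibble::tibble(
      run_id = rep(runs, each = cf$wells_per_run),
      ct = stats::rnorm(length(runs) * cf$wells_per_run,
                        cf$reference_mean, cf$reference_sd)
    )
    baseline <- stats::rnorm(cf$n_genes, cf$baseline_mean, cf$baseline_sd)
    noise <- stats::rnorm(cf$n_genes * nrow(design), 0, cf$noise_sd)
  })
  wells$ct <- pmin(pmax(wells$ct, 0.01), cf$ceiling)

  run_ref <- tapply(wells$ct, wells$run_id, stats::median)

  grid <- design[rep(seq_len(nrow(design)), each = cf$n_genes), ]
  grid$gene_id <- rep(gene_ids, times = nrow(design))
  gidx <- match(grid$gene_id, gene_ids)

  # planted delta-Ct: baseline minus cumulative planted log2 effect
  # (up-regulation lowers delta-Ct); effect depends on class, genotype, time
  side <- ifelse(grid$genotype == emb, "emb", "mut")
  ind_eff <- eff[cbind(match(classes[gidx], rownames(eff)),
                       match(paste0(side, "_ind"), colnames(eff)))]
  form_eff <- eff[cbind(match(classes[gidx], rownames(eff)),
                        match(paste0(side, "_form"), colnames(eff)))]
  cum_effect <- ifelse(grid$time_point >= times[3], ind_eff + form_eff,
                       ifelse(grid$time_point >= times[2], ind_eff, 0))

  delta_true <- baseline[gidx] - cum_effect
  ct <- delta_true + as.numeric(run_ref[grid$run_id]) + noise[seq_len(nrow(grid))]
  ct <- pmin(pmax(ct, 0.01), cf$ceiling)

  # unexpressed cells: at the ceiling everywhere (unexpressed class) or
  # throughout the non-embryogenic culture (exclusive class se_i)
  cls <- classes[gidx]
  dead <- cls == "unexpressed" | (cls == "se_i" & grid$genotype == mut)
  ct[dead] <- cf$ceiling

  records <- tibble::tibble(
    gene_id = grid$gene_id, genotype = grid$genotype,
    time_point = as.integer(grid$time_point),
    replicate = as.integer(grid$replicate),
    run_id = grid$run_id, ct = ct
  )

  truth <- tibble::tibble(
    gene_id = gene_ids, class = classes,
    expressed_emb = !(classes == "unexpressed"),
    expressed_mut = !(classes %in% c("unexpressed", "se_i")),
    log2fc_induction_emb = unname(eff[classes, "emb_ind"]),
    log2fc_formation_emb = unname(eff[classes, "emb_form"]),
    log2fc_induction_mut = unname(eff[classes, "mut_ind"]),
    log2fc_formation_mut = unname(eff[classes, "mut_form"])
  )
  truth$log2fc_induction_mut[!truth$expressed_mut] <- NA_real_
  truth$log2fc_formation_mut[!truth$expressed_mut] <- NA_real_
  truth$log2fc_induction_emb[!truth$expressed_emb] <- NA_real_
  truth$log2fc_formation_emb[!truth$expressed_emb] <- NA_real_

  status_or_na <- function(effect, expressed) {
    s <- effect_to_status(ifelse(is.na(effect), 0, effect))
    s[!expressed] <- "untestable"
    s
  }
  emb_ind_status <- status_or_na(truth$log2fc_induction_emb, truth$expressed_emb)
  mut_ind_status <- status_or_na(truth$log2fc_induction_mut, truth$expressed_mut)
  # formation statuses in the flipped (5d-10d) orientation
  flip <- c(up = "down", down = "up", steady = "steady",
            untestable = "untestable")
  emb_form_status <- flip[status_or_na(truth$log2fc_formation_emb,
                                       truth$expressed_emb)]
  mut_form_status <- flip[status_or_na(truth$log2fc_formation_mut,
                                       truth$expressed_mut)]

  truth$induction_class_emb <- effect_to_class(
    ifelse(is.na(truth$log2fc_induction_emb), 0, truth$log2fc_induction_emb))
  truth$formation_class_emb <- effect_to_class(
    ifelse(is.na(truth$log2fc_formation_emb), 0, truth$log2fc_formation_emb))
  truth$se_group <- classify_se_specific(
    emb_expressed = truth$expressed_emb, mut_expressed = truth$expressed_mut,
    emb_5d0d = emb_ind_status, emb_5d10d = unname(emb_form_status),
    mut_5d0d = mut_ind_status, mut_5d10d = unname(mut_form_status)
  )

  list(
    ct = ct_table(records, wells, ceiling = cf$ceiling),
    truth = truth
  )
}

#' Confusion-matrix metrics for a binary call set
#'
#' @param truth_pos,called_pos Aligned logical vectors.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `fdr` (0 when nothing is called positive).
#' @export
classification_metrics <- function(truth_pos, called_pos) {
  stopifnot(length(truth_pos) == length(called_pos))
  tp <- sum(truth_pos & called_pos)
  fp <- sum(!truth_pos & called_pos)
  fn <- sum(truth_pos & !called_pos)
  tn <- sum(!truth_pos & !called_pos)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    fdr = if (tp + fp == 0) 0 else fp / (tp + fp)
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items; 1 means
#' identical partitions, ~0 means chance-level agreement.
#'
#' @param a,b Aligned label vectors.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

#' Recovery metrics of pipeline calls against planted truth
#'
#' Scores how well the statistical pipeline recovered the generator's ground
#' truth: per-contrast sensitivity/specificity/empirical FDR of the modulated
#' calls in the embryogenic genotype, exact-agreement fraction of the finest
#' trajectory classes, and the SE-specific group confusion matrix. Optionally
#' the adjusted Rand index of cluster assignments against planted classes.
#'
#' @param truth Truth tibble from [generate_dataset()].
#' @param calls `gene_calls` table from [run_comparison_modes()] on the same
#'   dataset.
#' @param se_groups Optional tibble from [se_specific_classes()].
#' @param clusters Optional named cluster vector (e.g.
#'   `kmeans_patterns()$cluster`) scored against the planted classes.
#' @return List: `contrasts` (tibble with one row per scored contrast),
#'   `class_agreement`, `se_confusion` (matrix or NULL), `se_agreement`,
#'   `ari` (or NULL).
#' @export
recovery_metrics <- function(truth, calls, se_groups = NULL, clusters = NULL) {
  genes_truth <- sort(truth$gene_id)
  genes_calls <- sort(unique(calls$gene_id))
  if (!identical(genes_truth, genes_calls)) {
    extra <- setdiff(genes_calls, genes_truth)
    missing <- setdiff(genes_truth, genes_calls)
    stop_seqpcr(
      paste0("gene sets differ; only in calls: ",
             paste(utils::head(extra, 5), collapse = ", "),
             "; only in truth: ", paste(utils::head(missing, 5), collapse = ", ")),
      class = "seqpcr_parameter_error"
    )
  }
  params <- attr(calls, "params")
  emb <- params$embryogenic
  times <- sort(unique(calls$ref_time))

  truth_effect <- function(comparison) {
    ind <- ifelse(is.na(truth$log2fc_induction_emb), 0,
                  truth$log2fc_induction_emb)
    form <- ifelse(is.na(truth$log2fc_formation_emb), 0,
                   truth$log2fc_formation_emb)
    switch(comparison, induction = ind, formation = form,
           full = ind + form)
  }
  labels <- c(induction = sprintf("%dd-%dd", times[2], times[1]),
              formation = sprintf("%dd-%dd", times[3], times[2]),
              full = sprintf("%dd-%dd", times[3], times[1]))

  rows <- list()
  for (nm in names(labels)) {
    sub <- calls[calls$mode == 1L & calls$genotype == emb &
                   calls$comparison == labels[[nm]], ]
    sub <- sub[match(truth$gene_id, sub$gene_id), ]
    if (all(is.na(sub$status))) next
    called_pos <- sub$status %in% c("up", "down", "exclusive")
    truth_pos <- abs(truth_effect(nm)) >= 1 &
      (truth$expressed_emb | truth$class == "se_i")
    m <- classification_metrics(truth_pos, called_pos)
    m$contrast <- labels[[nm]]
    rows[[nm]] <- m
  }
  contrasts <- dplyr::bind_rows(rows) |>
    dplyr::select("contrast", dplyr::everything())

  # finest-trajectory agreement in the induction contrast
  sub <- calls[calls$mode == 1L & calls$genotype == emb &
                 calls$comparison == labels[["induction"]], ]
  sub <- sub[match(truth$gene_id, sub$gene_id), ]
  recovered <- as.character(classify_trajectory(sub$status, sub$magnitude))
  testable <- truth$expressed_emb
  class_agreement <- mean(recovered[testable] ==
                            truth$induction_class_emb[testable])

  se_confusion <- NULL
  se_agreement <- NA_real_
  if (!is.null(se_groups)) {
    rec <- se_groups$se_group[match(truth$gene_id, se_groups$gene_id)]
    se_confusion <- table(truth = truth$se_group, recovered = rec)
    se_agreement <- mean(as.character(rec) == as.character(truth$se_group),
                         na.rm = TRUE)
  }

  ari <- NULL
  if (!is.null(clusters)) {
    keep <- intersect(names(clusters), truth$gene_id)
    ari <- adjusted_rand_index(
      clusters[keep], truth$class[match(keep, truth$gene_id)])
  }

  list(contrasts = contrasts, class_agreement = class_agreement,
       se_confusion = se_confusion, se_agreement = se_agreement, ari = ari)
}
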
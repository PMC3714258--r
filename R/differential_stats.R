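#' One-way ANOVA across condition groups
#'
#' Classical fixed-effects one-way analysis of variance on replicate delta-Ct
#' values, used as the family-wise significance gate for a gene across all
#' genotype-by-time groups. Delegates to [stats::oneway.test()] with equal
#' variances; degenerate inputs are resolved first:
#' all values identical -> untestable (`NA` statistic and p); zero
#' within-group variance with unequal means -> infinite F, p reported as 0
#' with a `"zero_variance"` flag.
#'
#' @param groups List of numeric vectors, one per group; every group needs at
#'   least 2 values and at least 2 groups are required.
#' @return List: `statistic` (F), `p_value`, `df_between`, `df_within`,
#'   `degenerate` (`NA`, `"constant"` or `"zero_variance"`).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_seqpcr("need at least 2 groups", class = "seqpcr_parameter_error")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop_seqpcr("every group needs at least 2 values",
                class = "seqpcr_parameter_error")
  }
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n <- length(values)
  df_b <- k - 1L
  df_w <- n - k

  # constancy up to floating-point residue of the delta-Ct arithmetic
  scale <- max(abs(values), 1)
  tol <- 1e-10 * scale
  if (diff(range(values)) <= tol) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                df_between = df_b, df_within = df_w, degenerate = "constant"))
  }
  within_range <- vapply(groups, function(g) diff(range(g)), numeric(1))
  if (all(within_range <= tol)) {
    return(list(statistic = Inf, p_value = 0,
                df_between = df_b, df_within = df_w, degenerate = "zero_variance"))
  }

  g <- factor(rep(seq_along(groups), sizes))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df_between = df_b, df_within = df_w, degenerate = NA_character_)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]: each adjusted value is
#' at least its raw p, monotone in the sorted order, capped at 1, and returned
#' in the original input order.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_seqpcr("p-values must lie in [0, 1]", class = "seqpcr_value_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample t-test on replicate delta-Ct values
#'
#' Student's pooled-variance t-test by default (the Ct-scale noise model is
#' approximately Gaussian with common variance); Welch's unequal-variance
#' variant selectable. Degenerate zero-variance cases: both samples constant
#' with equal means -> t = 0, p = 1; constant with unequal means -> p
#' reported as 0 with a `"zero_variance"` flag.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @return List: `statistic` (t), `df`, `p_value`, `degenerate`.
#' @export
two_sample_t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    stop_seqpcr("each sample needs at least 2 values",
                class = "seqpcr_parameter_error")
  }
  # constancy up to floating-point residue (delta-Ct arithmetic can leave
  # ~1e-15 jitter on exactly replicated values)
  scale <- max(abs(c(a, b)), 1)
  constant <- function(x) diff(range(x)) <= 1e-10 * scale
  degenerate_result <- function() {
    if (abs(mean(a) - mean(b)) <= 1e-10 * scale) {
      list(statistic = 0, df = length(a) + length(b) - 2L,
           p_value = 1, degenerate = "constant")
    } else {
      list(statistic = sign(mean(a) - mean(b)) * Inf,
           df = length(a) + length(b) - 2L,
           p_value = 0, degenerate = "zero_variance")
    }
  }
  if (constant(a) && constant(b)) {
    return(degenerate_result())
  }
  fit <- tryCatch(stats::t.test(a, b, var.equal = (variant == "student")),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(degenerate_result())  # "data are essentially constant"
  }
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, degenerate = NA_character_)
}

#' Gate a contrast into a modulation call
#'
#' A gene is modulated in a contrast when all three gates pass: family-wise
#' ANOVA FDR below `alpha_fdr`, pairwise t-test p below `alpha_t`, and
#' absolute signed fold change at least the lower fold threshold. Direction
#' comes from the sign; magnitude is `"x10"` when the drastic threshold is
#' also met (thresholds are inclusive). Everything else is steady. An
#' untestable ANOVA (`NA`) means no evidence of change and yields steady.
#'
#' @param signed_fc Signed fold change(s).
#' @param anova_fdr FDR-adjusted ANOVA p-value(s); `NA` = untestable.
#' @param t_p Pairwise t-test p-value(s); `NA` = untestable.
#' @param alpha_fdr,alpha_t Significance levels, both default 0.05.
#' @param fold_thresholds Two increasing thresholds, default `c(2, 10)`.
#' @return Tibble with columns `status` (`"up"`, `"down"`, `"steady"`) and
#'   `magnitude` (`"none"`, `"x2"`, `"x10"`).
#' @export
call_gene_status <- function(signed_fc, anova_fdr, t_p,
                             alpha_fdr = 0.05, alpha_t = 0.05,
                             fold_thresholds = c(2, 10)) {
  stopifnot(length(fold_thresholds) == 2, diff(fold_thresholds) > 0)
  afc <- abs(signed_fc)
  modulated <- !is.na(signed_fc) & !is.na(anova_fdr) & !is.na(t_p) &
    anova_fdr < alpha_fdr & t_p < alpha_t & afc >= fold_thresholds[1]
  status <- ifelse(modulated, ifelse(signed_fc > 0, "up", "down"), "steady")
  magnitude <- ifelse(!modulated, "none",
                      ifelse(afc >= fold_thresholds[2], "x10", "x2"))
  tibble::tibble(status = status, magnitude = magnitude)
}

#' Run the two comparison modes of the profiling design
#'
#' The full statistical pipeline on a Ct table covering genotypes and time
#' points. Mode 1 contrasts time points within each genotype (later vs
#' earlier: 5d-0d, 10d-0d, 10d-5d in the reference design); mode 2 contrasts
#' the embryogenic genotype against each other genotype at every time point.
#' A single per-gene one-way ANOVA across all genotype-by-time groups gates
#' both modes; Benjamini-Hochberg FDR is computed over the tested genes,
#' per mode by default. Pairwise Student t-tests run on the replicate
#' delta-Ct values of each contrast.
#'
#' Comparison labels follow the "compared-reference" convention: `"5d-0d"`
#' compares day 5 against the day-0 reference, so a positive signed fold
#' change means up-regulation at day 5.
#'
#' @param x A [ct_table()].
#' @param embryogenic Genotype treated as the embryogenic (control) culture;
#'   default the first genotype occurring in the records.
#' @param min_detected Replicates required for a detection call, see
#'   [call_detection()].
#' @param alpha_fdr,alpha_t Significance levels for the gates.
#' @param t_variant `"student"` or `"welch"`.
#' @param fold_thresholds Modulation and drastic-change thresholds,
#'   default `c(2, 10)`.
#' @param fdr_scope `"per_mode"` (default) or `"global"`.
#' @return A tibble of per-gene, per-contrast calls (class `gene_calls`):
#'   design descriptors, `ddct`, `log2_fc`, `fold_change`, `signed_fc`,
#'   `anova_p`, `anova_fdr`, `t_p`, detection flags, `status`
#'   (up/down/steady/exclusive/untestable) and `magnitude`. The per-condition
#'   detection table and the call parameters are attached as attributes
#'   `"detection"` and `"params"`.
#' @export
run_comparison_modes <- function(x, embryogenic = NULL, min_detected = 2,
                                 alpha_fdr = 0.05, alpha_t = 0.05,
                                 t_variant = c("student", "welch"),
                                 fold_thresholds = c(2, 10),
                                 fdr_scope = c("per_mode", "global")) {
  t_variant <- match.arg(t_variant)
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(x, "ct_table"))

  norm <- compute_delta_ct(x)
  det <- detection_table(norm, min_detected)

  genotypes <- unique(x$records$genotype)
  times <- sort(unique(x$records$time_point))
  embryogenic <- embryogenic %||% genotypes[1]
  if (!embryogenic %in% genotypes) {
    stop_seqpcr(paste0("genotype not in data: ", embryogenic),
                class = "seqpcr_parameter_error")
  }

  # nested per-condition replicate vectors
  cond <- norm |>
    dplyr::group_by(.data$gene_id, .data$genotype, .data$time_point) |>
    dplyr::summarise(values = list(.data$delta_ct),
                     cens = list(.data$censored),
                     n = dplyr::n(), .groups = "drop")

  # one ANOVA per gene across all genotype x time groups with >= 2 replicates
  anova_tbl <- cond |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(anova_p = {
      grp <- .data$values[.data$n >= 2]
      if (length(grp) < 2) NA_real_ else one_way_anova(grp)$p_value
    }, .groups = "drop")

  # contrast plan
  plan <- list()
  for (g in genotypes) {
    for (i in seq_along(times)) {
      for (j in seq_along(times)) {
        if (j <= i) next
        plan[[length(plan) + 1]] <- tibble::tibble(
          mode = 1L, genotype = g,
          comparison = sprintf("%dd-%dd", times[j], times[i]),
          ref_genotype = g, ref_time = times[i],
          cmp_genotype = g, cmp_time = times[j]
        )
      }
    }
  }
  if (length(genotypes) >= 2) {
    others <- setdiff(genotypes, embryogenic)
    for (g in others) {
      for (t in times) {
        plan[[length(plan) + 1]] <- tibble::tibble(
          mode = 2L, genotype = NA_character_,
          comparison = if (length(others) == 1) sprintf("%dd", t) else
            sprintf("%dd:%s", t, g),
          ref_genotype = g, ref_time = t,
          cmp_genotype = embryogenic, cmp_time = t
        )
      }
    }
  }
  plan <- dplyr::bind_rows(plan)

  key <- function(g, t) paste(g, t, sep = "\r")
  cond_idx <- split(seq_len(nrow(cond)), key(cond$genotype, cond$time_point))

  rows <- vector("list", nrow(plan))
  for (p in seq_len(nrow(plan))) {
    ref_rows <- cond[cond_idx[[key(plan$ref_genotype[p], plan$ref_time[p])]], ]
    cmp_rows <- cond[cond_idx[[key(plan$cmp_genotype[p], plan$cmp_time[p])]], ]
    merged <- dplyr::inner_join(
      ref_rows[, c("gene_id", "values", "cens", "n")],
      cmp_rows[, c("gene_id", "values", "cens", "n")],
      by = "gene_id", suffix = c("_ref", "_cmp")
    )
    m <- nrow(merged)
    ddct <- log2fc <- fc <- sfc <- tp <- rep(NA_real_, m)
    excl <- rep(NA_character_, m)
    untestable <- rep(FALSE, m)
    for (i in seq_len(m)) {
      cr <- compute_contrast(merged$gene_id[i],
                             merged$values_ref[[i]], merged$values_cmp[[i]],
                             merged$cens_ref[[i]], merged$cens_cmp[[i]])
      ddct[i] <- cr$ddct; log2fc[i] <- cr$log2_fc
      fc[i] <- cr$fold_change; sfc[i] <- cr$signed_fc
      excl[i] <- cr$exclusive
      if (is.na(cr$exclusive)) {
        if (merged$n_ref[i] < 2 || merged$n_cmp[i] < 2) {
          untestable[i] <- TRUE
        } else {
          tp[i] <- two_sample_t_test(merged$values_ref[[i]],
                                     merged$values_cmp[[i]],
                                     variant = t_variant)$p_value
        }
      }
    }
    rows[[p]] <- tibble::tibble(
      mode = plan$mode[p], genotype = plan$genotype[p],
      comparison = plan$comparison[p],
      gene_id = merged$gene_id,
      ref_genotype = plan$ref_genotype[p], ref_time = plan$ref_time[p],
      cmp_genotype = plan$cmp_genotype[p], cmp_time = plan$cmp_time[p],
      n_ref = merged$n_ref, n_cmp = merged$n_cmp,
      ddct = ddct, log2_fc = log2fc, fold_change = fc, signed_fc = sfc,
      t_p = tp, exclusive = excl, untestable = untestable
    )
  }
  calls <- dplyr::bind_rows(rows) |>
    dplyr::left_join(anova_tbl, by = "gene_id")

  # FDR over tested genes, within the requested scope
  adjust_within <- function(df) {
    gene_p <- df |>
      dplyr::distinct(.data$gene_id, .data$anova_p)
    tested <- !is.na(gene_p$anova_p)
    gene_p$anova_fdr <- NA_real_
    gene_p$anova_fdr[tested] <- bh_adjust(gene_p$anova_p[tested])
    dplyr::left_join(df, gene_p[, c("gene_id", "anova_fdr")], by = "gene_id")
  }
  calls <- if (fdr_scope == "global") {
    adjust_within(calls)
  } else {
    calls |>
      dplyr::group_by(.data$mode) |>
      dplyr::group_modify(~ adjust_within(.x)) |>
      dplyr::ungroup()
  }

  # detection flags for each side
  det_key <- det[, c("gene_id", "genotype", "time_point", "expressed")]
  calls <- calls |>
    dplyr::left_join(det_key, by = c("gene_id",
                                     ref_genotype = "genotype",
                                     ref_time = "time_point")) |>
    dplyr::rename(expressed_ref = "expressed") |>
    dplyr::left_join(det_key, by = c("gene_id",
                                     cmp_genotype = "genotype",
                                     cmp_time = "time_point")) |>
    dplyr::rename(expressed_cmp = "expressed")

  gates <- call_gene_status(calls$signed_fc, calls$anova_fdr, calls$t_p,
                            alpha_fdr = alpha_fdr, alpha_t = alpha_t,
                            fold_thresholds = fold_thresholds)
  calls$status <- gates$status
  calls$magnitude <- gates$magnitude
  calls$status[!is.na(calls$exclusive)] <- "exclusive"
  calls$magnitude[!is.na(calls$exclusive)] <- NA_character_
  calls$status[calls$untestable] <- "untestable"
  calls$magnitude[calls$untestable] <- NA_character_

  calls <- dplyr::arrange(calls, .data$mode, .data$comparison,
                          .data$genotype, .data$gene_id)
  attr(calls, "detection") <- det
  attr(calls, "params") <- list(
    embryogenic = embryogenic, min_detected = min_detected,
    alpha_fdr = alpha_fdr, alpha_t = alpha_t, t_variant = t_variant,
    fold_thresholds = fold_thresholds, fdr_scope = fdr_scope
  )
  class(calls) <- c("gene_calls", class(calls))
  calls
}
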
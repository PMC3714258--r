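#' Reference Ct of a PCR run
#'
#' The run-level normaliser is the median of the reference-gene wells measured
#' on that run (four wells per run in the reference design; for even counts
#' the midpoint of the two central values).
#'
#' @param wells Numeric vector of reference-gene Ct values (cycles).
#' @param expected_wells Number of wells the design calls for; fewer triggers
#'   a warning, not an error. Default 4.
#' @return The median well Ct (cycles).
#' @export
compute_reference_ct <- function(wells, expected_wells = 4) {
  if (length(wells) == 0 || all(is.na(wells))) {
    stop_seqpcr("no reference wells supplied",
                class = "seqpcr_missing_reference_error")
  }
  if (length(wells) < expected_wells) {
    rlang::warn(sprintf("only %d reference well(s) present (expected %d)",
                        length(wells), expected_wells))
  }
  stats::median(wells)
}

#' Normalise Ct values to the run reference (delta-Ct)
#'
#' For every measurement, `delta_ct = ct - reference Ct of the sample's run`,
#' where the run reference is the median of that run's reference wells. A
#' measurement at the detection ceiling is flagged `censored`: its delta-Ct is
#' a conservative floor on expression, not a real quantification. The
#' `expression_index` is `ceiling - delta_ct`, a monotone expression proxy
#' (higher = more transcript) on the familiar 40-minus scale.
#'
#' @param x A [ct_table()].
#' @return A tibble with one row per measurement: the design columns plus
#'   `ct`, `ref_ct`, `delta_ct`, `censored`, `expression_index`.
#' @export
compute_delta_ct <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  refs <- x$reference_wells |>
    dplyr::group_by(.data$run_id) |>
    dplyr::summarise(ref_ct = compute_reference_ct(.data$ct), .groups = "drop")

  missing_runs <- setdiff(unique(x$records$run_id), refs$run_id)
  if (length(missing_runs) > 0) {
    stop_seqpcr(
      paste0("no reference Ct for run(s): ", paste(missing_runs, collapse = ", ")),
      class = "seqpcr_missing_reference_error"
    )
  }

  x$records |>
    dplyr::left_join(refs, by = "run_id") |>
    dplyr::mutate(
      delta_ct = .data$ct - .data$ref_ct,
      censored = .data$ct == x$ceiling,
      expression_index = x$ceiling - .data$delta_ct
    )
}

#' Detection call for one condition
#'
#' A gene is called expressed in a condition when at least `min_detected`
#' biological replicates are below the ceiling. With fewer replicates than
#' `min_detected` the threshold degrades to the number available (a single
#' uncensored replicate suffices in a one-replicate condition).
#'
#' @param censored Logical vector, one entry per replicate (`TRUE` = Ct at the
#'   ceiling).
#' @param min_detected Minimum number of uncensored replicates. Default 2
#'   (of the design's 3).
#' @return Logical scalar: expressed or not.
#' @export
call_detection <- function(censored, min_detected = 2) {
  if (length(censored) == 0) {
    stop_seqpcr("no replicate values supplied", class = "seqpcr_parameter_error")
  }
  sum(!censored) >= min(min_detected, length(censored))
}

#' Per-condition detection table
#'
#' Applies [call_detection()] to every (gene, genotype, time point) cell of a
#' normalised expression table.
#'
#' @param norm Output of [compute_delta_ct()].
#' @inheritParams call_detection
#' @return Tibble `gene_id`, `genotype`, `time_point`, `n_replicates`,
#'   `n_detected`, `expressed`.
#' @export
detection_table <- function(norm, min_detected = 2) {
  norm |>
    dplyr::group_by(.data$gene_id, .data$genotype, .data$time_point) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_detected = sum(!.data$censored),
      expressed = call_detection(.data$censored, min_detected),
      .groups = "drop"
    )
}

#' Delta-delta-Ct contrast between two conditions
#'
#' Replicate delta-Ct values are averaged per condition, then
#' `ddct = mean(compared) - mean(reference)`. Up-regulation in the compared
#' condition (lower delta-Ct) gives `log2_fc = -ddct > 0` and
#' `fold_change = 2^log2_fc > 1`. The signed fold change follows the
#' reciprocal reporting convention: `fold_change` when `>= 1`, otherwise
#' `-1 / fold_change`, so a 2.5-fold repression prints as -2.50.
#'
#' When one side is entirely censored while the other is expressed, no
#' numeric fold change exists; the result carries an `exclusive` marker
#' (`"compared"` or `"reference"`) for downstream exclusive-expression logic.
#'
#' @param gene_id Gene label (carried through).
#' @param ref_values Replicate delta-Ct values of the reference condition.
#' @param cmp_values Replicate delta-Ct values of the compared condition.
#' @param ref_censored,cmp_censored Optional logical vectors marking
#'   ceiling-censored replicates on each side.
#' @return One-row tibble: `gene_id`, `n_ref`, `n_cmp`, `ddct`, `log2_fc`,
#'   `fold_change`, `signed_fc`, `exclusive` (NA when numeric).
#' @export
compute_contrast <- function(gene_id, ref_values, cmp_values,
                             ref_censored = NULL, cmp_censored = NULL) {
  if (length(ref_values) == 0 || length(cmp_values) == 0) {
    stop_seqpcr("both conditions need at least one replicate",
                class = "seqpcr_parameter_error")
  }
  ref_censored <- ref_censored %||% rep(FALSE, length(ref_values))
  cmp_censored <- cmp_censored %||% rep(FALSE, length(cmp_values))

  ref_dead <- all(ref_censored)
  cmp_dead <- all(cmp_censored)
  if (xor(ref_dead, cmp_dead)) {
    return(tibble::tibble(
      gene_id = gene_id, n_ref = length(ref_values), n_cmp = length(cmp_values),
      ddct = NA_real_, log2_fc = NA_real_, fold_change = NA_real_,
      signed_fc = NA_real_,
      exclusive = if (cmp_dead) "reference" else "compared"
    ))
  }

  ddct <- mean(cmp_values) - mean(ref_values)
  log2_fc <- -ddct
  fc <- 2^log2_fc
  tibble::tibble(
    gene_id = gene_id, n_ref = length(ref_values), n_cmp = length(cmp_values),
    ddct = ddct, log2_fc = log2_fc, fold_change = fc,
    signed_fc = if (fc >= 1) fc else -1 / fc,
    exclusive = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
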
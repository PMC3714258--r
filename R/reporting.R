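#' Directional summary with rounded percentages
#'
#' Turns up/down counts for a comparison into the printed-table form: total,
#' counts, and integer percentages rounded half away from zero (so 546 of 673
#' prints as 81%). Vectorised over comparisons.
#'
#' @param n_up,n_down Non-negative integer counts.
#' @param comparison,threshold Optional labels carried into the output.
#' @return Tibble `comparison`, `threshold`, `n_total`, `n_up`, `n_down`,
#'   `pct_up`, `pct_down`.
#' @export
percentage_table <- function(n_up, n_down, comparison = NA_character_,
                             threshold = NA_character_) {
  if (any(n_up < 0 | n_down < 0)) {
    stop_seqpcr("counts must be non-negative", class = "seqpcr_value_error")
  }
  total <- n_up + n_down
  if (any(total == 0)) {
    stop_seqpcr("nothing to summarise: both counts are zero",
                class = "seqpcr_value_error")
  }
  tibble::tibble(
    comparison = comparison, threshold = threshold,
    n_total = as.integer(total),
    n_up = as.integer(n_up), n_down = as.integer(n_down),
    pct_up = as.integer(round_half_up(100 * n_up / total)),
    pct_down = as.integer(round_half_up(100 * n_down / total))
  )
}

#' Directional summary of a gene-call table
#'
#' Builds the up/down accounting (one row per comparison and fold threshold)
#' from the output of [run_comparison_modes()], mirroring the usual printed
#' layout: the `x2` threshold counts all modulated genes (at least 2-fold),
#' `x10` the drastic subset.
#'
#' @param calls A `gene_calls` table.
#' @param mode Which comparison mode to summarise (default 1).
#' @return Tibble as from [percentage_table()], plus a `genotype` column.
#' @export
directional_summary <- function(calls, mode = 1) {
  sub <- calls[calls$mode == mode & calls$status %in% c("up", "down"), ]
  out <- list()
  for (grp in split(sub, paste(sub$genotype, sub$comparison, sep = "\r"))) {
    for (thr in c("x2", "x10")) {
      keep <- if (thr == "x2") grp else grp[grp$magnitude == "x10", ]
      n_up <- sum(keep$status == "up")
      n_down <- sum(keep$status == "down")
      if (n_up + n_down == 0) next
      row <- percentage_table(n_up, n_down, comparison = grp$comparison[1],
                              threshold = thr)
      row$genotype <- grp$genotype[1]
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Family and functional-category tallies of a gene set
#'
#' Counts genes per TF family and per functional category (a gene carrying
#' several categories counts once in each), and reports the annotated
#' fraction. Category percentages are given against both denominators — all
#' genes in the set and the annotated subset — since printed reports use
#' either.
#'
#' @param genes Character vector of gene ids.
#' @param annotation An [read_annotation_table()] object.
#' @return List: `families` (tibble `family`, `n`), `categories` (tibble
#'   `category`, `n`, `pct_of_genes`, `pct_of_annotated`), `n_genes`,
#'   `n_annotated`, `pct_annotated`.
#' @export
annotation_tally <- function(genes, annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  genes <- unique(genes)
  n_genes <- length(genes)

  fam <- annotation$family[genes]
  fam <- fam[!is.na(fam)]
  families <- if (length(fam) == 0) {
    tibble::tibble(family = character(), n = integer())
  } else {
    tb <- sort(table(fam), decreasing = TRUE)
    tibble::tibble(family = names(tb), n = as.integer(tb))
  }

  cats <- annotation$categories[intersect(genes, names(annotation$categories))]
  if (is.null(cats)) cats <- list()
  n_annotated <- sum(vapply(cats, length, integer(1)) > 0)
  flat <- unlist(cats, use.names = FALSE)
  categories <- if (length(flat) == 0) {
    tibble::tibble(category = character(), n = integer(),
                   pct_of_genes = integer(), pct_of_annotated = integer())
  } else {
    tb <- sort(table(flat), decreasing = TRUE)
    tibble::tibble(
      category = names(tb), n = as.integer(tb),
      pct_of_genes = as.integer(round_half_up(100 * as.integer(tb) / n_genes)),
      pct_of_annotated = as.integer(round_half_up(100 * as.integer(tb) / n_annotated))
    )
  }

  list(
    families = families, categories = categories,
    n_genes = n_genes, n_annotated = n_annotated,
    pct_annotated = if (n_genes == 0) NA_integer_ else
      as.integer(round_half_up(100 * n_annotated / n_genes))
  )
}

#' Hormone-class direction breakdown
#'
#' For each hormone class, the percentage of up- versus down-regulated genes
#' among that class's modulated genes. Classes with no modulated genes are
#' omitted.
#'
#' @param status_by_gene Tibble with columns `gene_id` and `status`
#'   (`up` / `down` / other; only up and down rows contribute).
#' @param annotation An [read_annotation_table()] object with hormone classes.
#' @return Tibble `hormone_class`, `n_up`, `n_down`, `pct_up`, `pct_down`.
#' @export
hormone_direction_tally <- function(status_by_gene, annotation) {
  stopifnot(inherits(annotation, "annotation_table"))
  df <- status_by_gene[status_by_gene$status %in% c("up", "down"), ]
  df$hormone_class <- unname(annotation$hormone_class[df$gene_id])
  df <- df[!is.na(df$hormone_class), ]
  if (nrow(df) == 0) {
    return(tibble::tibble(hormone_class = character(), n_up = integer(),
                          n_down = integer(), pct_up = integer(),
                          pct_down = integer()))
  }
  df |>
    dplyr::group_by(.data$hormone_class) |>
    dplyr::summarise(n_up = sum(.data$status == "up"),
                     n_down = sum(.data$status == "down"), .groups = "drop") |>
    dplyr::mutate(
      pct_up = as.integer(round_half_up(100 * .data$n_up / (.data$n_up + .data$n_down))),
      pct_down = as.integer(round_half_up(100 * .data$n_down / (.data$n_up + .data$n_down)))
    )
}
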
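#' Construct a Ct table
#'
#' The central data container of the pipeline: one quantification-cycle (Ct)
#' measurement per (gene, genotype, time point, biological replicate), plus the
#' reference-gene wells measured on every PCR run. A Ct equal to the detection
#' `ceiling` (40 cycles by default) encodes an undetected transcript.
#'
#' @param records A data frame with columns `gene_id`, `genotype`,
#'   `time_point` (integer days), `replicate` (integer >= 1), `run_id` and
#'   `ct` (cycles in `(0, ceiling]`).
#' @param reference_wells A data frame with columns `run_id` and `ct`: the
#'   reference-gene wells of each PCR run (typically four per run).
#' @param reference_gene_id Label of the reference gene used for
#'   normalisation. Default `"AT1G55060"` (*UBQ*).
#' @param ceiling Detection ceiling in cycles; `ct == ceiling` means
#'   "undetected". Default 40.
#'
#' @return An object of class `ct_table`: a list with elements `records`
#'   (tibble), `reference_wells` (tibble), `reference_gene_id` and `ceiling`.
#' @export
ct_table <- function(records, reference_wells,
                     reference_gene_id = "AT1G55060", ceiling = 40) {
  records <- tibble::as_tibble(records)
  reference_wells <- tibble::as_tibble(reference_wells)

  needed <- c("gene_id", "genotype", "time_point", "replicate", "run_id", "ct")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop_seqpcr(
      paste0("records is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "seqpcr_format_error"
    )
  }
  if (!all(c("run_id", "ct") %in% names(reference_wells))) {
    stop_seqpcr("reference_wells must have columns run_id and ct",
                class = "seqpcr_format_error")
  }

  records$time_point <- as.integer(records$time_point)
  records$replicate <- as.integer(records$replicate)

  validate_ct_values(records$ct, ceiling, what = "records")
  validate_ct_values(reference_wells$ct, ceiling, what = "reference_wells")

  dup <- duplicated(records[, c("gene_id", "genotype", "time_point", "replicate")])
  if (any(dup)) {
    offender <- records[which(dup)[1], ]
    stop_seqpcr(
      sprintf("duplicate measurement for gene %s in sample (%s, %sd, rep %s)",
              offender$gene_id, offender$genotype, offender$time_point,
              offender$replicate),
      class = "seqpcr_duplicate_error"
    )
  }

  orphan_runs <- setdiff(unique(records$run_id), unique(reference_wells$run_id))
  if (length(orphan_runs) > 0) {
    stop_seqpcr(
      paste0("no reference wells for run(s): ",
             paste(orphan_runs, collapse = ", ")),
      class = "seqpcr_missing_reference_error"
    )
  }

  structure(
    list(
      records = records,
      reference_wells = reference_wells[, c("run_id", "ct")],
      reference_gene_id = reference_gene_id,
      ceiling = ceiling
    ),
    class = "ct_table"
  )
}

validate_ct_values <- function(ct, ceiling, what) {
  if (!is.numeric(ct)) {
    stop_seqpcr(paste0("ct column of ", what, " must be numeric"),
                class = "seqpcr_format_error")
  }
  bad <- which(is.na(ct) | ct <= 0 | ct > ceiling)
  if (length(bad) > 0) {
    stop_seqpcr(
      sprintf("%s row %d: ct = %s outside (0, %s]",
              what, bad[1], format(ct[bad[1]]), format(ceiling)),
      class = "seqpcr_value_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf(
    "<ct_table> %d measurements | %d genes | %d runs | reference %s | ceiling %s cycles\n",
    nrow(x$records), length(unique(x$records$gene_id)),
    length(unique(x$records$run_id)), x$reference_gene_id, format(x$ceiling)
  ))
  design <- dplyr::count(x$records, .data$genotype, .data$time_point)
  cat(sprintf("  %d genotype x time conditions; %d reference wells\n",
              nrow(design), nrow(x$reference_wells)))
  invisible(x)
}

#' Read a Ct table from a delimited file
#'
#' Expects a header with columns `gene_id`, `genotype`, `time_point`,
#' `replicate`, `run_id`, `ct`. Rows whose `gene_id` equals
#' `reference_gene_id` are routed to the run-level reference wells; all other
#' rows become gene measurements.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (canonical) or `"csv"` (accepted on read).
#' @inheritParams ct_table
#' @return A validated [ct_table()].
#' @export
read_ct_table <- function(path, dialect = c("tsv", "csv"),
                          reference_gene_id = "AT1G55060", ceiling = 40) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_seqpcr(paste0("file not found: ", path), class = "seqpcr_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- suppressWarnings(reader(path, show_col_types = FALSE, progress = FALSE))

  needed <- c("gene_id", "genotype", "time_point", "replicate", "run_id", "ct")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_seqpcr(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "seqpcr_format_error"
    )
  }

  is_ref <- raw$gene_id == reference_gene_id
  ct_table(
    records = raw[!is_ref, needed],
    reference_wells = raw[is_ref, c("run_id", "ct")],
    reference_gene_id = reference_gene_id,
    ceiling = ceiling
  )
}

#' Read a gene annotation table
#'
#' A flat user-supplied mapping of gene ids to a transcription-factor family,
#' a set of functional categories (`;`-separated in one cell) and an optional
#' hormone class. Genes absent from the expression data are allowed; an empty
#' categories cell means "not annotated".
#'
#' @param path Path to a TSV file with header
#'   `gene_id  family  categories  hormone_class` (the last two optional).
#' @return An object of class `annotation_table`: list with named elements
#'   `family` (character), `categories` (named list of character vectors) and
#'   `hormone_class` (character, `NA` where absent).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    stop_seqpcr(paste0("file not found: ", path), class = "seqpcr_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"gene_id" %in% names(raw)) {
    stop_seqpcr("missing required column(s): gene_id",
                class = "seqpcr_format_error")
  }
  genes <- raw$gene_id

  family <- if ("family" %in% names(raw)) raw$family else rep(NA_character_, length(genes))
  names(family) <- genes

  categories <- rep(list(character()), length(genes))
  if ("categories" %in% names(raw)) {
    cells <- raw$categories
    bad <- grepl("^;|;;|;$", trimws(cells))
    bad[is.na(cells)] <- FALSE
    if (any(bad)) {
      stop_seqpcr(
        sprintf("malformed categories cell in row %d: %s",
                which(bad)[1], cells[which(bad)[1]]),
        class = "seqpcr_format_error"
      )
    }
    categories <- lapply(cells, function(cell) {
      if (is.na(cell) || !nzchar(trimws(cell))) character() else
        trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    })
  }
  names(categories) <- genes

  hormone <- if ("hormone_class" %in% names(raw)) raw$hormone_class else
    rep(NA_character_, length(genes))
  hormone[!is.na(hormone) & !nzchar(trimws(hormone))] <- NA_character_
  names(hormone) <- genes

  structure(
    list(family = family, categories = categories, hormone_class = hormone),
    class = "annotation_table"
  )
}

#' Read a somatic-embryogenesis phenotype assay table
#'
#' Per-replicate SE capacity endpoints of mutant/transgenic lines: efficiency
#' (percent of explants forming somatic embryos, in `[0, 100]`) and
#' productivity (mean somatic embryos per responding explant, `>= 0`).
#'
#' @param path Path to a TSV file with header
#'   `line  replicate  efficiency  productivity`.
#' @return A tibble with those four columns.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) {
    stop_seqpcr(paste0("file not found: ", path), class = "seqpcr_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("line", "replicate", "efficiency", "productivity")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_seqpcr(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "seqpcr_format_error"
    )
  }
  bad_eff <- which(is.na(raw$efficiency) | raw$efficiency < 0 | raw$efficiency > 100)
  if (length(bad_eff) > 0) {
    stop_seqpcr(sprintf("row %d: efficiency outside [0, 100]", bad_eff[1]),
                class = "seqpcr_value_error")
  }
  bad_prod <- which(is.na(raw$productivity) | raw$productivity < 0)
  if (length(bad_prod) > 0) {
    stop_seqpcr(sprintf("row %d: productivity must be >= 0", bad_prod[1]),
                class = "seqpcr_value_error")
  }
  tibble::as_tibble(raw[, needed])
}

#' Write a result table as a byte-stable TSV
#'
#' Deterministic serialisation used for all pipeline outputs: column order as
#' given, fold-change-like doubles to 4 decimals, p-value-like columns in
#' scientific notation. Writing the same table twice yields identical bytes;
#' re-reading reproduces values to the stated precision.
#'
#' @param rows A data frame (possibly zero rows; a header-only file is then
#'   written).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  pval_like <- grepl("(^|_)(p|pval|p_value|fdr)$", names(rows))
  for (j in seq_along(rows)) {
    col <- rows[[j]]
    if (is.double(col)) {
      fmt <- if (pval_like[j]) "%.4e" else "%.4f"
      txt <- ifelse(is.na(col), "NA", sprintf(fmt, col))
      out[[j]] <- txt
    } else if (is.list(col)) {
      out[[j]] <- vapply(col, function(x) paste(x, collapse = ";"), character(1))
    }
  }
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(paste(names(out), collapse = "\t"), con)
    if (nrow(out) > 0) {
      body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
      writeLines(body, con)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_seqpcr(paste0("cannot write ", path, ": ", conditionMessage(ok)),
                class = "seqpcr_io_error")
  }
  invisible(path)
}
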
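#' Disjoint region counts of 2 or 3 gene sets
#'
#' Venn-diagram accounting: for named sets A, B (and C), the count of every
#' disjoint region ("A" = in A only, "A&B" = in A and B but not C, ...).
#' Region counts sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors of gene ids.
#' @return Named integer vector over the `2^n - 1` regions.
#' @export
venn_regions <- function(sets) {
  if (!is.list(sets) || !length(sets) %in% c(2, 3) || is.null(names(sets))) {
    stop_seqpcr("sets must be a named list of 2 or 3 gene-id vectors",
                class = "seqpcr_parameter_error")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), nrow = 0, ncol = length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  n <- length(sets)
  out <- integer(0)
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      inside <- rowSums(member[, idx, drop = FALSE]) == size
      outside <- rowSums(member[, -idx, drop = FALSE]) == 0
      out[paste(names(sets)[idx], collapse = "&")] <- sum(inside & outside)
    }
  }
  out
}

trajectory_levels <- c("up_x2", "up_x10", "down_x2", "down_x10", "steady")

#' Trajectory class of one contrast
#'
#' Labels a gated contrast by direction and finest magnitude: `up_x10` /
#' `down_x10` for drastic (at least 10-fold) changes, `up_x2` / `down_x2` for
#' 2-to-10-fold changes, `steady` otherwise (including untestable contrasts).
#'
#' @param status Status vector from the modulation calls
#'   (`up` / `down` / `steady` / `exclusive` / `untestable`).
#' @param magnitude Magnitude vector (`none` / `x2` / `x10`).
#' @return Factor with levels `up_x2, up_x10, down_x2, down_x10, steady`.
#' @export
classify_trajectory <- function(status, magnitude) {
  out <- rep("steady", length(status))
  mod <- status %in% c("up", "down")
  out[mod] <- paste0(status[mod], "_", magnitude[mod])
  factor(out, levels = trajectory_levels)
}

#' Cross-tabulate induction against formation trajectories
#'
#' Contingency table of per-gene trajectory classes in the embryo-induction
#' contrast (rows; 5d-0d in the reference design) against the embryo-formation
#' contrast (columns; 10d-5d). With `rollup = FALSE` the classes are exclusive
#' (the `x2` class is 2-to-10-fold) and cells sum to the number of genes. With
#' `rollup = TRUE` the table is presented the way such summaries are usually
#' printed: `x>=2` rows/columns cumulate the drastic subset, a `total` column
#' gives row sums over the exclusive partition.
#'
#' @param induction,formation Trajectory factors from [classify_trajectory()],
#'   aligned by gene.
#' @param rollup Present cumulative `x>=2` margins instead of the exclusive
#'   partition. Default `FALSE`.
#' @return An integer matrix.
#' @export
crosstab_trajectories <- function(induction, formation, rollup = FALSE) {
  induction <- factor(induction, levels = trajectory_levels)
  formation <- factor(formation, levels = trajectory_levels)
  if (length(induction) != length(formation)) {
    stop_seqpcr("induction and formation labels must be aligned by gene",
                class = "seqpcr_parameter_error")
  }
  tab <- table(induction = induction, formation = formation)
  tab <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  if (!rollup) {
    return(tab)
  }
  cum <- function(v, dir) v[paste0(dir, "_x2")] + v[paste0(dir, "_x10")]
  roll_cols <- function(row) c(
    down_x2 = unname(cum(row, "down")), down_x10 = unname(row["down_x10"]),
    up_x2 = unname(cum(row, "up")), up_x10 = unname(row["up_x10"]),
    steady = unname(row["steady"])
  )
  rows <- list(
    up_x2 = colSums(tab[c("up_x2", "up_x10"), , drop = FALSE]),
    up_x10 = tab["up_x10", ],
    down_x2 = colSums(tab[c("down_x2", "down_x10"), , drop = FALSE]),
    down_x10 = tab["down_x10", ],
    steady = tab["steady", ]
  )
  out <- t(vapply(rows, roll_cols, numeric(5)))
  out <- cbind(out, total = vapply(rows, sum, numeric(1)))
  storage.mode(out) <- "integer"
  out
}

se_group_levels <- c("i", "ii", "iii_a", "iii_b", "iv", "none")

#' SE-specific classification of one gene
#'
#' Assigns the genotype-contrast group comparing an embryogenic culture with
#' a non-embryogenic one, from the two printed contrasts (induction, 5d-0d,
#' and the early-versus-advanced contrast 5d-10d) plus expression flags.
#' Groups, in precedence order:
#' \describe{
#'   \item{i}{expressed in the embryogenic culture, never detected in the
#'     non-embryogenic one (exclusive expression — the strongest evidence);}
#'   \item{iii_a / iii_b}{opposite induction behaviour: up in embryogenic and
#'     down in non-embryogenic (`iii_a`), or the reverse (`iii_b`);}
#'   \item{ii}{modulated in the embryogenic culture, steady in the
#'     non-embryogenic one in both inspected contrasts;}
#'   \item{iv}{down-regulated over the non-embryogenic culture in either
#'     phase, with the embryogenic genotype not steady in both contrasts;}
#'   \item{none}{anything else.}
#' }
#'
#' @param emb_expressed,mut_expressed Logical: detected at any time point of
#'   the embryogenic / non-embryogenic culture.
#' @param emb_5d0d,emb_5d10d,mut_5d0d,mut_5d10d Status labels
#'   (`up` / `down` / `steady` / `untestable`) of the two contrasts in each
#'   genotype. A `"5d-10d"` `up` means higher expression at day 5 than at
#'   day 10, i.e. decline during embryo formation.
#' @return Factor with levels `i, ii, iii_a, iii_b, iv, none` (vectorised).
#' @export
classify_se_specific <- function(emb_expressed, mut_expressed,
                                 emb_5d0d, emb_5d10d,
                                 mut_5d0d, mut_5d10d) {
  n <- length(emb_expressed)
  args <- list(mut_expressed, emb_5d0d, emb_5d10d, mut_5d0d, mut_5d10d)
  if (any(lengths(args) != n)) {
    stop_seqpcr("all classification inputs must have equal length",
                class = "seqpcr_parameter_error")
  }
  modulated <- function(s) s %in% c("up", "down")
  emb_mod <- modulated(emb_5d0d) | modulated(emb_5d10d)
  mut_steady <- mut_5d0d == "steady" & mut_5d10d == "steady"
  # down-regulation over culture time: induction down, or formation decline
  # (which prints as "up" in the 5d-10d orientation)
  mut_down_over_culture <- mut_5d0d == "down" | mut_5d10d == "up"

  out <- rep("none", n)
  out[mut_down_over_culture & emb_mod] <- "iv"
  out[emb_mod & mut_steady] <- "ii"
  out[emb_5d0d == "down" & mut_5d0d == "up"] <- "iii_b"
  out[emb_5d0d == "up" & mut_5d0d == "down"] <- "iii_a"
  out[emb_expressed & !mut_expressed] <- "i"
  out[is.na(emb_expressed) | is.na(mut_expressed)] <- NA
  factor(out, levels = se_group_levels)
}

#' SE-specific groups for a whole analysis
#'
#' Convenience wrapper deriving the [classify_se_specific()] inputs from the
#' output of [run_comparison_modes()] for a two-genotype design: mode-1
#' contrasts 5d-0d and 10d-5d (orientation flipped to 5d-10d), detection
#' flags pooled over all time points. Exclusive-expression contrasts count as
#' modulated in the direction of the expressed side.
#'
#' @param calls A `gene_calls` table from [run_comparison_modes()].
#' @param embryogenic,mutant Genotype labels; defaults come from the call
#'   parameters (embryogenic genotype, and the single remaining genotype).
#' @return Tibble `gene_id`, `se_group`.
#' @export
se_specific_classes <- function(calls, embryogenic = NULL, mutant = NULL) {
  params <- attr(calls, "params")
  det <- attr(calls, "detection")
  if (is.null(det)) {
    stop_seqpcr("calls must carry a detection attribute (see run_comparison_modes)",
                class = "seqpcr_parameter_error")
  }
  embryogenic <- embryogenic %||% params$embryogenic
  genotypes <- unique(det$genotype)
  mutant <- mutant %||% setdiff(genotypes, embryogenic)[1]
  if (is.na(mutant) || !all(c(embryogenic, mutant) %in% genotypes)) {
    stop_seqpcr("need both an embryogenic and a non-embryogenic genotype",
                class = "seqpcr_parameter_error")
  }

  times <- sort(unique(det$time_point))
  if (length(times) < 3) {
    stop_seqpcr("need at least 3 time points for SE-specific classification",
                class = "seqpcr_parameter_error")
  }
  lab_ind <- sprintf("%dd-%dd", times[2], times[1])   # induction, e.g. 5d-0d
  lab_form <- sprintf("%dd-%dd", times[3], times[2])  # formation, e.g. 10d-5d

  # status of one mode-1 contrast per genotype, exclusive resolved to a
  # direction, orientation optionally flipped (10d-5d -> 5d-10d)
  contrast_status <- function(g, label, flip = FALSE) {
    sub <- calls[calls$mode == 1L & calls$genotype == g &
                   calls$comparison == label, ]
    s <- sub$status
    # the exclusive marker names the expressed side: expressed only in the
    # compared condition means up-regulation there
    s[s == "exclusive"] <- ifelse(sub$exclusive[s == "exclusive"] == "compared",
                                  "up", "down")
    if (flip) s <- c(up = "down", down = "up", steady = "steady",
                     untestable = "untestable")[s]
    stats::setNames(unname(s), sub$gene_id)
  }

  genes <- sort(unique(calls$gene_id))
  emb_ind <- contrast_status(embryogenic, lab_ind)[genes]
  emb_form <- contrast_status(embryogenic, lab_form, flip = TRUE)[genes]
  mut_ind <- contrast_status(mutant, lab_ind)[genes]
  mut_form <- contrast_status(mutant, lab_form, flip = TRUE)[genes]

  expressed_any <- function(g) {
    d <- det[det$genotype == g, ]
    tapply(d$expressed, d$gene_id, any)[genes]
  }

  tibble::tibble(
    gene_id = genes,
    se_group = classify_se_specific(
      emb_expressed = unname(expressed_any(embryogenic)),
      mut_expressed = unname(expressed_any(mutant)),
      emb_5d0d = unname(emb_ind), emb_5d10d = unname(emb_form),
      mut_5d0d = unname(mut_ind), mut_5d10d = unname(mut_form)
    )
  )
}

#' K-means clustering of expression trajectories
#'
#' Lloyd's algorithm on per-gene expression-index profiles (condition means
#' of `ceiling - delta_ct` at each time point), Euclidean distance, `restarts`
#' random initialisations keeping the solution with the lowest total
#' within-cluster sum of squares. Clusters are renumbered deterministically by
#' descending centroid mean, so cluster 1 is always the highest-expression
#' pattern. Restarts whose initial centres collapse a cluster are redrawn.
#'
#' @param profiles Numeric matrix, genes in rows (rownames = gene ids),
#'   time points in columns.
#' @param k Number of clusters (default 4, the number of main patterns in the
#'   reference analysis).
#' @param restarts Random restarts, default 10.
#' @param seed Integer seed making the restart draws reproducible. Default 1.
#' @param scale_rows Z-score each gene's profile first (off by default; the
#'   reference scale is the raw 40-minus-delta-Ct index).
#' @return List of class `kmeans_patterns`: `cluster` (named integer vector),
#'   `centers` (k x time matrix), `withinss`, `tot_withinss`.
#' @export
kmeans_patterns <- function(profiles, k = 4, restarts = 10, seed = 1,
                            scale_rows = FALSE) {
  profiles <- as.matrix(profiles)
  if (scale_rows) {
    profiles <- t(scale(t(profiles)))
    profiles[is.nan(profiles)] <- 0
  }
  distinct <- unique(profiles)
  if (k < 1 || k > nrow(distinct)) {
    stop_seqpcr(sprintf("k = %d but only %d distinct profiles", k, nrow(distinct)),
                class = "seqpcr_parameter_error")
  }

  best <- NULL
  withr::with_seed(seed, {
    r <- 0
    attempts <- 0
    while (r < restarts && attempts < 50 * restarts) {
      attempts <- attempts + 1
      init <- distinct[sample(nrow(distinct), k), , drop = FALSE]
      fit <- tryCatch(
        stats::kmeans(profiles, centers = init, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (is.null(fit)) next  # empty cluster: redraw this restart's centres
      r <- r + 1
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) {
    stop_seqpcr("k-means failed to converge on any restart",
                class = "seqpcr_parameter_error")
  }

  ord <- order(rowMeans(best$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cluster <- stats::setNames(relabel[best$cluster], rownames(profiles))
  structure(
    list(cluster = cluster,
         centers = best$centers[ord, , drop = FALSE],
         withinss = best$withinss[ord],
         tot_withinss = best$tot.withinss),
    class = "kmeans_patterns"
  )
}

#' Per-gene expression-index profiles for clustering
#'
#' Condition means of the expression index (`ceiling - delta_ct`) for one
#' genotype, genes in rows and time points in columns.
#'
#' @param norm Output of [compute_delta_ct()].
#' @param genotype Genotype to profile; default the first one present.
#' @return Numeric matrix with gene-id rownames.
#' @export
expression_profiles <- function(norm, genotype = NULL) {
  genotype <- genotype %||% norm$genotype[1]
  sub <- norm[norm$genotype == genotype, ]
  wide <- sub |>
    dplyr::group_by(.data$gene_id, .data$time_point) |>
    dplyr::summarise(value = mean(.data$expression_index), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time_point", values_from = "value",
                       names_sort = TRUE)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$gene_id
  mat
}

#' Principal component analysis of samples
#'
#' Quality-control PCA on a samples-by-genes expression-index matrix via
#' [stats::prcomp()]: column-centred, unscaled by default. Zero-variance
#' genes are dropped with a message. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making scores reproducible
#' across platforms.
#'
#' @param mat Numeric matrix, samples in rows, genes in columns.
#' @param center Centre columns (default `TRUE`).
#' @return List: `scores` (samples x components), `loadings`
#'   (genes x components), `variance_fractions` (sums to 1), `dropped`
#'   (zero-variance gene names).
#' @export
pca_samples <- function(mat, center = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) {
    stop_seqpcr("need at least 2 samples", class = "seqpcr_parameter_error")
  }
  v <- apply(mat, 2, stats::var)
  dropped <- if (is.null(colnames(mat))) which(v == 0) else colnames(mat)[v == 0]
  if (any(v == 0)) {
    rlang::inform(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    mat <- mat[, v > 0, drop = FALSE]
  }
  fit <- stats::prcomp(mat, center = center, scale. = FALSE)
  flip <- apply(fit$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  list(
    scores = scores,
    loadings = loadings,
    variance_fractions = fit$sdev^2 / sum(fit$sdev^2),
    dropped = dropped
  )
}
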
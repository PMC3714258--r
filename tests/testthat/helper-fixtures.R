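# Fixtures are built in code: small Ct tables with known delta-Ct structure,
# written to tempfiles where a reader is under test.

# A Ct table planted directly on the delta-Ct scale: `values` is a named list
# gene -> list of "genotype.time" -> replicate delta-Ct vectors. Reference
# wells sit at exactly `ref_ct`, one run per condition, so ct = ref_ct + delta.
plant_ct_table <- function(values, ref_ct = 22, ceiling = 40, wells = 4) {
  rows <- list()
  for (gene in names(values)) {
    for (cond in names(values[[gene]])) {
      parts <- strsplit(cond, ".", fixed = TRUE)[[1]]
      reps <- values[[gene]][[cond]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = gene, genotype = parts[1],
        time_point = as.integer(parts[2]),
        replicate = seq_along(reps),
        run_id = paste0("run_", cond),
        ct = pmin(ref_ct + reps, ceiling)
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  ref <- tibble::tibble(
    run_id = rep(unique(records$run_id), each = wells),
    ct = ref_ct
  )
  ct_table(records, ref, ceiling = ceiling)
}

# Two-genotype, three-time-point table where every condition of every gene is
# given by a mean delta-Ct and replicates sit exactly at the mean (noiseless).
# `profile` is a function(genotype, time) -> mean delta-Ct for the gene.
plant_profiles <- function(profiles, n_rep = 3, ref_ct = 22, ceiling = 40) {
  values <- lapply(profiles, function(f) {
    conds <- list()
    for (g in c("Col-0", "tan1-2")) {
      for (t in c(0L, 5L, 10L)) {
        conds[[paste(g, t, sep = ".")]] <- rep(f(g, t), n_rep)
      }
    }
    conds
  })
  plant_ct_table(values, ref_ct = ref_ct, ceiling = ceiling)
}

# The toy delimited file of the reader examples: 2 genes x 3 samples plus
# 4 reference wells on one run.
write_toy_ct_tsv <- function(path, ref_gene = "AT1G55060") {
  lines <- c(
    "gene_id\tgenotype\ttime_point\treplicate\trun_id\tct",
    "G1\tCol-0\t0\t1\tR1\t25.0",
    "G1\tCol-0\t0\t2\tR1\t25.2",
    "G1\tCol-0\t0\t3\tR1\t24.8",
    "G2\tCol-0\t0\t1\tR1\t30.0",
    "G2\tCol-0\t0\t2\tR1\t30.4",
    "G2\tCol-0\t0\t3\tR1\t29.6",
    paste0(ref_gene, "\tCol-0\t0\t1\tR1\t21.9"),
    paste0(ref_gene, "\tCol-0\t0\t2\tR1\t22.1"),
    paste0(ref_gene, "\tCol-0\t0\t3\tR1\t22.3"),
    paste0(ref_gene, "\tCol-0\t0\t4\tR1\t22.5")
  )
  writeLines(lines, path)
  path
}

write_toy_annotation_tsv <- function(path) {
  lines <- c(
    "gene_id\tfamily\tcategories\thormone_class",
    "G1\tMYB\tdevelopment;stress\tauxin",
    "G2\tWRKY\t\t",
    "G3\tNAC\tdevelopment\tethylene"
  )
  writeLines(lines, path)
  path
}

# Independent sums-of-squares oracle for the one-way F statistic.
anova_f_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  k <- length(groups)
  n <- lengths(groups)
  ssb <- sum(n * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (sum(n) - k))
}

# Independent step-up oracle for Benjamini-Hochberg adjustment.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
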
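#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum comparison of two small phenotype samples. Up to `exact_limit`
#' total observations the two-sided p-value is computed exactly by full
#' enumeration of all `choose(n1 + n2, n1)` group labelings of the pooled
#' mid-ranks (ties handled naturally); two-sided p is twice the smaller tail
#' probability, capped at 1. Above the limit a normal approximation with tie
#' correction and continuity correction is used.
#'
#' With three replicates per group the smallest achievable exact two-sided
#' p-value is 0.1, so no 3-versus-3 comparison can reach p < 0.05 under the
#' exact test — a point worth remembering when interpreting significance
#' marks on triplicate assays.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Maximum `n1 + n2` for full enumeration. Default 12.
#' @return Tibble: `statistic` (U of the first sample), `p_value`, `method`
#'   (`"mann_whitney_exact"` or `"mann_whitney_normal"`), `n1`, `n2`.
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 12) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) {
    stop_seqpcr("both samples must be non-empty", class = "seqpcr_parameter_error")
  }
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= exact_limit) {
    picks <- utils::combn(n1 + n2, n1, simplify = FALSE)
    u_all <- vapply(picks, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2,
                    numeric(1))
    eps <- 1e-9
    p_le <- mean(u_all <= u_obs + eps)
    p_ge <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mann_whitney_exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nn + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "mann_whitney_normal"
  }
  tibble::tibble(statistic = u_obs, p_value = p, method = method,
                 n1 = n1, n2 = n2)
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric one-way comparison of two or more groups via
#' [stats::kruskal.test()] (H statistic with tie correction, chi-squared
#' p-value on k - 1 degrees of freedom). If every observation is identical,
#' H = 0 and p = 1.
#'
#' @param groups List of numeric vectors, each non-empty.
#' @return Tibble: `statistic` (H), `p_value`, `df`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(lengths(groups) == 0)) {
    stop_seqpcr("need at least 2 non-empty groups",
                class = "seqpcr_parameter_error")
  }
  values <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (all(values == values[1])) {
    return(tibble::tibble(statistic = 0, p_value = 1, df = df,
                          method = "kruskal_wallis"))
  }
  fit <- stats::kruskal.test(groups)
  tibble::tibble(statistic = unname(fit$statistic), p_value = fit$p.value,
                 df = df, method = "kruskal_wallis")
}

#' Compare every assayed line against the control line
#'
#' For each line in a phenotype assay table, Mann-Whitney tests of both SE
#' endpoints (efficiency and productivity) against the control line, with a
#' significance flag at `alpha`. Lines with fewer than 2 replicates are
#' skipped with a warning.
#'
#' @param assays Tibble from [read_phenotype_table()] (columns `line`,
#'   `replicate`, `efficiency`, `productivity`).
#' @param control Control line label, default `"Col-0"`.
#' @param alpha Significance level, default 0.05.
#' @inheritParams mann_whitney_exact
#' @return Tibble: `line`, `endpoint`, `statistic`, `p_value`, `method`,
#'   `n1`, `n2`, `significant`.
#' @export
compare_lines_to_control <- function(assays, control = "Col-0", alpha = 0.05,
                                     exact_limit = 12) {
  ctrl <- assays[assays$line == control, ]
  if (nrow(ctrl) < 2) {
    stop_seqpcr(sprintf("control line %s needs at least 2 replicates", control),
                class = "seqpcr_parameter_error")
  }
  out <- list()
  for (line in setdiff(unique(assays$line), control)) {
    sub <- assays[assays$line == line, ]
    if (nrow(sub) < 2) {
      rlang::warn(sprintf("skipping line %s: fewer than 2 replicates", line))
      next
    }
    for (endpoint in c("efficiency", "productivity")) {
      res <- mann_whitney_exact(sub[[endpoint]], ctrl[[endpoint]],
                                exact_limit = exact_limit)
      res$line <- line
      res$endpoint <- endpoint
      out[[length(out) + 1]] <- res
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(line = character(), endpoint = character(),
                          statistic = numeric(), p_value = numeric(),
                          method = character(), n1 = integer(),
                          n2 = integer(), significant = logical()))
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(significant = .data$p_value < alpha) |>
    dplyr::select("line", "endpoint", "statistic", "p_value", "method",
                  "n1", "n2", "significant")
}
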
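#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention used for all
#' printed percentages), in contrast to base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Combined discovery + validation mutation frequency
#'
#' @param mut_discovery,mut_validation Mutated-sample counts in the
#'   discovery and validation cohorts.
#' @param denominator Total samples screened for this gene (> 0).
#' @return List: `fraction` and `percent` (half-up, one decimal).
#' @export
combined_frequency <- function(mut_discovery, mut_validation, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  k <- mut_discovery + mut_validation
  if (k > denominator) stop("mutated count exceeds denominator")
  list(fraction = k / denominator,
       percent = round_half_up(100 * k / denominator, 1L))
}

#' Detection / confirmation rate across variant classes
#'
#' @param detected_by_class Named list, class -> c(detected, total).
#' @return List: `per_class` (percent per class) and `overall` (pooled
#'   percent, half-up one decimal).
#' @export
detection_rate <- function(detected_by_class) {
  m <- do.call(rbind, detected_by_class)
  if (any(m[, 1] > m[, 2])) stop("detected must not exceed total")
  if (sum(m[, 2]) == 0) stop("zero total")
  per <- round_half_up(100 * m[, 1] / m[, 2], 1L)
  list(per_class = stats::setNames(per, rownames(m)),
       overall = round_half_up(100 * sum(m[, 1]) / sum(m[, 2]), 1L))
}

contingency_result <- function(table, test, statistic, p_value) {
  structure(list(table = table, test = test, statistic = statistic,
                 p_value = p_value), class = "contingency_result")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by probability-mass ordering: the sum of
#' hypergeometric probabilities (margins fixed) of all tables at most as
#' probable as the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return A `contingency_result` (statistic = odds-ratio estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("fisher_exact_2x2 needs a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  ft <- stats::fisher.test(table)
  contingency_result(table, "fisher_exact",
                     unname(ft$estimate %||% NA_real_), ft$p.value)
}

#' Pearson chi-square test for an r x c table
#'
#' Uncorrected Pearson statistic by default (Yates continuity correction
#' available for 2x2 via `correct = TRUE`); df = (r-1)(c-1).
#'
#' @param table r x c matrix of nonnegative counts, r, c >= 2.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return A `contingency_result`.
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("need an r x c table, r,c >= 2")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  contingency_result(table, "chi_square", unname(ct$statistic), ct$p.value)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact enumeration p-value when both groups have <= 8 observations and no
#' ties are present; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param group_a,group_b Numeric vectors (nonempty).
#' @return A `contingency_result` (statistic = Mann-Whitney U of group A).
#' @export
rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 8L && length(group_b) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  contingency_result(list(a = group_a, b = group_b), "rank_sum",
                     unname(wt$statistic), min(wt$p.value, 1))
}

#' Per-gene recurrence table (discovery + validation, by histology)
#'
#' A sample counts once per gene regardless of mutation multiplicity.
#' Validation screens may test different subsets, so the denominator is
#' per gene.
#'
#' @param mutations `data.frame` with columns `tumor_id`, `gene_id`
#'   (protein-altering mutations from the discovery cohort).
#' @param metadata Cohort metadata with `tumor_id`, `histology`.
#' @param validation Optional `data.frame` per gene: `gene_id`,
#'   `mutated_samples`, `tested_samples` and optional per-histology columns
#'   `mutated_<group>`, `tested_<group>`.
#' @return `data.frame` per gene: mutated_discovery, tested_discovery,
#'   mutated_validation, tested_validation, denominator, mutated_total,
#'   frequency_pct, and per-histology discovery counts.
#' @export
recurrence_table <- function(mutations, metadata, validation = NULL) {
  if (nrow(mutations) == 0L)
    return(data.frame(gene_id = character(), mutated_discovery = integer(),
                      tested_discovery = integer(), mutated_validation = integer(),
                      tested_validation = integer(), denominator = integer(),
                      mutated_total = integer(), frequency_pct = numeric(),
                      stringsAsFactors = FALSE))
  unknown <- setdiff(mutations$tumor_id, metadata$tumor_id)
  if (length(unknown))
    stop("samples absent from metadata: ", paste(unknown, collapse = ", "))
  n_disc <- nrow(metadata)
  groups <- sort(unique(metadata$histology))
  per_gene <- lapply(split(mutations, mutations$gene_id), function(m) {
    samples <- unique(m$tumor_id)
    row <- data.frame(gene_id = m$gene_id[1],
                      mutated_discovery = length(samples),
                      tested_discovery = n_disc, stringsAsFactors = FALSE)
    for (g in groups) {
      in_g <- metadata$tumor_id[metadata$histology == g]
      row[[paste0("mutated_", g)]] <- sum(samples %in% in_g)
      row[[paste0("tested_", g)]] <- length(in_g)
    }
    row
  })
  out <- do.call(rbind, per_gene)
  out$mutated_validation <- 0L
  out$tested_validation <- 0L
  if (!is.null(validation)) {
    i <- match(out$gene_id, validation$gene_id)
    out$mutated_validation <- ifelse(is.na(i), 0L, validation$mutated_samples[i])
    out$tested_validation <- ifelse(is.na(i), 0L, validation$tested_samples[i])
  }
  if (any(out$mutated_validation > out$tested_validation))
    stop("validation mutated count exceeds tested count")
  out$denominator <- out$tested_discovery + out$tested_validation
  out$mutated_total <- out$mutated_discovery + out$mutated_validation
  out$frequency_pct <- round_half_up(100 * out$mutated_total / out$denominator, 1L)
  out <- out[order(-out$mutated_total, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
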
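#' Consensus-filter configuration
#'
#' Holds every threshold of the somatic-variant consolidation cascade:
#' SNVs must be called by at least `min_snv_callers` of the five SNV-eligible
#' callers; indels by any of the four indel-eligible callers; the variant
#' must be supported by >= 10 tumor reads for pindel or >= 2 for any other
#' caller; the germline variant allele fraction must be <= 5 %; indels
#' called by the tumor/germline-separate callers (pindel, unifiedgenotyper)
#' need a tumor-minus-germline VAF gap of at least 10 percentage points; the
#' variant must not be seen in more than two other cohort germlines nor in
#' more than two of the external panel germlines; and its population minor
#' allele frequency must be <= 5 %.
#'
#' @param min_snv_callers Minimum distinct SNV-eligible callers (default 2).
#' @param snv_caller_set The five SNV-eligible callers.
#' @param indel_caller_set The four indel-eligible callers.
#' @param min_tumor_reads_pindel,min_tumor_reads_other Tumor alt-read
#'   thresholds (defaults 10 and 2).
#' @param max_germline_vaf Maximum germline VAF (default 0.05).
#' @param min_tumor_germline_vaf_gap Minimum tumor-germline VAF gap for
#'   pindel/unifiedgenotyper indels (default 0.10).
#' @param max_panel_cohort,max_panel_external Maximum carrier counts in the
#'   cohort panel and the external panel (defaults 2 and 2).
#' @param panel_external_size Size of the external germline panel
#'   (default 147).
#' @param max_pop_maf Maximum population MAF (default 0.05).
#' @return A classed list (`filter_config`).
#' @export
filter_config <- function(min_snv_callers = 2L,
                          snv_caller_set = c("mutect", "jointsnvmix",
                                             "somaticsniper", "varscan",
                                             "unifiedgenotyper"),
                          indel_caller_set = c("somaticindeldetector",
                                               "varscan", "pindel",
                                               "unifiedgenotyper"),
                          min_tumor_reads_pindel = 10L,
                          min_tumor_reads_other = 2L,
                          max_germline_vaf = 0.05,
                          min_tumor_germline_vaf_gap = 0.10,
                          max_panel_cohort = 2L,
                          max_panel_external = 2L,
                          panel_external_size = 147L,
                          max_pop_maf = 0.05) {
  cfg <- list(min_snv_callers = as.integer(min_snv_callers),
              snv_caller_set = snv_caller_set,
              indel_caller_set = indel_caller_set,
              min_tumor_reads_pindel = as.integer(min_tumor_reads_pindel),
              min_tumor_reads_other = as.integer(min_tumor_reads_other),
              max_germline_vaf = max_germline_vaf,
              min_tumor_germline_vaf_gap = min_tumor_germline_vaf_gap,
              max_panel_cohort = as.integer(max_panel_cohort),
              max_panel_external = as.integer(max_panel_external),
              panel_external_size = as.integer(panel_external_size),
              max_pop_maf = max_pop_maf)
  if (any(c(cfg$min_snv_callers, cfg$min_tumor_reads_pindel,
            cfg$min_tumor_reads_other, cfg$max_panel_cohort,
            cfg$max_panel_external) < 0L))
    stop("thresholds must be nonnegative")
  if (cfg$max_germline_vaf < 0 || cfg$max_germline_vaf > 1 ||
      cfg$max_pop_maf < 0 || cfg$max_pop_maf > 1 ||
      cfg$min_tumor_germline_vaf_gap < 0 || cfg$min_tumor_germline_vaf_gap > 1)
    stop("fractions must lie in [0,1]")
  structure(cfg, class = "filter_config")
}

RULES <- c("support", "evidence", "germline_vaf", "vaf_gap",
           "cohort_panel", "external_panel", "pop_freq", "noncoding")

#' Caller-support rule
#'
#' SNVs pass with calls from >= `min_snv_callers` distinct callers of the
#' SNV-eligible set; indels pass with a call from any caller of the
#' indel-eligible set. Callers outside the eligible set are ignored for
#' support counting.
#'
#' @param calls Caller-call table for ONE variant (identical variant key).
#' @param cfg [filter_config()].
#' @return List: `pass` (logical) and `supporting` (eligible caller names).
#' @export
support_rule <- function(calls, cfg = filter_config()) {
  k <- unique(sprintf("%s:%d:%s>%s", calls$chrom, calls$pos, calls$ref, calls$alt))
  if (length(k) > 1L) stop("support_rule: calls span multiple variants")
  vclass <- calls$vclass[1]
  eligible <- if (vclass == "snv") cfg$snv_caller_set else cfg$indel_caller_set
  supporting <- sort(unique(calls$caller[calls$caller %in% eligible]))
  need <- if (vclass == "snv") cfg$min_snv_callers else 1L
  list(pass = length(supporting) >= need, supporting = supporting)
}

#' Tumor read-evidence rule (single call)
#'
#' A pindel call needs >= `min_tumor_reads_pindel` tumor alt reads; any
#' other caller's call needs >= `min_tumor_reads_other`. At the variant
#' level the rule is satisfied if at least one call passes.
#'
#' @param call One-row caller-call table.
#' @param cfg [filter_config()].
#' @return Logical.
#' @export
evidence_rule <- function(call, cfg = filter_config()) {
  need <- ifelse(call$caller == "pindel", cfg$min_tumor_reads_pindel,
                 cfg$min_tumor_reads_other)
  call$tumor_alt_reads >= need
}

#' Germline allele-fraction rule (single call)
#'
#' Passes iff germline alt reads / germline depth <= `max_germline_vaf`.
#' Zero germline depth is treated as 0 % (pass) but reported as
#' low-confidence by [consolidate()].
#'
#' @inheritParams evidence_rule
#' @return Logical.
#' @export
germline_vaf_rule <- function(call, cfg = filter_config()) {
  vaf <- ifelse(call$germline_depth > 0L,
                call$germline_alt_reads / call$germline_depth, 0)
  vaf <= cfg$max_germline_vaf
}

#' Tumor-germline VAF-gap rule (single call)
#'
#' Applies only to indels called by pindel or unifiedgenotyper (the callers
#' that genotype tumor and germline separately); all other calls pass
#' vacuously. Passes iff tumor VAF minus germline VAF >= the configured gap
#' (absolute fraction).
#'
#' @inheritParams evidence_rule
#' @return Logical.
#' @export
vaf_gap_rule <- function(call, cfg = filter_config()) {
  subject <- call$vclass == "indel" &
    call$caller %in% c("pindel", "unifiedgenotyper")
  t_vaf <- ifelse(call$tumor_depth > 0L,
                  call$tumor_alt_reads / call$tumor_depth, 0)
  g_vaf <- ifelse(call$germline_depth > 0L,
                  call$germline_alt_reads / call$germline_depth, 0)
  !subject | (t_vaf - g_vaf >= cfg$min_tumor_germline_vaf_gap)
}

#' Germline-panel rules
#'
#' The variant must not be carried by more than `max_panel_cohort` of the
#' OTHER germline samples in the cohort, nor by more than
#' `max_panel_external` germlines of the external panel. Variants absent
#' from a panel count as 0.
#'
#' @param keys Character vector of variant keys.
#' @param panel_counts Named integer vector, key -> carrier count (own
#'   matched germline already excluded).
#' @param cfg [filter_config()].
#' @param which `"cohort"` or `"external"`.
#' @return Logical vector.
#' @export
panel_rule <- function(keys, panel_counts, cfg = filter_config(),
                       which = c("cohort", "external")) {
  which <- match.arg(which)
  maxc <- if (which == "cohort") cfg$max_panel_cohort else cfg$max_panel_external
  cnt <- panel_counts[keys]
  cnt[is.na(cnt)] <- 0L
  unname(cnt <= maxc)
}

#' Population allele-frequency rule
#'
#' Passes iff the variant's population minor allele frequency is
#' <= `max_pop_maf`; variants absent from the table have MAF 0 and pass.
#'
#' @param keys Character vector of variant keys.
#' @param pop_freq Named numeric vector, key -> MAF.
#' @param cfg [filter_config()].
#' @return Logical vector.
#' @export
pop_freq_rule <- function(keys, pop_freq, cfg = filter_config()) {
  maf <- pop_freq[keys]
  maf[is.na(maf)] <- 0
  unname(maf <= cfg$max_pop_maf)
}

#' Consolidate one pair's call sets through the full filter cascade
#'
#' Calls are pooled across callers, grouped by normalized variant key, and
#' run through the cascade: caller support, tumor read evidence (any call),
#' germline VAF (maximum across calls), VAF gap (pindel/unifiedgenotyper
#' indels, any such call), cohort panel, external panel, population
#' frequency, then the coding/splice (+/-2 bp intronic) restriction. Every
#' input variant appears exactly once in the output with the complete list
#' of failed rules (empty iff retained).
#'
#' @param callsets List of caller-call tables (one per caller), already
#'   normalized against `ref`.
#' @param panel_counts Named integer vector of cohort-panel carrier counts
#'   (excluding this pair's own germline).
#' @param external_counts Named integer vector of external-panel carrier
#'   counts.
#' @param pop_freq Named numeric vector of population MAFs.
#' @param genes Gene models (for the coding/splice restriction); `NULL`
#'   skips that rule.
#' @param ref Reference genome.
#' @param cfg [filter_config()].
#' @return Decision `data.frame`: variant columns, `key`, `callers`
#'   (comma-joined supporting callers), `retained`, `failed_rules`
#'   (comma-joined), `low_confidence` (zero germline depth in all calls),
#'   `gene_id`, `consequence`.
#' @export
consolidate <- function(callsets, panel_counts = integer(),
                        external_counts = integer(), pop_freq = numeric(),
                        genes = NULL, ref = NULL, cfg = filter_config()) {
  calls <- do.call(rbind, unname(callsets))
  if (is.null(calls) || nrow(calls) == 0L) return(empty_decisions())
  calls <- calls[!calls$flagged, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty_decisions())
  key <- sprintf("%s:%d:%s>%s", calls$chrom, calls$pos, calls$ref, calls$alt)
  groups <- split(seq_len(nrow(calls)), key)
  ## deterministic order, independent of input call order
  ord <- order(vapply(groups, function(i) calls$chrom[i[1]], character(1)),
               vapply(groups, function(i) calls$pos[i[1]], integer(1)),
               names(groups))
  groups <- groups[ord]

  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    g <- calls[idx, , drop = FALSE]
    failed <- character(0)
    sup <- support_rule(g, cfg)
    if (!sup$pass) failed <- c(failed, "support")
    if (!any(evidence_rule(g, cfg))) failed <- c(failed, "evidence")
    if (!all(germline_vaf_rule_pooled(g, cfg))) failed <- c(failed, "germline_vaf")
    subject <- g$vclass == "indel" & g$caller %in% c("pindel", "unifiedgenotyper")
    if (any(subject) && !any(vaf_gap_rule(g[subject, , drop = FALSE], cfg)))
      failed <- c(failed, "vaf_gap")
    if (!panel_rule(k, panel_counts, cfg, "cohort"))
      failed <- c(failed, "cohort_panel")
    if (!panel_rule(k, external_counts, cfg, "external"))
      failed <- c(failed, "external_panel")
    if (!pop_freq_rule(k, pop_freq, cfg)) failed <- c(failed, "pop_freq")
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], vclass = g$vclass[1], key = k,
               callers = paste(sup$supporting, collapse = ","),
               failed_rules = paste(failed, collapse = ","),
               low_confidence = all(g$germline_depth == 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  ## coding/splice restriction, applied last so the audit separates
  ## biological-context rejections from evidence rejections
  out$gene_id <- NA_character_
  out$consequence <- NA_character_
  if (!is.null(genes) && !is.null(ref)) {
    cons <- classify_variants(out[, c("chrom", "pos", "ref", "alt", "vclass")],
                              genes, ref)
    out$gene_id <- cons$gene_id
    out$consequence <- cons$consequence
    nc <- cons$consequence == "noncoding"
    out$failed_rules <- ifelse(nc & nzchar(out$failed_rules),
                               paste(out$failed_rules, "noncoding", sep = ","),
                               ifelse(nc, "noncoding", out$failed_rules))
  }
  out$retained <- !nzchar(out$failed_rules)
  rownames(out) <- NULL
  out
}

## the <=5% germline rule is evaluated on the maximum germline VAF across
## the callers reporting the variant (conservative against germline leakage)
germline_vaf_rule_pooled <- function(g, cfg) {
  vaf <- ifelse(g$germline_depth > 0L, g$germline_alt_reads / g$germline_depth, 0)
  max(vaf) <= cfg$max_germline_vaf
}

empty_decisions <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character(), key = character(),
             callers = character(), failed_rules = character(),
             low_confidence = logical(), gene_id = character(),
             consequence = character(), retained = logical(),
             stringsAsFactors = FALSE)
}

#' Cohort-panel carrier counts from panel variant sets
#'
#' @param panel Named list (germline_id -> variant table) of panel call
#'   sets, e.g. read with [read_panel_vcf()].
#' @param exclude Germline id(s) to leave out (the pair's own matched
#'   germline).
#' @return Named integer vector, key -> number of carrying germlines.
#' @export
panel_counts <- function(panel, exclude = character()) {
  keep <- setdiff(names(panel), exclude)
  keys <- unlist(lapply(panel[keep], function(v)
    unique(variant_key(v))), use.names = FALSE)
  if (!length(keys)) return(stats::setNames(integer(), character()))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

#' Evaluate filter decisions against the simulated truth
#'
#' Sensitivity = retained true coding somatic variants / all true coding
#' somatic variants; precision = retained true somatic variants / all
#' retained variants. Reported overall and per variant class.
#'
#' @param decisions Decision table(s) from [consolidate()], with a
#'   `tumor_id` column when covering several pairs.
#' @param truth `truth_set` from [simulate_truth()].
#' @param tumor_id Pair to evaluate; default all pairs in `decisions`.
#' @return `data.frame` with rows overall/snv/indel: detected, total_true,
#'   sensitivity, retained, true_retained, precision.
#' @export
evaluate_against_truth <- function(decisions, truth, tumor_id = NULL) {
  if (is.null(decisions$tumor_id)) {
    if (is.null(tumor_id)) stop("supply tumor_id for single-pair decisions")
    decisions$tumor_id <- tumor_id
  }
  if (!is.null(tumor_id)) {
    decisions <- decisions[decisions$tumor_id %in% tumor_id, , drop = FALSE]
    tv <- truth$variants[truth$variants$tumor_id %in% tumor_id, , drop = FALSE]
  } else tv <- truth$variants[truth$variants$tumor_id %in%
                                unique(decisions$tumor_id), , drop = FALSE]
  som <- tv[tv$origin == "somatic" & tv$in_coding, , drop = FALSE]
  som_key <- paste(som$tumor_id, sprintf("%s:%d:%s>%s", som$chrom, som$pos,
                                         som$ref, som$alt))
  ret <- decisions[decisions$retained, , drop = FALSE]
  ret_key <- paste(ret$tumor_id, ret$key)
  per_class <- function(cls) {
    s <- if (cls == "overall") rep(TRUE, nrow(som)) else som$vclass == cls
    r <- if (cls == "overall") rep(TRUE, nrow(ret)) else ret$vclass == cls
    detected <- sum(som_key[s] %in% ret_key)
    true_ret <- sum(ret_key[r] %in% som_key)
    data.frame(class = cls, detected = detected, total_true = sum(s),
               sensitivity = if (sum(s)) detected / sum(s) else NA_real_,
               retained = sum(r), true_retained = true_ret,
               precision = if (sum(r)) true_ret / sum(r) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(per_class("overall"), per_class("snv"), per_class("indel"))
  rownames(out) <- NULL
  out
}
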
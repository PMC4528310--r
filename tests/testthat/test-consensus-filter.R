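# The eight-rule consolidation cascade and its audit trail.

test_that("support rule enforces >=2-of-5 for SNVs and any-of-4 for indels", {
  cfg <- filter_config()
  snv2 <- rbind(one_call(caller = "mutect"), one_call(caller = "varscan"))
  expect_true(support_rule(snv2, cfg)$pass)
  expect_false(support_rule(one_call(caller = "mutect"), cfg)$pass)
  # SNV-ineligible callers are ignored for SNV support
  snv_bad <- rbind(one_call(caller = "mutect"),
                   one_call(caller = "somaticindeldetector"))
  expect_false(support_rule(snv_bad, cfg)$pass)
  expect_equal(support_rule(snv_bad, cfg)$supporting, "mutect")
  ind1 <- one_call(pos = 7L, ref = "CA", alt = "C", caller = "pindel",
                   t_alt = 12L)
  expect_true(support_rule(ind1, cfg)$pass)
  # mutect is not indel-eligible
  indm <- one_call(pos = 7L, ref = "CA", alt = "C", caller = "mutect")
  expect_false(support_rule(indm, cfg)$pass)
  # mixed keys are rejected
  expect_error(support_rule(rbind(one_call(pos = 5L), one_call(pos = 6L, ref = "G", alt = "A")), cfg),
               "multiple variants")
})

test_that("read-evidence thresholds sit exactly at the documented boundaries", {
  cfg <- filter_config()
  expect_false(evidence_rule(one_call(caller = "pindel", t_alt = 9L), cfg))
  expect_true(evidence_rule(one_call(caller = "pindel", t_alt = 10L), cfg))
  expect_true(evidence_rule(one_call(caller = "mutect", t_alt = 2L), cfg))
  expect_false(evidence_rule(one_call(caller = "mutect", t_alt = 1L), cfg))
})

test_that("germline VAF rule is inclusive at 5% and passes zero-depth germlines", {
  cfg <- filter_config()
  expect_true(germline_vaf_rule(one_call(g_alt = 1L, g_dp = 25L), cfg))   # 4%
  expect_false(germline_vaf_rule(one_call(g_alt = 2L, g_dp = 25L), cfg))  # 8%
  expect_true(germline_vaf_rule(one_call(g_alt = 1L, g_dp = 20L), cfg))   # 5% inclusive
  expect_true(germline_vaf_rule(one_call(g_alt = 0L, g_dp = 0L), cfg))
})

test_that("VAF-gap rule binds only for pindel/unifiedgenotyper indels", {
  cfg <- filter_config()
  gap5 <- one_call(pos = 7L, ref = "CA", alt = "C", caller = "pindel",
                   t_alt = 30L, t_dp = 100L, g_alt = 25L, g_dp = 100L)
  expect_false(vaf_gap_rule(gap5, cfg))
  gap15 <- one_call(pos = 7L, ref = "CA", alt = "C", caller = "pindel",
                    t_alt = 40L, t_dp = 100L, g_alt = 25L, g_dp = 100L)
  expect_true(vaf_gap_rule(gap15, cfg))
  # SNVs and somatic-aware callers pass vacuously whatever the VAFs
  expect_true(vaf_gap_rule(one_call(t_alt = 10L, t_dp = 100L,
                                    g_alt = 9L, g_dp = 100L), cfg))
  ind_vs <- one_call(pos = 7L, ref = "CA", alt = "C", caller = "varscan",
                     t_alt = 20L, t_dp = 100L, g_alt = 15L, g_dp = 100L)
  expect_true(vaf_gap_rule(ind_vs, cfg))
})

test_that("panel and population rules use 'more than two' / '<=5%' boundaries", {
  cfg <- filter_config()
  counts <- c("c1:5:C>T" = 2L, "c1:9:G>A" = 3L)
  expect_true(panel_rule("c1:5:C>T", counts, cfg, "cohort"))
  expect_false(panel_rule("c1:9:G>A", counts, cfg, "cohort"))
  expect_true(panel_rule("c1:7:A>G", counts, cfg, "cohort"))  # absent -> 0
  maf <- c("c1:5:C>T" = 0.05, "c1:9:G>A" = 0.051)
  expect_true(pop_freq_rule("c1:5:C>T", maf, cfg))
  expect_false(pop_freq_rule("c1:9:G>A", maf, cfg))
  expect_true(pop_freq_rule("c1:7:A>G", maf, cfg))  # novel -> 0
})

# a small enumerated cohort hitting every rule boundary, checked against the
# independent brute-force oracle in helper-fixtures.R
test_that("consolidate matches the brute-force cascade oracle on a toy cohort", {
  ref <- toy_ref()
  genes <- list(toy_gene_plus())
  cfg <- filter_config()
  mk <- function(pos, refA, altA, caller, t_alt = 30L, t_dp = 100L,
                 g_alt = 0L, g_dp = 100L)
    one_call(pos = pos, ref = refA, alt = altA, caller = caller,
             t_alt = t_alt, t_dp = t_dp, g_alt = g_alt, g_dp = g_dp)
  ref_at <- function(p) ref_seq(ref, "chr1", p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1]

  callsets <- list(
    mutect = rbind(
      mk(12L, ref_at(12L), alt_of(12L), "mutect"),              # retained
      mk(14L, ref_at(14L), alt_of(14L), "mutect"),              # support fail (1 caller)
      mk(16L, ref_at(16L), alt_of(16L), "mutect", g_alt = 8L),  # germline 8%
      mk(18L, ref_at(18L), alt_of(18L), "mutect", t_alt = 1L),  # low evidence...
      mk(5L,  ref_at(5L),  alt_of(5L),  "mutect")),             # noncoding
    varscan = rbind(
      mk(12L, ref_at(12L), alt_of(12L), "varscan"),
      mk(16L, ref_at(16L), alt_of(16L), "varscan"),
      mk(18L, ref_at(18L), alt_of(18L), "varscan", t_alt = 1L),
      mk(5L,  ref_at(5L),  alt_of(5L),  "varscan"),
      mk(20L, ref_at(20L), alt_of(20L), "varscan")),            # panel-recurrent below
    jointsnvmix = rbind(
      mk(20L, ref_at(20L), alt_of(20L), "jointsnvmix"),
      mk(21L, ref_at(21L), alt_of(21L), "jointsnvmix")),        # pop-common below
    somaticsniper = mk(21L, ref_at(21L), alt_of(21L), "somaticsniper"),
    pindel = rbind(
      mk(36L, paste0(ref_at(36L), ref_at(37L)), ref_at(36L), "pindel",
         t_alt = 9L),                                           # pindel evidence fail
      mk(38L, paste0(ref_at(38L), ref_at(39L)), ref_at(38L), "pindel",
         t_alt = 30L, t_dp = 100L, g_alt = 25L, g_dp = 100L)),  # vaf gap 5%
    somaticindeldetector =
      mk(40L, paste0(ref_at(40L), ref_at(41L)), ref_at(40L),
         "somaticindeldetector", t_alt = 15L))                  # retained indel
  callsets <- lapply(callsets, function(cs)
    cbind(normalize_variants(cs[, c("chrom", "pos", "ref", "alt", "vclass")], ref),
          cs[, setdiff(names(cs), c("chrom", "pos", "ref", "alt", "vclass"))]))

  key20 <- variant_key(normalize_variants(
    variant_table("chr1", 20L, ref_at(20L), alt_of(20L)), ref))
  key21 <- variant_key(normalize_variants(
    variant_table("chr1", 21L, ref_at(21L), alt_of(21L)), ref))
  cohort_counts <- stats::setNames(3L, key20)
  external_counts <- stats::setNames(5L, key21)
  pop_freq <- stats::setNames(0.12, key21)

  d <- consolidate(callsets, cohort_counts, external_counts, pop_freq,
                   genes, ref, cfg)
  oracle <- brute_force_cascade(callsets, cohort_counts, external_counts,
                                pop_freq, genes, ref, cfg)
  expect_setequal(d$key, names(oracle))
  for (k in d$key)
    expect_equal(d$retained[d$key == k], oracle[[k]], label = k)
  # each input variant appears exactly once; audit is complete
  expect_equal(anyDuplicated(d$key), 0L)
  expect_true(all(xor(d$retained, nzchar(d$failed_rules))))
  # spot-check the named failures
  expect_match(d$failed_rules[d$pos == 14L], "support")
  expect_match(d$failed_rules[d$key == key20], "cohort_panel")
  expect_match(d$failed_rules[d$key == key21], "external_panel")
  expect_match(d$failed_rules[d$key == key21], "pop_freq")
  expect_match(d$failed_rules[d$pos == 5L], "noncoding")
  expect_match(d$failed_rules[d$pos == 36L], "evidence")
  expect_match(d$failed_rules[d$pos == 38L], "vaf_gap")
})

test_that("consolidate equals the oracle on random small cohorts", {
  set.seed(99)
  cfg <- filter_config()
  ref <- toy_ref()
  genes <- list(toy_gene_plus())
  for (rep in 1:8) {
    n <- sample(10:40, 1)
    pos <- sample(3:55, n, replace = TRUE)
    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- ref_seq(ref, "chr1", pos[i])
      if (stats::runif(1) < 0.75) {
        a <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        v <- variant_table("chr1", pos[i], b, a)
      } else {
        v <- variant_table("chr1", pos[i], paste0(b, ref_seq(ref, "chr1", pos[i] + 1L)), b)
      }
      g_dp <- sample(c(0L, 80L), 1, prob = c(.1, .9))
      caller_calls(v, sample(caller_names(), 1),
                   sample(0:40, 1), 100L, if (g_dp) sample(0:10, 1) else 0L,
                   g_dp)
    }))
    calls <- cbind(normalize_variants(calls[, c("chrom", "pos", "ref", "alt",
                                                "vclass")], ref),
                   calls[, setdiff(names(calls),
                                   c("chrom", "pos", "ref", "alt", "vclass"))])
    keys <- sprintf("%s:%d:%s>%s", calls$chrom, calls$pos, calls$ref, calls$alt)
    universe <- unique(keys)
    cohort_counts <- stats::setNames(sample(0:4, length(universe), TRUE), universe)
    external_counts <- stats::setNames(sample(0:4, length(universe), TRUE), universe)
    pop_freq <- stats::setNames(stats::runif(length(universe), 0, 0.1), universe)
    callsets <- split(calls, calls$caller)

    d <- consolidate(callsets, cohort_counts, external_counts, pop_freq,
                     genes, ref, cfg)
    oracle <- brute_force_cascade(callsets, cohort_counts, external_counts,
                                  pop_freq, genes, ref, cfg)
    expect_setequal(d$key, names(oracle))
    expect_equal(stats::setNames(d$retained, d$key)[names(oracle)],
                 unlist(oracle), ignore_attr = TRUE)

    # order independence: shuffling the calls changes nothing
    perm <- sample(nrow(calls))
    d2 <- consolidate(split(calls[perm, ], calls$caller[perm]),
                      cohort_counts, external_counts, pop_freq, genes, ref, cfg)
    expect_identical(d2, d)
  }
})

test_that("relaxing every threshold retains the union of eligible-caller variants", {
  ref <- toy_ref()
  loose <- filter_config(min_snv_callers = 1L, min_tumor_reads_pindel = 0L,
                         min_tumor_reads_other = 0L, max_germline_vaf = 1,
                         min_tumor_germline_vaf_gap = 0, max_panel_cohort = 10000L,
                         max_panel_external = 10000L, max_pop_maf = 1)
  callsets <- list(mutect = one_call(pos = 12L, ref = "T", alt = "A"),
                   varscan = one_call(pos = 14L, ref = "G", alt = "C",
                                      caller = "varscan", g_alt = 50L))
  d <- consolidate(callsets, genes = NULL, ref = ref, cfg = loose)
  expect_true(all(d$retained))
  expect_equal(nrow(d), 2L)
  # empty input
  expect_equal(nrow(consolidate(list(), cfg = loose)), 0L)
})

test_that("tightening any single threshold never grows the retained set", {
  set.seed(123)
  ref <- toy_ref()
  genes <- list(toy_gene_plus())
  base_cfg <- filter_config()
  # reuse one random cohort
  calls <- do.call(rbind, lapply(1:30, function(i) {
    p <- sample(3:55, 1)
    b <- ref_seq(ref, "chr1", p)
    caller_calls(variant_table("chr1", p, b, sample(setdiff(c("A", "C", "G", "T"), b), 1)),
                 sample(caller_names(), 1), sample(0:40, 1), 100L,
                 sample(0:8, 1), 80L)
  }))
  callsets <- split(calls, calls$caller)
  retained_with <- function(cfg)
    sum(consolidate(callsets, genes = genes, ref = ref, cfg = cfg)$retained)
  base_n <- retained_with(base_cfg)
  tighter <- list(filter_config(min_snv_callers = 3L),
                  filter_config(min_tumor_reads_other = 5L),
                  filter_config(max_germline_vaf = 0.02),
                  filter_config(max_pop_maf = 0.01),
                  filter_config(max_panel_cohort = 0L))
  for (cfg in tighter) expect_lte(retained_with(cfg), base_n)
})

test_that("evaluation against truth reports per-class sensitivity and precision", {
  # perfect pipeline: sensitivity and precision both 1
  cfg <- small_sim_config(seed = 51L, germline_snp_rate = 0)
  ref <- generate_reference(cfg)
  genes <- generate_gene_models(cfg, ref)
  truth <- simulate_truth(cfg, ref, genes)
  prof <- caller_profiles(
    sens_snv = stats::setNames(rep(1, 7), caller_names()),
    sens_indel = stats::setNames(rep(1, 7), caller_names()),
    fp_per_mb = stats::setNames(rep(0, 7), caller_names()))
  calls <- emulate_calls(truth, prof, cfg, ref)
  decisions <- do.call(rbind, lapply(names(calls), function(tid) {
    d <- consolidate(calls[[tid]]$callsets, genes = genes, ref = ref,
                     cfg = filter_config(min_tumor_reads_other = 0L,
                                         min_tumor_reads_pindel = 0L,
                                         min_tumor_germline_vaf_gap = 0))
    d$tumor_id <- tid
    d
  }))
  ev <- evaluate_against_truth(decisions, truth)
  expect_equal(ev$sensitivity[ev$class == "overall"], 1)
  expect_equal(ev$precision[ev$class == "overall"], 1)
})

test_that("zero-depth germlines are retained but flagged low-confidence", {
  ref <- toy_ref()
  calls <- list(
    mutect = one_call(pos = 12L, ref = "T", alt = "A", g_alt = 0L, g_dp = 0L),
    varscan = one_call(pos = 12L, ref = "T", alt = "A", caller = "varscan",
                       g_alt = 0L, g_dp = 0L))
  d <- consolidate(calls, genes = NULL, ref = ref)
  expect_true(d$retained)
  expect_true(d$low_confidence)
})
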
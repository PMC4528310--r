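# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing binary is stored.

make_ref <- function(...) {
  seqs <- c(...)
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- names(seqs)
  ref
}

# a 60 bp contig with a two-exon plus-strand gene and CpG-rich patches
toy_ref <- function() {
  #         1v        11v       21v       31v       41v       51v
  s <- paste0("TTACGTACGT", "ATGGCACGTC", "AAGTTTGACC", "GTGTGTGTGT",
              "ACGTTAGGCA", "TTTACGCGAT")
  make_ref(chr1 = s)
}

# + strand gene: exons [11,22] and [35,46], CDS the full exon chain (24 bases)
toy_gene_plus <- function() {
  gene_model("toyA", "chr1", "+", rbind(c(11L, 22L), c(35L, 46L)), 11L, 46L)
}

# mirror fixture on the reverse-complemented contig for strand tests
toy_ref_rc <- function() {
  make_ref(chr1 = revcomp(as.character(toy_ref()[["chr1"]])))
}

toy_gene_minus <- function() {
  # coordinates of toy_gene_plus mapped through x -> 61 - x
  gene_model("toyA", "chr1", "-", rbind(c(61L - 46L, 61L - 35L),
                                        c(61L - 22L, 61L - 11L)),
             61L - 46L, 61L - 11L)
}

one_call <- function(chrom = "chr1", pos = 5L, ref = "C", alt = "T",
                     caller = "mutect", t_alt = 30L, t_dp = 100L,
                     g_alt = 0L, g_dp = 100L) {
  caller_calls(variant_table(chrom, pos, ref, alt), caller,
               t_alt, t_dp, g_alt, g_dp)
}

# small deterministic config for pipeline-level tests
small_sim_config <- function(seed = 11L, ...) {
  sim_config(seed = seed,
             n_pairs = c(benign = 1L, borderline = 1L, carcinoma = 2L),
             n_contigs = 1L, contig_length = 120000L, n_genes = 50L,
             ...)
}

# independent brute-force re-implementation of the eight-rule cascade,
# deliberately structured rule-by-rule over explicit loops (the oracle for
# consolidate())
brute_force_cascade <- function(callsets, cohort_counts, external_counts,
                                pop_freq, genes, ref, cfg) {
  all_calls <- do.call(rbind, unname(callsets))
  all_calls <- all_calls[!all_calls$flagged, , drop = FALSE]
  keys <- unique(sprintf("%s:%d:%s>%s", all_calls$chrom, all_calls$pos,
                         all_calls$ref, all_calls$alt))
  res <- list()
  for (k in keys) {
    sel <- sprintf("%s:%d:%s>%s", all_calls$chrom, all_calls$pos,
                   all_calls$ref, all_calls$alt) == k
    g <- all_calls[sel, , drop = FALSE]
    is_snv <- g$vclass[1] == "snv"
    failed <- character(0)

    eligible <- if (is_snv) cfg$snv_caller_set else cfg$indel_caller_set
    nsup <- length(unique(g$caller[g$caller %in% eligible]))
    if (is_snv && nsup < cfg$min_snv_callers) failed <- c(failed, "support")
    if (!is_snv && nsup < 1) failed <- c(failed, "support")

    ev <- FALSE
    for (i in seq_len(nrow(g))) {
      thr <- if (g$caller[i] == "pindel") cfg$min_tumor_reads_pindel
             else cfg$min_tumor_reads_other
      if (g$tumor_alt_reads[i] >= thr) ev <- TRUE
    }
    if (!ev) failed <- c(failed, "evidence")

    gv <- 0
    for (i in seq_len(nrow(g)))
      if (g$germline_depth[i] > 0)
        gv <- max(gv, g$germline_alt_reads[i] / g$germline_depth[i])
    if (gv > cfg$max_germline_vaf) failed <- c(failed, "germline_vaf")

    subj <- which(g$vclass == "indel" &
                    g$caller %in% c("pindel", "unifiedgenotyper"))
    if (length(subj)) {
      ok <- FALSE
      for (i in subj) {
        tv <- if (g$tumor_depth[i] > 0) g$tumor_alt_reads[i] / g$tumor_depth[i] else 0
        gvv <- if (g$germline_depth[i] > 0)
          g$germline_alt_reads[i] / g$germline_depth[i] else 0
        if (tv - gvv >= cfg$min_tumor_germline_vaf_gap) ok <- TRUE
      }
      if (!ok) failed <- c(failed, "vaf_gap")
    }

    cc <- cohort_counts[k]; cc <- if (is.na(cc)) 0 else cc
    if (cc > cfg$max_panel_cohort) failed <- c(failed, "cohort_panel")
    ec <- external_counts[k]; ec <- if (is.na(ec)) 0 else ec
    if (ec > cfg$max_panel_external) failed <- c(failed, "external_panel")
    mf <- pop_freq[k]; mf <- if (is.na(mf)) 0 else mf
    if (mf > cfg$max_pop_maf) failed <- c(failed, "pop_freq")

    if (!is.null(genes)) {
      cons <- classify_variants(g[1, c("chrom", "pos", "ref", "alt", "vclass")],
                                genes, ref)$consequence
      if (cons == "noncoding") failed <- c(failed, "noncoding")
    }
    res[[k]] <- length(failed) == 0
  }
  res
}
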
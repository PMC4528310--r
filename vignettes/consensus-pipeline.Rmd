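---
title: "Consensus somatic calling and the mutational landscape: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus somatic calling and the mutational landscape: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Calling somatic mutations from matched tumor/germline exomes with a single
algorithm is unreliable: each caller has its own error profile, and germline
polymorphisms, sequencing artifacts and low-level contamination all leak into
the raw call sets. A widely used remedy is *consensus calling*: run several
callers, keep variants with enough independent support, and then pass the
survivors through a cascade of evidence and population filters. This package
implements such a cascade end to end — together with the downstream landscape
analyses (consequence classification, mutation burden, substitution spectra,
cohort recurrence statistics) — and, because real tumor data of this kind is
typically access-restricted, ships a fully synthetic tumor/normal cohort
generator with a known truth set against which every stage can be measured.

# The filter cascade

Calls from seven emulated callers (three SNV-only, one indel-only, one
handling both, and two that genotype tumor and germline separately) are
pooled per pair, matched across callers by *normalized* variant identity
(left-aligned, minimal representation — the usual VCF convention), and
filtered:

1. **Support** — SNVs need calls from at least 2 of the 5 SNV-eligible
   callers; indels need any of the 4 indel-eligible callers.
2. **Tumor evidence** — at least 10 alt reads for pindel calls, at least 2
   for any other caller; the variant passes if any one call does.
3. **Germline VAF** — the germline variant allele fraction must be at most
   5 %, evaluated on the maximum VAF across the callers reporting the
   variant (conservative against germline leakage).
4. **VAF gap** — indels from the tumor/germline-separate callers (pindel,
   unifiedgenotyper) additionally need the tumor VAF to exceed the germline
   VAF by at least 10 percentage points. The rule passes if any
   subject call meets the gap, mirroring the any-call convention of rule 2;
   germline indels carry similar VAFs in both samples, so the two
   conventions rarely disagree.
5. **Cohort panel** — the variant must not be carried by more than two of
   the *other* germline samples in the cohort.
6. **External panel** — nor by more than two of an external panel of 147
   germline exomes (carrier counts by genotype presence, not read support).
7. **Population frequency** — population minor allele frequency at most 5 %
   (unknown variants count as 0).
8. **Coding restriction** — only variants in coding sequence or within 2
   intronic bases of an exon/intron boundary are kept. This runs last so the
   audit trail separates biological-context rejections from evidence
   rejections.

Every candidate appears exactly once in the decision table with the full
list of failed rules; a variant is retained exactly when that list is empty.
Germline records with zero depth pass rule 3 (0 % by convention) but are
flagged low-confidence rather than silently trusted.

Design points the cascade's source text left open, decided here once:

* cross-caller matching uses the normalized (chrom, pos, ref, alt) key;
* SNVs from the tumor/germline-separate genotyper are *not* subject to the
  VAF-gap rule (it is an indel rule);
* panel membership counts genotype calls in the panel VCFs;
* "splice site (±2 bp)" means the two intronic bases at each junction —
  exonic junction bases are already coding;
* no stand-in is provided for manual read-level review: it is not an
  algorithm.

# Consequence classification

Gene models are single-transcript: ordered exons, CDS bounds, strand. A CDS
SNV is translated strand-aware; stop gains are `nonsense`, silent changes
`synonymous`, everything else `missense` (stop-loss and start-loss are binned
with missense — the landscape categories do not separate them). Indels fully
inside CDS are `frameshift_indel` when the length change is not a multiple of
3, else `inframe_indel`; indels touching the ±2 intronic window or spanning a
CDS/intron boundary are `splice_site` (boundary overlap is the conservative
call). Percentages in the consequence summary are taken over the
protein-altering total and rounded half-up to one decimal, the convention
used for all printed percentages in this package.

# Spectrum and burden

Substitutions are collapsed onto the pyrimidine strand (G>A is counted as
C>T), giving the six canonical classes, and tallied in 96
pyrimidine-oriented trinucleotide contexts. The NpCpG statistic counts C>T
events whose central C is followed by a 3′ G in pyrimidine orientation — the
motif of spontaneous 5-methylcytosine deamination. Events at contig edges or
with N in the context are excluded from the 96-class table but kept in the
six-class tallies; the profile therefore conserves counts exactly
(Σ six-class = n, Σ contexts + excluded = n) and is invariant under
reverse-complementing the whole cohort.

Mutation burden is coding mutations per callable megabase; a sample with
more than 10 mutations/Mb is flagged as a hypermutator. Group rates are
pooled (total mutations / total territory) rather than means of per-sample
rates, because per-sample territories differ.

# The synthetic cohort

The generator emulates the study conditions of a small three-group ovarian
tumor cohort (5 benign, 8 borderline, 11 carcinoma pairs by default):

* **Reference and genes.** An i.i.d. reference (41 % GC, two 200 kb
  contigs) with 90 deterministic-placed genes × 4 exons × 150 bp — a
  miniature 0.054 Mb CDS that serves as the *positional canvas* for
  mutations.
* **Territory and burden.** Burdens are defined against a nominal callable
  territory per histology group (31.75 / 36.6 / 44.6 Mb), emulating the
  heterogeneous capture designs of real cohorts, with true somatic rates of
  0.8 / 0.9 / 1.5 mutations/Mb. Expected per-tumor counts are therefore
  ≈ 25 / 33 / 67 — the scale of a real exome study — while positions are
  drawn on the miniature canvas. Per-Mb rates and the hypermutator flag
  read exactly as they would on real data.
* **Signature.** Substitution sites are drawn over all (CDS position, alt)
  pairs, with C>T-at-CpG choices up-weighted by `cpg_ct_weight` (default 8).
  With weight 1 the CpG C>T fraction equals the genomic opportunity
  fraction; with weight 8 the spectrum shows the marked NpCpG preference of
  methylcytosine deamination. Only the CpG channel is boosted, so the
  overall C>T fraction stays below what heavily deamination-driven real
  cohorts show (~64 %); the simulator is a qualitative template, not a fit.
* **Germline variation.** Cohort-level loci at 8×10⁻⁴/bp (10 % small
  indels) in four categories: common (MAF 0.06–0.5), rare (MAF < 0.04),
  private, and artifact-like (absent from the population table but carried
  by ~30 % of germlines — these exercise the panel rules). External-panel
  carrier counts are binomial over 147 exomes.
* **Read model.** Depths are negative binomial (mean 140, size 25, range
  roughly 50–220); alt reads are binomial at the true VAF. Somatic sites
  get Binomial(depth, 0.005) germline noise, so the 5 % germline rule passes
  almost all true somatics yet binds occasionally.
* **Callers.** Sensitivities 0.75–0.95 by caller and class; false positives
  are placed caller-privately and uniformly genome-wide (the coding
  restriction then removes most, and the 2-of-5 rule removes nearly all SNV
  FPs — indel FPs survive more often because a single indel caller
  suffices, which is a true property of the cascade). The two
  tumor/germline-separate callers also emit the pair's germline variants,
  which is what rules 3–7 exist to remove.

Everything is deterministic given the seed: the generator, the VCF/FASTA/
GFF3 serializations, and the pipeline outputs are byte-identical across
reruns, which the test suite asserts via md5.

What the simulator does *not* model: read-level errors (no FASTQ/BAM),
caller-specific artifact signatures, mapping ambiguity, copy number, tumor
purity gradients, FFPE damage. Passing tests therefore demonstrate the
correctness of the consolidation logic and statistics — not robustness to
the full mess of real sequencing data.

# Statistics

Recurrence tables count a sample once per gene regardless of mutation
multiplicity and allow per-gene denominators (validation screens test
different subsets). Contingency tests wrap the standard implementations:
Fisher's exact test (two-sided by probability-mass ordering; the test suite
verifies it against full hypergeometric enumeration for every 2×2 table with
N ≤ 60), Pearson's chi-square (uncorrected by default, Yates optional), and
the Mann–Whitney rank-sum test for burden comparisons (exact for groups of
≤ 8 without ties, otherwise normal approximation with tie and continuity
corrections). The burden comparison uses a rank test because group sizes are
small and distributions skewed. Note that for a 2×2 table the doubled
one-sided tail is an alternative two-sided convention that can differ from
probability-mass ordering in the third decimal; published p-values of
borderline magnitude can reflect either choice.

# Problem sizes and numerical choices

The bundled demo cohort (24 pairs, ~0.05 Mb canvas, ~1100 true somatic
mutations) runs the full pipeline in well under a minute; the test suite
uses smaller cohorts (4 pairs, 120 kb genome) for pipeline-level properties
and a 6-pair, 30 Mb-territory configuration to measure consensus sensitivity
on > 1000 SNVs against the closed-form 2-of-5 composition. Percent
formatting is half-up at one decimal everywhere (verified against a
rational-arithmetic oracle). Variant normalization left-extends through the
contig start is an error; variants overlapping N reference bases are
rejected at load because their trinucleotide context is undefined. Ties in
rank tests fall back to the corrected normal approximation because no exact
null is available under ties.

# Known limitations

Single-transcript gene models (no isoforms, no UTR-aware consequences, no
HGVS); no signature deconvolution; no indel spectra; recurrence significance
is reported as raw counts and test p-values without multiple-testing
correction, since gene-level significance calling belongs to dedicated
driver-discovery tools.
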
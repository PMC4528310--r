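# somaticsieve

Consensus filtering and mutational-landscape analysis of multi-caller
tumor/normal variant calls.

## What this is for

Exome studies of tumor cohorts call somatic mutations by running several
variant callers on each tumor/germline pair and consolidating their output:
no single caller is trustworthy, and raw call sets are contaminated with
germline polymorphisms and recurrent artifacts. `somaticsieve` implements
that consolidation as a transparent, fully audited cascade, plus the
standard downstream landscape analyses, for anyone who needs a reproducible,
testable version of this workflow — method developers benchmarking filter
designs, and analysts who want every rejection accounted for.

The cascade retains a variant when all of the following hold:

* **support** — SNVs called by ≥ 2 of {mutect, jointsnvmix, somaticsniper,
  varscan, unifiedgenotyper}; indels by ≥ 1 of {somaticindeldetector,
  varscan, pindel, unifiedgenotyper};
* **evidence** — ≥ 10 tumor alt reads (pindel) or ≥ 2 (any other caller);
* **germline VAF** — ≤ 5 % in the matched germline (maximum across callers);
* **VAF gap** — tumor VAF − germline VAF ≥ 10 points for pindel /
  unifiedgenotyper indels;
* **panels** — carried by ≤ 2 other cohort germlines and ≤ 2 of 147
  external germline exomes;
* **population** — minor allele frequency ≤ 5 %;
* **coding** — in CDS or within 2 intronic bases of a splice junction.

Retained mutations are classified (missense / nonsense / synonymous /
frameshift / inframe / splice), profiled as mutation burden per megabase
(hypermutator flag at > 10/Mb), six-class substitution spectra with 96
trinucleotide contexts and the NpCpG (CpG-deamination) C>T fraction, and
tabulated as per-gene recurrence with Fisher / chi-square / rank-sum group
comparisons.

Because data of this kind is usually access-restricted, the package also
ships a deterministic synthetic cohort generator (reference, gene models,
germline panel, population frequencies, per-caller VCFs with emulated
sensitivities and false positives) with a known truth set, so the whole
pipeline is benchmarkable: sensitivity and precision are measured, not
assumed.

## Worked example

```r
library(somaticsieve)

cfg <- sim_config(seed = 1)                       # 5 benign / 8 borderline / 11 carcinoma pairs
simulate_cohort(cfg, "demo-cohort")               # reference, genes, VCFs, panel, truth
res <- run_pipeline(pipeline_config("demo-cohort", "demo-out"))
res$stats$evaluation
```

The report (`demo-out/report.md`) for this seed reads, in part:

```
## Filter cascade funnel

- candidate variants: 2596
- after support: 1325
- after evidence: 1307
- after germline_vaf: 1164
- after vaf_gap: 1140
- after cohort_panel: 1140
- after external_panel: 1139
- after pop_freq: 1139
- after noncoding: 1089
- retained: 1089

## Burden by histology

- benign (n=5): mean 24.2 coding mutations (range 19-30), 0.76/Mb pooled, 0 hypermutated
- borderline (n=8): mean 32.2 coding mutations (range 25-42), 0.88/Mb pooled, 0 hypermutated
- carcinoma (n=11): mean 64.5 coding mutations (range 46-74), 1.45/Mb pooled, 0 hypermutated

## Substitution spectrum

C>A 12.5%, C>G 10.9%, C>T 28.0%, T>A 17.3%, T>C 16.4%, T>G 14.9%
- C>T at NpCpG: 65.8% of C>T, 18.4% of all substitutions
```

Reading the funnel: 2596 distinct candidate variants entered the cascade;
the support rule removed 1271 (mostly germline variants seen by a single
tumor/germline-separate caller, and caller-private false positives), the
germline-VAF rule removed another 143 shared germline variants, and the
coding restriction trimmed 50 noncoding survivors, leaving 1089 somatic
coding mutations. Burdens sit near 0.8 / 0.9 / 1.5 mutations/Mb by group
with no hypermutators, and the C>T class is strongly CpG-enriched (65.8 %
of C>T at NpCpG versus a ~8 % opportunity fraction) — the deamination
signature the simulator plants. Against the truth set this run retains
1089 calls of which 1084 are true (precision 99.5 %) and finds 99.0 % of
the 1095 true coding somatic mutations.

A thin CLI over the same functions is included at
`inst/scripts/somaticsieve.R` (`simulate`, `run`, `report` subcommands).

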
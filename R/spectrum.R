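SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Six-class substitution class of SNVs
#'
#' Purine reference bases are complement-collapsed to the pyrimidine
#' representation (G>A is reported as C>T, etc.), giving the six canonical
#' base-pair substitution classes.
#'
#' @param ref,alt Character vectors of single-base alleles.
#' @return Factor with levels `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
substitution_class <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("substitution_class is defined for SNVs only")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  cls <- paste0(r, ">", a)
  if (!all(cls %in% SIX_CLASSES)) stop("invalid substitution")
  factor(cls, levels = SIX_CLASSES)
}

#' Pyrimidine-oriented trinucleotide context of SNVs
#'
#' Returns the reference 3-mer centered on the mutated base, reverse-
#' complemented when the reference base is a purine so the mutated
#' pyrimidine is central. The `cpg` flag is true iff the central C is
#' followed by a 3' G in this orientation (the NpCpG deamination motif).
#' Contexts at contig edges or containing N are returned as `NA` (callers
#' exclude them from context tallies but keep them in six-class tallies).
#'
#' @param variants SNV variant table.
#' @param ref Reference genome.
#' @return `data.frame`: `context` (3-mer), `cpg` (logical), `class`
#'   (six-class factor), `excluded` (edge/N flag).
#' @export
trinucleotide_context <- function(variants, ref) {
  if (any(variants$vclass != "snv")) stop("SNVs only")
  n <- nrow(variants)
  lens <- contig_lengths(ref)
  ctx <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- variants$pos[i]; chrom <- variants$chrom[i]
    if (p > 1L && p < lens[[chrom]]) {
      tri <- ref_seq(ref, chrom, p - 1L, p + 1L)
      if (!grepl("N", tri, fixed = TRUE)) ctx[i] <- tri
    }
  }
  purine <- variants$ref %in% c("A", "G")
  oriented <- ifelse(is.na(ctx), NA_character_,
                     ifelse(purine, revcomp(ifelse(is.na(ctx), "NNN", ctx)), ctx))
  data.frame(context = oriented,
             cpg = !is.na(oriented) & substr(oriented, 2L, 2L) == "C" &
               substr(oriented, 3L, 3L) == "G",
             class = substitution_class(variants$ref, variants$alt),
             excluded = is.na(oriented), stringsAsFactors = FALSE)
}

all_context_classes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cls in SIX_CLASSES)
    for (p5 in bases) for (p3 in bases)
      out <- c(out, sprintf("%s[%s]%s", p5, cls, p3))
  out
}

#' Substitution-spectrum profile
#'
#' Tallies SNVs into the six substitution classes and the 96
#' pyrimidine-oriented trinucleotide-change classes, and counts C>T events
#' at NpCpG sites. Indels in the input are ignored. The 96-class tallies
#' marginalize exactly onto the six-class tallies minus edge/N-excluded
#' events.
#'
#' @param variants Normalized variant table (SNVs and indels; only SNVs are
#'   profiled).
#' @param ref Reference genome.
#' @return List of class `"spectrum_profile"`: `six_class_counts`,
#'   `context_counts` (96 named counts), `n_substitutions`, `ct_at_cpg`,
#'   `n_excluded`.
#' @export
spectrum_profile <- function(variants, ref) {
  snv <- variants[variants$vclass == "snv", , drop = FALSE]
  six <- stats::setNames(integer(6), SIX_CLASSES)
  ctx96 <- stats::setNames(integer(96), all_context_classes())
  prof <- list(six_class_counts = six, context_counts = ctx96,
               n_substitutions = 0L, ct_at_cpg = 0L, n_excluded = 0L)
  class(prof) <- "spectrum_profile"
  if (nrow(snv) == 0L) return(prof)
  tc <- trinucleotide_context(snv, ref)
  tab6 <- table(tc$class)
  six[names(tab6)] <- as.integer(tab6)
  kept <- !tc$excluded
  lab <- sprintf("%s[%s]%s", substr(tc$context[kept], 1, 1),
                 as.character(tc$class)[kept], substr(tc$context[kept], 3, 3))
  tab96 <- table(factor(lab, levels = all_context_classes()))
  ctx96[names(tab96)] <- as.integer(tab96)
  prof$six_class_counts <- six
  prof$context_counts <- ctx96
  prof$n_substitutions <- nrow(snv)
  prof$ct_at_cpg <- sum(tc$class == "C>T" & tc$cpg, na.rm = TRUE)
  prof$n_excluded <- sum(tc$excluded)
  prof
}

#' NpCpG deamination fractions of a spectrum profile
#'
#' @param profile A `spectrum_profile`.
#' @return List: `of_ct` — C>T-at-CpG / all C>T; `of_all` — C>T-at-CpG /
#'   all substitutions. `NA` (undefined) when the denominator is zero.
#' @export
npcpg_fraction <- function(profile) {
  ct <- profile$six_class_counts[["C>T"]]
  list(of_ct = if (ct > 0) profile$ct_at_cpg / ct else NA_real_,
       of_all = if (profile$n_substitutions > 0)
         profile$ct_at_cpg / profile$n_substitutions else NA_real_)
}

#' Per-sample mutation burden
#'
#' @param n_coding_mutations Count of coding somatic mutations.
#' @param territory_mb Callable territory in megabases (> 0).
#' @param sample_id,histology Optional labels.
#' @return One-row `data.frame`: sample_id, histology, n_coding_mutations,
#'   territory_mb, mutations_per_mb, hypermutated (rate > 10/Mb).
#' @export
mutation_burden <- function(n_coding_mutations, territory_mb,
                            sample_id = NA_character_,
                            histology = NA_character_) {
  if (any(territory_mb <= 0)) stop("territory_mb must be positive")
  rate <- n_coding_mutations / territory_mb
  data.frame(sample_id = sample_id, histology = histology,
             n_coding_mutations = as.integer(n_coding_mutations),
             territory_mb = territory_mb, mutations_per_mb = rate,
             hypermutated = rate > 10, stringsAsFactors = FALSE)
}

#' Per-histology burden summary
#'
#' Group rate is pooled (total mutations / total territory), not the mean
#' of per-sample rates.
#'
#' @param records Burden table ([mutation_burden()] rows).
#' @return `data.frame` per histology: n_samples, mean_count, min/max
#'   count, pooled_rate_per_mb, n_hypermutated.
#' @export
group_burden <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$histology), function(g) {
    data.frame(histology = g$histology[1], n_samples = nrow(g),
               mean_count = mean(g$n_coding_mutations),
               min_count = min(g$n_coding_mutations),
               max_count = max(g$n_coding_mutations),
               pooled_rate_per_mb = sum(g$n_coding_mutations) / sum(g$territory_mb),
               n_hypermutated = sum(g$hypermutated),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
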
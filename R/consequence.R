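CONSEQUENCES <- c("missense", "nonsense", "synonymous", "frameshift_indel",
                  "inframe_indel", "splice_site", "noncoding")
PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift_indel",
                      "inframe_indel", "splice_site")

#' Classify variants against gene models
#'
#' Classification per variant, against the single transcript model of the
#' overlapped gene:
#' * `splice_site` — the variant touches an intronic base within 2 bp of an
#'   exon/intron boundary, or an indel spans a CDS/intron boundary;
#' * CDS SNV — the codon is translated strand-aware: stop gain is
#'   `nonsense`, amino-acid change `missense` (stop-loss and start-loss are
#'   binned here too), silent `synonymous`;
#' * CDS indel — `frameshift_indel` iff the length difference is not a
#'   multiple of 3, else `inframe_indel`;
#' * everything else (intergenic, deep intronic, UTR) — `noncoding`.
#'
#' @param variants Normalized variant table.
#' @param genes List of `gene_model` objects.
#' @param ref Reference genome.
#' @return `data.frame`: variant columns + `gene_id`, `consequence`,
#'   `protein_altering`.
#' @export
classify_variants <- function(variants, genes, ref) {
  n <- nrow(variants)
  gene_id <- rep(NA_character_, n)
  consequence <- rep("noncoding", n)
  by_chrom <- split(genes, vapply(genes, `[[`, character(1), "chrom"))
  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]
    if (!chrom %in% names(ref)) stop("variant outside known contigs: ", chrom)
    cand <- by_chrom[[chrom]]
    if (is.null(cand)) next
    for (g in cand) {
      span <- c(min(g$exons), max(g$exons))
      if (variants$pos[i] > span[2] || variants$pos[i] + nchar(variants$ref[i]) - 1L < span[1])
        next
      consequence[i] <- classify_one(variants$pos[i], variants$ref[i],
                                     variants$alt[i], g, ref)
      gene_id[i] <- g$gene_id
      break
    }
  }
  cbind(variants,
        data.frame(gene_id = gene_id, consequence = consequence,
                   protein_altering = consequence %in% PROTEIN_ALTERING,
                   stringsAsFactors = FALSE))
}

classify_one <- function(pos, ref_allele, alt_allele, gene, ref) {
  cds <- cds_positions(gene)
  splice <- splice_region(gene, 2L)
  is_snv <- nchar(ref_allele) == 1L && nchar(alt_allele) == 1L
  if (is_snv) {
    if (pos %in% splice) return("splice_site")
    if (!(pos %in% cds)) return("noncoding")
    return(classify_cds_snv(pos, alt_allele, gene, cds, ref))
  }
  ## indel: affected bases are those beyond the shared anchor base
  L <- abs(nchar(ref_allele) - nchar(alt_allele))
  if (nchar(ref_allele) > nchar(alt_allele)) {
    affected <- seq.int(pos + 1L, pos + nchar(ref_allele) - 1L)
  } else {
    affected <- c(pos, pos + 1L)  # insertion point between pos and pos+1
  }
  if (any(affected %in% splice)) return("splice_site")
  in_cds <- affected %in% cds
  if (all(in_cds)) {
    return(if (L %% 3L != 0L) "frameshift_indel" else "inframe_indel")
  }
  if (any(in_cds)) return("splice_site")  # spans a CDS boundary
  "noncoding"
}

classify_cds_snv <- function(pos, alt_allele, gene, cds, ref) {
  ## CDS bases in transcription order
  tx_pos <- if (gene$strand == "+") cds else rev(cds)
  i <- match(pos, tx_pos)
  codon_idx <- (i - 1L) %/% 3L
  cpos <- tx_pos[codon_idx * 3L + 1:3]
  codon <- vapply(cpos, function(p) ref_seq(ref, gene$chrom, p), character(1))
  alt_codon <- codon
  alt_codon[match(pos, cpos)] <- alt_allele
  if (gene$strand == "-") {
    codon <- complement_base(codon)
    alt_codon <- complement_base(alt_codon)
  }
  aa_ref <- GENETIC_CODE_TABLE[paste(codon, collapse = "")]
  aa_alt <- GENETIC_CODE_TABLE[paste(alt_codon, collapse = "")]
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_alt == aa_ref) return("synonymous")
  "missense"  # includes stop-loss / start-loss by design
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Consequence summary table
#'
#' Counts per consequence category with percentages of the protein-altering
#' total, rounded half-up to one decimal.
#'
#' @param consequence Character vector of consequence labels (e.g. the
#'   `consequence` column of [classify_variants()] output), or a named
#'   integer vector of per-category counts.
#' @return `data.frame`: category, n, pct (percent of protein-altering
#'   total; `NA` for non-protein-altering categories or when the
#'   protein-altering total is zero).
#' @export
consequence_summary <- function(consequence) {
  if (is.numeric(consequence)) {
    counts <- stats::setNames(integer(length(CONSEQUENCES)), CONSEQUENCES)
    bad <- setdiff(names(consequence), CONSEQUENCES)
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    counts[names(consequence)] <- as.integer(consequence)
  } else {
    consequence <- factor(consequence, levels = CONSEQUENCES)
    if (anyNA(consequence)) stop("unknown consequence label")
    counts <- table(consequence)
  }
  out <- data.frame(category = CONSEQUENCES, n = as.integer(counts[CONSEQUENCES]),
                    stringsAsFactors = FALSE)
  pa_total <- sum(out$n[out$category %in% PROTEIN_ALTERING])
  out$pct <- ifelse(out$category %in% PROTEIN_ALTERING & pa_total > 0,
                    round_half_up(100 * out$n / pa_total, 1), NA_real_)
  attr(out, "protein_altering_total") <- pa_total
  out
}
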
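#' Construct a gene model
#'
#' Single-transcript gene model: ordered non-overlapping exons (1-based
#' closed intervals) with CDS bounds falling inside the exon union and a CDS
#' length divisible by 3.
#'
#' @param gene_id Gene name.
#' @param chrom Contig.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end), 1-based inclusive.
#' @param cds_start,cds_end 1-based inclusive CDS bounds.
#' @return A list of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stop("exon end < start")
  if (nrow(exons) > 1L && any(exons[-1L, 1] <= exons[-nrow(exons), 2]))
    stop("exons must be non-overlapping and sorted")
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  g <- structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                      exons = exons, cds_start = as.integer(cds_start),
                      cds_end = as.integer(cds_end)),
                 class = "gene_model")
  cds <- cds_positions(g)
  if (length(cds) == 0L) stop("empty CDS")
  if (cds_start < min(exons) || cds_end > max(exons) ||
      !in_exons(g, cds_start) || !in_exons(g, cds_end))
    stop("CDS bounds must fall inside the exon union")
  if (length(cds) %% 3L != 0L)
    stop("CDS length must be divisible by 3 (got ", length(cds), ")")
  g
}

in_exons <- function(gene, pos) {
  any(pos >= gene$exons[, 1] & pos <= gene$exons[, 2])
}

## genomic positions of CDS bases in ascending genomic order
cds_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$exons)), function(i) {
    s <- max(gene$exons[i, 1], gene$cds_start)
    e <- min(gene$exons[i, 2], gene$cds_end)
    if (s <= e) seq.int(s, e) else integer(0)
  }))
  as.integer(pos)
}

## intronic positions within `flank` bases of an exon/intron boundary
splice_region <- function(gene, flank = 2L) {
  n <- nrow(gene$exons)
  if (n < 2L) return(integer(0))
  pos <- integer(0)
  for (i in seq_len(n - 1L)) {
    don <- gene$exons[i, 2]     # intron starts at don + 1
    acc <- gene$exons[i + 1L, 1] # intron ends at acc - 1
    pos <- c(pos, seq.int(don + 1L, min(don + flank, acc - 1L)),
             seq.int(max(acc - flank, don + 1L), acc - 1L))
  }
  sort(unique(as.integer(pos)))
}

#' Total CDS territory of a gene-model set, in megabases
#'
#' @param genes List of `gene_model` objects.
#' @return CDS base count / 1e6.
#' @export
cds_territory_mb <- function(genes) {
  sum(vapply(genes, function(g) length(cds_positions(g)), integer(1))) / 1e6
}

#' Write gene models to GFF3
#'
#' Minimal GFF3 with `gene`, `exon` and `CDS` features; read back with
#' [read_gene_models()].
#'
#' @param genes List of `gene_model` objects.
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    gene_row <- sprintf("%s\tsomaticsieve\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, min(g$exons), max(g$exons), g$strand, g$gene_id)
    exon_rows <- sprintf("%s\tsomaticsieve\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom, g$exons[, 1], g$exons[, 2], g$strand, g$gene_id)
    cds_row <- sprintf("%s\tsomaticsieve\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                       g$chrom, g$cds_start, g$cds_end, g$strand, g$gene_id)
    c(gene_row, exon_rows, cds_row)
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path as written by [write_gene_models()] (gene/exon/CDS
#'   features with ID/Parent attributes).
#' @return List of `gene_model` objects, with attribute `territory_mb`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  ids <- as.character(df$ID)
  parents <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  gene_rows <- which(df$type == "gene")
  genes <- lapply(gene_rows, function(i) {
    gid <- ids[i]
    ex <- df[df$type == "exon" & parents == gid, , drop = FALSE]
    cds <- df[df$type == "CDS" & parents == gid, , drop = FALSE]
    if (nrow(cds) != 1L) stop("gene ", gid, " must have exactly one CDS record")
    gene_model(gid, as.character(df$seqnames[i]), as.character(df$strand[i]),
               cbind(ex$start, ex$end), cds$start, cds$end)
  })
  attr(genes, "territory_mb") <- cds_territory_mb(genes)
  genes
}
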
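#' Read a reference genome from FASTA
#'
#' Loads a (small) reference genome into memory as an uppercase
#' [Biostrings::DNAStringSet]. Every contig must be nonempty and contain only
#' A, C, G, T or N.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A named `DNAStringSet`, one entry per contig.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  validate_reference(ref)
  ref
}

#' Write a reference genome to FASTA
#'
#' @param ref A named `DNAStringSet` as returned by [read_reference()] or
#'   [generate_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  validate_reference(ref)
  Biostrings::writeXStringSet(ref, path, width = 70L)
  invisible(path)
}

validate_reference <- function(ref) {
  if (!methods::is(ref, "DNAStringSet"))
    stop("reference must be a DNAStringSet")
  if (length(ref) == 0L || is.null(names(ref)) || anyDuplicated(names(ref)))
    stop("reference contigs must be named and unique")
  if (any(Biostrings::width(ref) == 0L))
    stop("reference contigs must be nonempty")
  bad <- Biostrings::alphabetFrequency(ref, baseOnly = TRUE)[, "other"]
  # baseOnly buckets everything outside ACGT into "other"; N is allowed
  nN <- Biostrings::vcountPattern("N", ref)
  if (any(bad - nN > 0))
    stop("reference contains letters outside {A,C,G,T,N}")
  invisible(TRUE)
}

#' Extract reference sequence
#'
#' @param ref Reference genome (`DNAStringSet`).
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase character string of length `end - start + 1`.
#' @export
ref_seq <- function(ref, chrom, start, end = start) {
  if (!chrom %in% names(ref)) stop("unknown contig: ", chrom)
  len <- length(ref[[chrom]])
  if (start < 1L || end > len || start > end)
    stop(sprintf("coordinates %d-%d outside contig %s (length %d)",
                 start, end, chrom, len))
  as.character(Biostrings::subseq(ref[[chrom]], start, end))
}

contig_lengths <- function(ref) {
  stats::setNames(Biostrings::width(ref), names(ref))
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over {A,C,G,T,N}.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}
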
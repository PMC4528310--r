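#' Build a variant table
#'
#' The package represents genomic variants as plain data frames with columns
#' `chrom`, `pos` (1-based leftmost reference position), `ref`, `alt` and
#' `vclass` (`"snv"` or `"indel"`). Alleles are uppercase strings over
#' {A,C,G,T}; `vclass` is `"snv"` exactly when both alleles are single bases.
#'
#' @param chrom Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `vclass`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character()) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  recycle <- function(x) if (length(x) == 1L && n > 1L) rep(x, n) else x
  chrom <- recycle(chrom); pos <- recycle(pos)
  ref <- recycle(ref); alt <- recycle(alt)
  if (length(pos) != n || length(ref) != n || length(alt) != n ||
      length(chrom) != n)
    stop("chrom, pos, ref, alt must have equal length (or length 1)")
  if (n) {
    if (any(is.na(pos)) || any(pos < 1L)) stop("pos must be positive integers")
    if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("alleles must be nonempty")
    if (any(grepl("[^ACGT]", c(ref, alt)))) stop("alleles must be over {A,C,G,T}")
    if (any(ref == alt)) stop("ref and alt must differ")
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = vclass_of(ref, alt), stringsAsFactors = FALSE)
}

vclass_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

#' Normalize variants (left-align and trim to minimal representation)
#'
#' Converts each variant to its canonical form: shared suffix removed, shared
#' prefix reduced to the single anchor base required for indels, and indels
#' shifted to the leftmost position that produces the same edited sequence
#' (the usual VCF left-alignment convention). Normalization is idempotent and
#' preserves the edit: applying the raw or the normalized representation to
#' the reference yields identical sequences.
#'
#' @param v Variant table (see [variant_table()]).
#' @param ref_genome Reference genome (`DNAStringSet`).
#' @return The normalized variant table, same number of rows.
#' @export
normalize_variants <- function(v, ref_genome) {
  if (nrow(v) == 0L) return(v)
  lens <- contig_lengths(ref_genome)
  for (i in seq_len(nrow(v))) {
    chrom <- v$chrom[i]
    if (!chrom %in% names(lens)) stop("unknown contig: ", chrom)
    res <- normalize_one(v$pos[i], v$ref[i], v$alt[i],
                         ref_genome[[chrom]], lens[[chrom]], chrom)
    v$pos[i] <- res$pos; v$ref[i] <- res$ref; v$alt[i] <- res$alt
  }
  v$vclass <- vclass_of(v$ref, v$alt)
  v
}

normalize_one <- function(pos, ref, alt, contig_seq, contig_len, chrom) {
  if (pos < 1L || pos + nchar(ref) - 1L > contig_len)
    stop(sprintf("variant %s:%d %s>%s outside contig", chrom, pos, ref, alt))
  obs <- as.character(Biostrings::subseq(contig_seq, pos, pos + nchar(ref) - 1L))
  if (obs != ref)
    stop(sprintf("reference mismatch at %s:%d: expected %s, genome has %s",
                 chrom, pos, ref, obs))
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    # trim common suffix; if an allele empties, extend left with the reference
    if (length(r) && length(a) && r[length(r)] == a[length(a)] &&
        (length(r) > 1L || length(a) > 1L)) {
      r <- r[-length(r)]
      a <- a[-length(a)]
      if (length(r) == 0L || length(a) == 0L) {
        if (pos == 1L) stop(sprintf(
          "cannot left-extend indel at %s:%d beyond contig start", chrom, pos))
        pos <- pos - 1L
        b <- as.character(Biostrings::subseq(contig_seq, pos, pos))
        r <- c(b, r)
        a <- c(b, a)
      }
    } else break
  }
  # trim common prefix down to a single anchor base for indels, none for MNVs
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Canonical variant key
#'
#' Keys are equal iff (chrom, pos, ref, alt) are identical, so normalized
#' variants from different callers can be matched by key. Non-minimal
#' representations (shared suffix, or shared prefix beyond the indel anchor
#' base) are rejected; left-alignment itself can only be verified against the
#' genome and is the caller's responsibility via [normalize_variants()].
#'
#' @param v Variant table.
#' @return Character vector of keys, `"chrom:pos:ref>alt"`.
#' @export
variant_key <- function(v) {
  if (nrow(v) == 0L) return(character())
  nr <- nchar(v$ref); na <- nchar(v$alt)
  suff <- nr > 1L | na > 1L
  suff <- suff & substr(v$ref, nr, nr) == substr(v$alt, na, na)
  pref <- nr > 1L & na > 1L & substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  if (any(suff | pref))
    stop("variant_key requires normalized (minimal) variants; run normalize_variants()")
  sprintf("%s:%d:%s>%s", v$chrom, v$pos, v$ref, v$alt)
}

#' Apply a variant to a reference sequence
#'
#' Utility used mainly for testing edit-equivalence of variant
#' representations.
#'
#' @param seq Character string (one contig's sequence).
#' @param pos,ref,alt One variant on that contig.
#' @return The edited sequence as a character string.
#' @export
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}
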
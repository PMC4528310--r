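## VCF dialect used throughout the package: VCF 4.2, one file per caller per
## tumor/germline pair, sample columns TUMOR and GERMLINE, FORMAT "AD:DP"
## where AD is the alt-supporting read count for the (single) alternate
## allele of the record. The emitting caller is recorded in a ##caller=<name>
## header line. Multi-allelic records are split into one call per alternate
## allele on read.

CALLERS <- c("mutect", "jointsnvmix", "somaticsniper", "varscan",
             "somaticindeldetector", "pindel", "unifiedgenotyper")

#' Names of the seven emulated variant callers
#' @return Character vector of caller names.
#' @export
caller_names <- function() CALLERS

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vclass = character(), caller = character(),
             tumor_alt_reads = integer(), tumor_depth = integer(),
             germline_alt_reads = integer(), germline_depth = integer(),
             flagged = logical(), stringsAsFactors = FALSE)
}

#' Assemble a caller-call table
#'
#' One row per observation of a variant by one caller, with tumor and
#' germline read evidence. `0 <= alt_reads <= depth` is enforced for both
#' samples; compatibility of caller and variant class is deliberately NOT
#' enforced here (the consensus stage decides which callers are eligible).
#'
#' @param variants Variant table ([variant_table()]).
#' @param caller Caller name (recycled), one of [caller_names()].
#' @param tumor_alt_reads,tumor_depth,germline_alt_reads,germline_depth
#'   Integer read counts.
#' @param flagged Logical; marks records with missing/implausible evidence
#'   fields (kept, never silently dropped).
#' @return A caller-call `data.frame`.
#' @export
caller_calls <- function(variants, caller, tumor_alt_reads, tumor_depth,
                         germline_alt_reads, germline_depth,
                         flagged = FALSE) {
  n <- nrow(variants)
  if (n == 0L) return(empty_calls())
  caller <- rep_len(as.character(caller), n)
  if (!all(caller %in% CALLERS))
    stop("unknown caller(s): ", paste(setdiff(caller, CALLERS), collapse = ", "))
  out <- cbind(variants,
               data.frame(caller = caller,
                          tumor_alt_reads = rep_len(as.integer(tumor_alt_reads), n),
                          tumor_depth = rep_len(as.integer(tumor_depth), n),
                          germline_alt_reads = rep_len(as.integer(germline_alt_reads), n),
                          germline_depth = rep_len(as.integer(germline_depth), n),
                          flagged = rep_len(as.logical(flagged), n),
                          stringsAsFactors = FALSE))
  ok <- !out$flagged
  if (any(ok & (out$tumor_alt_reads > out$tumor_depth |
                out$germline_alt_reads > out$germline_depth |
                out$tumor_alt_reads < 0L | out$germline_alt_reads < 0L)))
    stop("alt read counts must satisfy 0 <= alt <= depth")
  out
}

#' Write a per-caller VCF
#'
#' @param calls Caller-call table for ONE caller.
#' @param path Output path (plain text `.vcf`).
#' @param tumor_id,germline_id Sample identifiers recorded in the header.
#' @param ref Optional reference genome; when given, contig header lines are
#'   written.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, tumor_id = "TUMOR",
                             germline_id = "GERMLINE", ref = NULL) {
  caller <- unique(calls$caller)
  if (length(caller) > 1L) stop("one VCF per caller; got: ",
                                paste(caller, collapse = ", "))
  if (length(caller) == 0L) caller <- "unknown"
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##caller=%s", caller),
           sprintf("##tumor_sample=%s", tumor_id),
           sprintf("##germline_sample=%s", germline_id),
           '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Alt-supporting read count">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(ref))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(ref),
                          Biostrings::width(ref)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "TUMOR", "GERMLINE", sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d:%d\t%d:%d",
                    calls$chrom, calls$pos, calls$ref, calls$alt,
                    calls$tumor_alt_reads, calls$tumor_depth,
                    calls$germline_alt_reads, calls$germline_depth)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-caller VCF into a caller-call table
#'
#' Multi-allelic records are split into one call per alternate allele (AD is
#' taken per-allele when comma-separated, else attributed to each split
#' record). Records with missing or unparseable AD/DP are kept and marked
#' `flagged = TRUE` with a warning naming the offending line numbers.
#' Variants whose REF overlaps an `N` reference base are rejected when `ref`
#' is supplied.
#'
#' @param path VCF path.
#' @param caller Caller name; default taken from the `##caller=` header line.
#' @param ref Optional reference genome for N-overlap rejection and
#'   reference-allele verification.
#' @return Caller-call `data.frame` (possibly 0 rows).
#' @export
read_caller_vcf <- function(path, caller = NULL, ref = NULL) {
  raw <- readLines(path)
  if (is.null(caller)) {
    cl <- grep("^##caller=", raw, value = TRUE)
    caller <- if (length(cl)) sub("^##caller=", "", cl[1]) else "unknown"
  }
  body_idx <- which(!startsWith(raw, "#"))
  body_idx <- body_idx[nzchar(raw[body_idx])]
  if (!length(body_idx)) return(empty_calls())

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  fmt <- gt[, "FORMAT"]
  samples <- setdiff(colnames(gt), "FORMAT")
  if (!all(c("TUMOR", "GERMLINE") %in% samples))
    stop("VCF must carry TUMOR and GERMLINE sample columns: ", path)

  get_field <- function(col, field) {
    keys <- strsplit(fmt, ":", fixed = TRUE)
    vals <- strsplit(gt[, col], ":", fixed = TRUE)
    vapply(seq_along(keys), function(i) {
      j <- match(field, keys[[i]])
      if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
    }, character(1))
  }
  t_ad <- get_field("TUMOR", "AD"); t_dp <- get_field("TUMOR", "DP")
  g_ad <- get_field("GERMLINE", "AD"); g_dp <- get_field("GERMLINE", "DP")

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ads <- strsplit(ifelse(is.na(t_ad[i]), "", t_ad[i]), ",", fixed = TRUE)[[1]]
    gads <- strsplit(ifelse(is.na(g_ad[i]), "", g_ad[i]), ",", fixed = TRUE)[[1]]
    per_alt_ad <- function(vals, k) {
      if (length(vals) == length(alts)) vals[k]
      else if (length(vals) == 1L) vals[1]
      else NA_character_
    }
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = toupper(fix[i, "REF"]), alt = toupper(alts[k]),
        tumor_alt_reads = suppressWarnings(as.integer(per_alt_ad(ads, k))),
        tumor_depth = suppressWarnings(as.integer(t_dp[i])),
        germline_alt_reads = suppressWarnings(as.integer(per_alt_ad(gads, k))),
        germline_depth = suppressWarnings(as.integer(g_dp[i])),
        line = body_idx[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty_calls())
  out <- out[!is.na(out$pos) & nzchar(out$ref) & nzchar(out$alt), , drop = FALSE]
  out$vclass <- vclass_of(out$ref, out$alt)
  out$caller <- caller
  out$flagged <- is.na(out$tumor_alt_reads) | is.na(out$tumor_depth) |
    is.na(out$germline_alt_reads) | is.na(out$germline_depth)
  if (any(out$flagged))
    warning(sprintf("%s: %d record(s) with missing AD/DP flagged (lines %s)",
                    path, sum(out$flagged),
                    paste(out$line[out$flagged], collapse = ",")))
  if (!is.null(ref)) {
    hasN <- vapply(seq_len(nrow(out)), function(i) {
      grepl("N", ref_seq(ref, out$chrom[i], out$pos[i],
                         out$pos[i] + nchar(out$ref[i]) - 1L), fixed = TRUE)
    }, logical(1))
    if (any(hasN)) out <- out[!hasN, , drop = FALSE]
  }
  out$line <- NULL
  rownames(out) <- NULL
  out[, names(empty_calls())]
}

#' Write / read a sites-only panel VCF
#'
#' Germline panel files carry only variant sites (no genotype columns); the
#' panel rules need presence, not read evidence.
#'
#' @param variants Variant table.
#' @param path VCF path.
#' @param sample_id Germline sample identifier, recorded in the header.
#' @return `path` (write) or a variant table (read).
#' @export
write_panel_vcf <- function(variants, path, sample_id) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##germline_sample=%s", sample_id),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    variants$chrom, variants$pos, variants$ref, variants$alt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
read_panel_vcf <- function(path) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(body)) return(variant_table())
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  sample_id <- sub("^##germline_sample=", "",
                   grep("^##germline_sample=", raw, value = TRUE)[1])
  v <- variant_table(f[, 1], as.integer(f[, 2]), f[, 4], f[, 5])
  attr(v, "sample_id") <- sample_id
  v
}

#' Write / read the consolidated variant decision table
#'
#' Fixed-column TSV audit table: `chrom`, `pos`, `ref`, `alt`, `vclass`,
#' `callers` (comma-joined supporting callers), `decision`
#' (`retained`/`rejected`), `failed_rules` (comma-joined, empty when
#' retained). Round-trip stable.
#'
#' @param decisions Filter-decision table from [consolidate()].
#' @param path TSV path.
#' @return `path` (write) or the decision table (read).
#' @export
write_variant_table <- function(decisions, path) {
  out <- data.frame(chrom = decisions$chrom, pos = decisions$pos,
                    ref = decisions$ref, alt = decisions$alt,
                    vclass = decisions$vclass,
                    callers = decisions$callers,
                    decision = ifelse(decisions$retained, "retained", "rejected"),
                    failed_rules = decisions$failed_rules,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer", "character",
                                          "character", "character", "character",
                                          "character", "character"),
                           na.strings = NULL)
  out$retained <- out$decision == "retained"
  out
}
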
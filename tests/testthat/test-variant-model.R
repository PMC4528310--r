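# Variant representation, normalization, keying and I/O round-trips.

test_that("normalization matches exhaustive enumeration of equivalent representations", {
  # oracle: enumerate every (pos, ref, alt) with alleles up to 5 bp that
  # produces the same edited sequence, and demand the minimal, leftmost one
  enumerate_equivalents <- function(seq, pos, ref, alt) {
    target <- apply_variant(seq, pos, ref, alt)
    reps <- list()
    for (p in seq_len(nchar(seq))) {
      for (lr in 1:5) {
        if (p + lr - 1L > nchar(seq)) next
        r <- substr(seq, p, p + lr - 1L)
        for (la in 0:5) {
          alts <- if (la == 0) "" else
            apply(expand.grid(rep(list(c("A", "C", "G", "T")), la)), 1, paste,
                  collapse = "")
          for (a in alts) {
            if (r == a || a == "") next
            if (apply_variant(seq, p, r, a) == target)
              reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
          }
        }
      }
    }
    reps
  }
  minimal_leftmost <- function(reps) {
    sizes <- vapply(reps, function(x) nchar(x$ref) + nchar(x$alt), numeric(1))
    reps <- reps[sizes == min(sizes)]
    reps[[which.min(vapply(reps, `[[`, numeric(1), "pos"))]]
  }

  ctx <- "TTTTCAGAGAGTTT"   # deletion in a CAGAG repeat context
  ref <- make_ref(c1 = ctx)
  v <- variant_table("c1", 5L, "CAG", "CG")
  nv <- normalize_variants(v, ref)
  oracle <- minimal_leftmost(enumerate_equivalents(ctx, 5L, "CAG", "CG"))
  expect_equal(nv$pos, oracle$pos)
  expect_equal(nv$ref, oracle$ref)
  expect_equal(nv$alt, oracle$alt)

  # insertion inside a dinucleotide repeat must left-align to the repeat start
  ctx2 <- "GGATATATATCC"
  ref2 <- make_ref(c1 = ctx2)
  v2 <- variant_table("c1", 9L, "A", "AAT")
  nv2 <- normalize_variants(v2, ref2)
  oracle2 <- minimal_leftmost(enumerate_equivalents(ctx2, 9L, "A", "AAT"))
  expect_equal(nv2$pos, oracle2$pos)
  expect_equal(nv2$ref, oracle2$ref)
  expect_equal(nv2$alt, oracle2$alt)
})

test_that("normalization trims shared suffix and leaves minimal SNVs unchanged", {
  ref <- make_ref(c1 = "AAAACATGGG")
  expect_equal(normalize_variants(variant_table("c1", 5L, "C", "T"), ref),
               variant_table("c1", 5L, "C", "T"))
  # "AT" > "GT" at pos 5? ref at 5..6 is CA; use pos 6: AT>GT
  nv <- normalize_variants(variant_table("c1", 6L, "AT", "GT"), ref)
  expect_equal(nv$pos, 6L)
  expect_equal(nv$ref, "A")
  expect_equal(nv$alt, "G")
  expect_equal(nv$vclass, "snv")
})

test_that("normalization errors on reference mismatch and out-of-range input", {
  ref <- make_ref(c1 = "ACGTACGT")
  expect_error(normalize_variants(variant_table("c1", 2L, "G", "T"), ref),
               "mismatch")
  expect_error(normalize_variants(variant_table("c1", 7L, "GTT", "G"), ref),
               "outside")
  expect_error(normalize_variants(variant_table("c2", 1L, "A", "T"), ref),
               "contig")
})

test_that("normalization is idempotent and preserves the edit", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
  ref <- make_ref(c1 = seq)
  for (i in 1:60) {
    pos <- sample(20:170, 1)
    type <- sample(c("snv", "del", "ins"), 1)
    b <- substr(seq, pos, pos)
    v <- switch(type,
      snv = variant_table("c1", pos, b, sample(setdiff(c("A", "C", "G", "T"), b), 1)),
      del = variant_table("c1", pos, substr(seq, pos, pos + sample(1:4, 1)), b),
      ins = variant_table("c1", pos, b,
                          paste0(b, paste(sample(c("A", "C", "G", "T"),
                                                 sample(1:4, 1), replace = TRUE),
                                          collapse = ""))))
    nv <- normalize_variants(v, ref)
    expect_identical(normalize_variants(nv, ref), nv)
    expect_identical(apply_variant(seq, nv$pos, nv$ref, nv$alt),
                     apply_variant(seq, v$pos, v$ref, v$alt))
  }
})

test_that("variant keys collide only for true duplicates", {
  set.seed(7)
  n <- 1000
  chrom <- sample(c("c1", "c2"), n, TRUE)
  pos <- sample(1:400, n, TRUE)
  refA <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(refA, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  v <- variant_table(chrom, pos, refA, alt)
  keys <- variant_key(v)
  # brute force: rows identical iff all four fields identical
  sig <- paste(v$chrom, v$pos, v$ref, v$alt)
  expect_identical(duplicated(keys), duplicated(sig))
  expect_equal(anyDuplicated(unique(keys)), 0L)
  # same position, different alt -> different key
  a <- variant_table("c1", 10L, "C", "T")
  b <- variant_table("c1", 10L, "C", "G")
  expect_false(variant_key(a) == variant_key(b))
})

test_that("variant_key rejects non-minimal representations", {
  expect_error(variant_key(data.frame(chrom = "c1", pos = 5L, ref = "AT",
                                      alt = "GT", vclass = "snv")),
               "normalized")
  expect_error(variant_key(data.frame(chrom = "c1", pos = 5L, ref = "CCA",
                                      alt = "CCAG", vclass = "indel")),
               "normalized")
})

test_that("caller VCF round-trips, including multi-allelic decomposition", {
  dir <- withr::local_tempdir()
  ref <- make_ref(chr1 = paste(rep("ACGTGATTCA", 20), collapse = ""))
  v <- variant_table(rep("chr1", 5), c(11L, 25L, 40L, 77L, 120L),
                     c("C", "A", "T", "G", "A"), c("T", "G", "A", "C", "T"))
  calls <- caller_calls(v, "mutect", c(10L, 5L, 8L, 30L, 2L), 60L,
                        c(0L, 1L, 0L, 2L, 0L), 50L)
  path <- file.path(dir, "mutect.vcf")
  write_caller_vcf(calls, path, "T1", "N1")
  back <- read_caller_vcf(path)
  expect_equal(back[order(back$pos), ], calls[order(calls$pos), ],
               ignore_attr = TRUE)

  # empty body
  write_caller_vcf(empty <- caller_calls(variant_table(), "varscan", 0L, 0L, 0L, 0L),
                   file.path(dir, "empty.vcf"), "T1", "N1")
  expect_equal(nrow(read_caller_vcf(file.path(dir, "empty.vcf"))), 0L)

  # multi-allelic record: split into one call per alt with per-allele AD
  lines <- c("##fileformat=VCFv4.2", "##caller=varscan",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "TUMOR", "GERMLINE", sep = "\t"),
             "chr1\t11\t.\tC\tT,G\t.\tPASS\t.\tAD:DP\t7,3:40\t0,1:45")
  ma <- file.path(dir, "multi.vcf")
  writeLines(lines, ma)
  got <- read_caller_vcf(ma)
  # manual decomposition of the fixture record
  expect_equal(nrow(got), 2L)
  expect_equal(got$alt, c("T", "G"))
  expect_equal(got$tumor_alt_reads, c(7L, 3L))
  expect_equal(got$germline_alt_reads, c(0L, 1L))
  expect_equal(got$tumor_depth, c(40L, 40L))
})

test_that("records with missing depth fields are flagged, not dropped", {
  dir <- withr::local_tempdir()
  lines <- c("##fileformat=VCFv4.2", "##caller=mutect",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "TUMOR", "GERMLINE", sep = "\t"),
             "chr1\t5\t.\tA\tT\t.\tPASS\t.\tAD:DP\t9:50\t0:44",
             "chr1\t9\t.\tC\tG\t.\tPASS\t.\tAD\t4\t1")
  path <- file.path(dir, "flagged.vcf")
  writeLines(lines, path)
  expect_warning(got <- read_caller_vcf(path), "flagged")
  expect_equal(nrow(got), 2L)
  expect_equal(got$flagged, c(FALSE, TRUE))
})

test_that("variants overlapping N reference bases are rejected at load", {
  dir <- withr::local_tempdir()
  ref <- make_ref(chr1 = "ACGTANGTACGT")
  lines <- c("##fileformat=VCFv4.2", "##caller=mutect",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "TUMOR", "GERMLINE", sep = "\t"),
             "chr1\t2\t.\tC\tA\t.\tPASS\t.\tAD:DP\t9:50\t0:44",
             "chr1\t5\t.\tAN\tA\t.\tPASS\t.\tAD:DP\t9:50\t0:44")
  path <- file.path(dir, "n.vcf")
  writeLines(lines, path)
  got <- read_caller_vcf(path, ref = ref)
  expect_equal(nrow(got), 1L)
  expect_equal(got$pos, 2L)
})

test_that("decision tables round-trip through the TSV audit format", {
  dir <- withr::local_tempdir()
  d <- data.frame(chrom = c("chr1", "chr2"), pos = c(5L, 9L),
                  ref = c("C", "A"), alt = c("T", "AG"),
                  vclass = c("snv", "indel"),
                  callers = c("mutect,varscan", "pindel"),
                  retained = c(TRUE, FALSE),
                  failed_rules = c("", "evidence,pop_freq"),
                  stringsAsFactors = FALSE)
  path <- file.path(dir, "decisions.tsv")
  write_variant_table(d, path)
  back <- read_variant_table(path)
  expect_equal(back[, c("chrom", "pos", "ref", "alt", "vclass", "callers",
                        "failed_rules", "retained")],
               d[, c("chrom", "pos", "ref", "alt", "vclass", "callers",
                     "failed_rules", "retained")])
  # second round trip is the identity
  write_variant_table(back, path)
  expect_identical(read_variant_table(path), back)
})
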
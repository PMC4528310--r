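#' Simulation configuration for the synthetic tumor/normal cohort
#'
#' The simulator emulates the study conditions of a small exome cohort of
#' mucinous ovarian tumors: three histology groups (benign, borderline,
#' carcinoma), a C>T-at-CpG-weighted somatic substitution signature, germline
#' SNPs/indels shared across a cohort panel, population allele frequencies,
#' and seven callers with caller-specific sensitivity and false-positive
#' behavior. The synthetic CDS is miniature (~0.05 Mb) and serves as the
#' positional canvas; the nominal callable territory (`territory_mb`,
#' per histology, emulating heterogeneous capture designs) is what burdens
#' are defined against, so default per-tumor mutation counts and per-Mb
#' rates both match a real exome cohort. See the methods vignette.
#'
#' @param seed Integer RNG seed; fixes all outputs bit-for-bit.
#' @param n_contigs,contig_length Reference shape.
#' @param gc_fraction Base composition (fraction G+C).
#' @param n_genes,exons_per_gene,exon_length,intron_length Gene-model shape.
#' @param n_pairs Named integer vector: tumor/normal pairs per histology
#'   group (`benign`, `borderline`, `carcinoma`).
#' @param somatic_burden_per_mb Named numeric: true coding somatic mutation
#'   rate per callable megabase, per histology group.
#' @param cpg_ct_weight Multiplier (>= 1) for C>T substitutions at CpG sites
#'   relative to all other (site, alt) choices; 1 = uniform opportunity.
#' @param indel_fraction Fraction of somatic events that are indels.
#' @param germline_snp_rate Per-bp probability of a germline polymorphic
#'   locus in the cohort.
#' @param germline_indel_fraction Fraction of germline loci that are indels.
#' @param common_fraction Fraction of germline loci that are population-
#'   common (MAF > 5 %); the rest are rare or private.
#' @param artifact_fraction Fraction of germline loci that emulate recurrent
#'   artifacts: absent from the population table but carried by many cohort
#'   germlines (exercises the panel rules).
#' @param germline_share_prob Per-pair carrier probability for common and
#'   artifact loci.
#' @param mean_depth,depth_dispersion Negative-binomial read-depth model
#'   (mean and size).
#' @param tumor_vaf_mean Expected somatic variant allele fraction in tumor.
#' @param germline_noise Per-read probability of the somatic alt allele
#'   appearing in the matched germline (sequencing noise / contamination).
#' @param territory_mb Nominal callable territory in Mb: a scalar, or a
#'   numeric named by histology group (heterogeneous capture designs). The
#'   expected somatic count per pair is `somatic_burden_per_mb *
#'   territory_mb` for its group.
#' @return A classed list (`sim_config`).
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L, contig_length = 200000L,
                       gc_fraction = 0.41,
                       n_genes = 90L, exons_per_gene = 4L, exon_length = 150L,
                       intron_length = 120L,
                       n_pairs = c(benign = 5L, borderline = 8L, carcinoma = 11L),
                       somatic_burden_per_mb = c(benign = 0.8, borderline = 0.9,
                                                 carcinoma = 1.5),
                       cpg_ct_weight = 8,
                       indel_fraction = 0.08,
                       germline_snp_rate = 0.0008,
                       germline_indel_fraction = 0.1,
                       common_fraction = 0.5,
                       artifact_fraction = 0.05,
                       germline_share_prob = 0.3,
                       mean_depth = 140, depth_dispersion = 25,
                       tumor_vaf_mean = 0.3,
                       germline_noise = 0.005,
                       territory_mb = c(benign = 31.75, borderline = 36.6,
                                        carcinoma = 44.6)) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              n_pairs = n_pairs, somatic_burden_per_mb = somatic_burden_per_mb,
              cpg_ct_weight = cpg_ct_weight, indel_fraction = indel_fraction,
              germline_snp_rate = germline_snp_rate,
              germline_indel_fraction = germline_indel_fraction,
              common_fraction = common_fraction,
              artifact_fraction = artifact_fraction,
              germline_share_prob = germline_share_prob,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              tumor_vaf_mean = tumor_vaf_mean,
              germline_noise = germline_noise,
              territory_mb = territory_mb)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  groups <- c("benign", "borderline", "carcinoma")
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$n_contigs < 1L || cfg$contig_length < 1L)
    stop("reference dimensions must be positive")
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1)
    stop("gc_fraction must be in [0,1]")
  if (!all(groups %in% names(cfg$n_pairs)))
    stop("n_pairs must be named benign/borderline/carcinoma")
  if (!all(groups %in% names(cfg$somatic_burden_per_mb)))
    stop("somatic_burden_per_mb must be named benign/borderline/carcinoma")
  if (cfg$cpg_ct_weight < 1) stop("cpg_ct_weight must be >= 1")
  fr <- c(cfg$indel_fraction, cfg$germline_indel_fraction,
          cfg$common_fraction, cfg$artifact_fraction,
          cfg$germline_share_prob, cfg$tumor_vaf_mean, cfg$germline_noise)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (any(cfg$somatic_burden_per_mb < 0) || cfg$germline_snp_rate < 0 ||
      cfg$mean_depth <= 0 || cfg$depth_dispersion <= 0)
    stop("rates must be nonnegative, depth model positive")
  if (any(cfg$territory_mb <= 0)) stop("territory_mb must be positive")
  if (length(cfg$territory_mb) > 1L && !all(groups %in% names(cfg$territory_mb)))
    stop("territory_mb must be a scalar or named benign/borderline/carcinoma")
  invisible(TRUE)
}

#' Default caller profiles for the seven emulated callers
#'
#' Encodes which variant classes each caller handles (three SNV-only
#' callers, one indel-only, one both; plus two callers that genotype tumor
#' and germline separately and therefore also emit germline variants),
#' detection sensitivities and genome-wide false-positive rates.
#'
#' @param sens_snv,sens_indel,fp_per_mb Optional named numeric overrides,
#'   names from [caller_names()].
#' @return A `data.frame`, one row per caller.
#' @export
caller_profiles <- function(sens_snv = NULL, sens_indel = NULL,
                            fp_per_mb = NULL) {
  p <- data.frame(
    caller = CALLERS,
    handles_snv = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    handles_indel = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    sens_snv = c(0.95, 0.90, 0.85, 0.90, 0, 0, 0.85),
    sens_indel = c(0, 0, 0, 0.80, 0.85, 0.80, 0.75),
    fp_per_mb = c(3, 5, 6, 4, 3, 4, 5),
    calls_germline_separately = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  override <- function(col, v) {
    if (!is.null(v)) {
      i <- match(names(v), p$caller)
      if (anyNA(i)) stop("unknown caller in override")
      p[i, col] <- unname(v)
    }
    p
  }
  p <- override("sens_snv", sens_snv)
  p <- override("sens_indel", sens_indel)
  p <- override("fp_per_mb", fp_per_mb)
  p$sens_snv[!p$handles_snv] <- 0
  p$sens_indel[!p$handles_indel] <- 0
  p
}

#' Generate a synthetic reference genome
#'
#' i.i.d. bases with P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg [sim_config()].
#' @return Named `DNAStringSet` with contigs `chr1..chrN`.
#' @export
generate_reference <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$contig_length <= 0L) stop("contig_length must be positive")
  set.seed(cfg$seed)
  gc <- cfg$gc_fraction
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(cfg$n_contigs), function(i) {
    paste(sample(names(prob), cfg$contig_length, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0("chr", seq_len(cfg$n_contigs))
  ref
}

#' Generate synthetic gene models
#'
#' Genes are tiled deterministically across contigs, alternating strand,
#' with fixed exon and intron lengths. The CDS spans the exon chain, trimmed
#' at the 3' end so its length is divisible by 3.
#'
#' @param cfg [sim_config()].
#' @param ref Reference genome.
#' @return List of `gene_model` objects with attribute `territory_mb`.
#' @export
generate_gene_models <- function(cfg, ref) {
  validate_sim_config(cfg)
  gene_span <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  gap <- max(200L, cfg$intron_length)
  per_contig_cap <- (Biostrings::width(ref) - gap) %/% (gene_span + gap)
  if (sum(pmax(per_contig_cap, 0L)) < cfg$n_genes)
    stop(sprintf("cannot place %d genes of span %d bp on the given contigs",
                 cfg$n_genes, gene_span))
  genes <- vector("list", cfg$n_genes)
  gi <- 0L
  for (ci in seq_along(ref)) {
    n_here <- min(per_contig_cap[ci], cfg$n_genes - gi)
    if (n_here <= 0L) next
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      start <- gap + (k - 1L) * (gene_span + gap) + 1L
      ex_start <- start + (seq_len(cfg$exons_per_gene) - 1L) *
        (cfg$exon_length + cfg$intron_length)
      exons <- cbind(ex_start, ex_start + cfg$exon_length - 1L)
      cds_len <- cfg$exons_per_gene * cfg$exon_length
      trim <- cds_len %% 3L
      cds_end <- max(exons) - trim  # trim stays inside the last exon
      genes[[gi]] <- gene_model(sprintf("gene%03d", gi), names(ref)[ci],
                                if (gi %% 2L) "+" else "-",
                                exons, min(exons), cds_end)
      if (gi == cfg$n_genes) break
    }
  }
  attr(genes, "territory_mb") <- cds_territory_mb(genes)
  genes
}

## precompute per-(CDS site, alt) sampling weights for the somatic SNV model
snv_opportunity <- function(cfg, ref, genes) {
  pos_by_contig <- list()
  for (g in genes) {
    p <- cds_positions(g)
    pos_by_contig[[g$chrom]] <- c(pos_by_contig[[g$chrom]], p)
  }
  tab <- do.call(rbind, lapply(names(pos_by_contig), function(chrom) {
    pos <- sort(unique(pos_by_contig[[chrom]]))
    data.frame(chrom = chrom, pos = pos,
               base = unlist(strsplit(ref_seq(ref, chrom, min(pos), max(pos)),
                                      ""))[pos - min(pos) + 1L],
               stringsAsFactors = FALSE)
  }))
  len <- contig_lengths(ref)
  nxt <- ifelse(tab$pos < len[tab$chrom],
                substr(as.character(ref)[tab$chrom], tab$pos + 1L, tab$pos + 1L), "")
  prv <- ifelse(tab$pos > 1L,
                substr(as.character(ref)[tab$chrom], tab$pos - 1L, tab$pos - 1L), "")
  ## expand to one row per (site, alt)
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  idx <- rep(seq_len(nrow(tab)), each = 3L)
  out <- tab[idx, , drop = FALSE]
  out$alt <- unlist(alts[tab$base], use.names = FALSE)
  out$nxt <- nxt[idx]
  out$prv <- prv[idx]
  ## C>T at CpG in pyrimidine orientation: C>T with 3' G, or G>A with 5' C
  out$cpg_ct <- (out$base == "C" & out$alt == "T" & out$nxt == "G") |
    (out$base == "G" & out$alt == "A" & out$prv == "C")
  out$weight <- ifelse(out$cpg_ct, cfg$cpg_ct_weight, 1)
  rownames(out) <- NULL
  out
}

#' Simulate the cohort truth set
#'
#' Per pair, the somatic coding mutation count is Poisson with mean
#' `burden_per_mb[histology] * territory_mb`. Substitutions are drawn over
#' all (CDS site, alt) pairs with C>T-at-CpG events up-weighted by
#' `cpg_ct_weight`; a configured fraction of events are small coding indels.
#' Germline loci are placed genome-wide and shared across pairs (common /
#' rare / private / artifact-like categories) with population MAFs.
#'
#' @param cfg [sim_config()].
#' @param ref Reference genome.
#' @param genes Gene models.
#' @return A list of class `"truth_set"`: `variants` (per-pair truth table),
#'   `pairs` (metadata), `pop_freq`, `external_counts`, `territory_mb`.
#' @export
simulate_truth <- function(cfg, ref, genes) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  territory_for <- function(g) {
    if (length(cfg$territory_mb) == 1L) unname(cfg$territory_mb)
    else cfg$territory_mb[[g]]
  }
  groups <- c("benign", "borderline", "carcinoma")
  pairs <- do.call(rbind, lapply(groups, function(g) {
    n <- cfg$n_pairs[[g]]
    if (n == 0L) return(NULL)
    data.frame(tumor_id = sprintf("%s%02d_T", toupper(substr(g, 1, 3)), seq_len(n)),
               germline_id = sprintf("%s%02d_N", toupper(substr(g, 1, 3)), seq_len(n)),
               histology = g, territory_mb = territory_for(g),
               stringsAsFactors = FALSE)
  }))
  opp <- snv_opportunity(cfg, ref, genes)
  glen <- contig_lengths(ref)

  ## --- cohort-level germline loci -----------------------------------------
  n_loci <- stats::rpois(1, cfg$germline_snp_rate * sum(glen))
  gl <- NULL
  if (n_loci > 0) {
    gpos <- sample.int(sum(glen), n_loci)
    cum <- cumsum(glen)
    chrom_i <- findInterval(gpos - 1L, c(0L, cum[-length(cum)]))
    chrom <- names(glen)[chrom_i]
    pos <- gpos - c(0L, cum)[chrom_i]
    pos <- pmin(pmax(pos, 2L), glen[chrom] - 7L)  # room for indel alleles
    base <- vapply(seq_len(n_loci), function(i) ref_seq(ref, chrom[i], pos[i]),
                   character(1))
    is_indel <- stats::runif(n_loci) < cfg$germline_indel_fraction
    refA <- base; altA <- base
    for (i in seq_len(n_loci)) {
      if (!is_indel[i]) {
        altA[i] <- sample(setdiff(c("A", "C", "G", "T"), base[i]), 1)
      } else if (stats::runif(1) < 0.5) {  # deletion of 1-3 bp
        L <- sample(1:3, 1)
        refA[i] <- ref_seq(ref, chrom[i], pos[i], pos[i] + L)
      } else {                             # insertion of 1-3 bp
        L <- sample(1:3, 1)
        altA[i] <- paste0(base[i], paste(sample(c("A", "C", "G", "T"), L,
                                                replace = TRUE), collapse = ""))
      }
    }
    u <- stats::runif(n_loci)
    category <- ifelse(u < cfg$artifact_fraction, "artifact",
                ifelse(u < cfg$artifact_fraction + cfg$common_fraction,
                       "common", "rare"))
    maf <- numeric(n_loci)
    maf[category == "common"] <- stats::runif(sum(category == "common"), 0.06, 0.5)
    maf[category == "rare"] <- stats::runif(sum(category == "rare"), 0, 0.04)
    maf[category == "artifact"] <- 0
    carry_p <- ifelse(category == "rare",
                      pmax(2 * maf * (1 - maf) + maf^2, 0.04),
                      cfg$germline_share_prob)
    gl <- data.frame(chrom = chrom, pos = as.integer(pos), ref = refA,
                     alt = altA, category = category, maf = maf,
                     carry_p = carry_p, stringsAsFactors = FALSE)
    gl <- normalize_variants(variant_table(gl$chrom, gl$pos, gl$ref, gl$alt),
                             ref) |> cbind(gl[c("category", "maf", "carry_p")])
    gl <- gl[!duplicated(variant_key(gl)), , drop = FALSE]
  }

  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    hist <- pairs$histology[pi]
    ## germline carriers for this pair
    g_keys <- character(0)
    if (!is.null(gl) && nrow(gl)) {
      carried <- stats::runif(nrow(gl)) < gl$carry_p
      if (any(carried)) {
        gsub_ <- gl[carried, , drop = FALSE]
        hom <- stats::runif(nrow(gsub_)) < 0.2
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_id = pairs$tumor_id[pi], chrom = gsub_$chrom, pos = gsub_$pos,
          ref = gsub_$ref, alt = gsub_$alt, vclass = gsub_$vclass,
          origin = "germline", true_tumor_vaf = ifelse(hom, 1, 0.5),
          true_germline_vaf = ifelse(hom, 1, 0.5),
          in_coding = FALSE, pop_maf = gsub_$maf, stringsAsFactors = FALSE)
        g_keys <- variant_key(gsub_)
      }
    }
    ## somatic events
    n_som <- stats::rpois(1, cfg$somatic_burden_per_mb[[hist]] * pairs$territory_mb[pi])
    n_ind <- stats::rbinom(1, n_som, cfg$indel_fraction)
    n_snv <- n_som - n_ind
    som <- NULL
    if (n_snv > 0) {
      pick <- sample.int(nrow(opp), min(n_snv, nrow(opp)), prob = opp$weight)
      som <- opp[pick, c("chrom", "pos", "base", "alt"), drop = FALSE]
      names(som)[3] <- "ref"
    }
    if (n_ind > 0) {
      ind <- simulate_coding_indels(n_ind, ref, genes)
      som <- rbind(som, ind)
    }
    if (!is.null(som) && nrow(som)) {
      som <- normalize_variants(variant_table(som$chrom, som$pos, som$ref, som$alt),
                                ref)
      keys <- variant_key(som)
      keep <- !duplicated(keys) & !(keys %in% g_keys)
      som <- som[keep, , drop = FALSE]
      vaf <- stats::rbeta(nrow(som), cfg$tumor_vaf_mean * 10,
                          (1 - cfg$tumor_vaf_mean) * 10)
      rows[[length(rows) + 1L]] <- data.frame(
        tumor_id = pairs$tumor_id[pi], som[c("chrom", "pos", "ref", "alt", "vclass")],
        origin = "somatic", true_tumor_vaf = round(vaf, 4),
        true_germline_vaf = 0, in_coding = TRUE, pop_maf = 0,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL

  ## population-frequency table and external-panel carrier counts
  pop_freq <- external <- NULL
  if (!is.null(gl) && nrow(gl)) {
    key <- variant_key(gl)
    pop_freq <- data.frame(key = key[gl$maf > 0], maf = gl$maf[gl$maf > 0],
                           stringsAsFactors = FALSE)
    ext_p <- ifelse(gl$category == "artifact", cfg$germline_share_prob,
                    pmin(2 * gl$maf * (1 - gl$maf) + gl$maf^2, 1))
    external <- data.frame(key = key,
                           carriers = stats::rbinom(nrow(gl), 147L, ext_p),
                           stringsAsFactors = FALSE)
    external <- external[external$carriers > 0, , drop = FALSE]
  }
  if (is.null(pop_freq))
    pop_freq <- data.frame(key = character(), maf = numeric())
  if (is.null(external))
    external <- data.frame(key = character(), carriers = integer())

  structure(list(variants = variants, pairs = pairs, pop_freq = pop_freq,
                 external_counts = external, territory_mb = cfg$territory_mb),
            class = "truth_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## small 1-3 bp coding indels fully inside one exon's CDS
simulate_coding_indels <- function(n, ref, genes) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[[sample.int(length(genes), 1)]]
    cds <- cds_positions(g)
    L <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    del <- stats::runif(1) < 0.5
    if (del) {
      ## anchor..anchor+L must stay within one contiguous CDS run
      runs <- split(cds, cumsum(c(1, diff(cds) != 1)))
      cand <- unlist(lapply(runs, function(r) if (length(r) > L) utils::head(r, -L) else integer(0)))
      if (!length(cand)) next
      pos <- sample(cand, 1)
      out[[i]] <- data.frame(chrom = g$chrom, pos = pos,
                             ref = ref_seq(ref, g$chrom, pos, pos + L),
                             alt = ref_seq(ref, g$chrom, pos),
                             stringsAsFactors = FALSE)
    } else {
      pos <- sample(cds[-length(cds)], 1)
      ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      out[[i]] <- data.frame(chrom = g$chrom, pos = pos,
                             ref = ref_seq(ref, g$chrom, pos),
                             alt = paste0(ref_seq(ref, g$chrom, pos), ins),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Emulate per-caller call sets from a truth set
#'
#' Each caller detects compatible true variants with its configured
#' sensitivity; callers that genotype tumor and germline separately
#' (pindel, unifiedgenotyper) also emit the pair's germline variants.
#' False positives are placed uniformly genome-wide at `fp_per_mb`.
#' Read depths are negative-binomial; alt reads binomial at the true VAF
#' (with low-level noise in the germline at somatic sites). Deterministic
#' under `cfg$seed`.
#'
#' @param truth `truth_set` from [simulate_truth()].
#' @param profiles Caller profile table ([caller_profiles()]); must cover
#'   all seven callers.
#' @param cfg [sim_config()].
#' @param ref Reference genome.
#' @return Named list per tumor_id: list of per-caller call tables
#'   (`callsets`) and the pair's germline variant table (`germline`).
#' @export
emulate_calls <- function(truth, profiles, cfg, ref) {
  if (!all(CALLERS %in% profiles$caller))
    stop("profiles must cover all callers: ",
         paste(setdiff(CALLERS, profiles$caller), collapse = ", "))
  set.seed(cfg$seed + 2L)
  glen <- contig_lengths(ref)
  genome_mb <- sum(glen) / 1e6
  out <- list()
  for (pi in seq_len(nrow(truth$pairs))) {
    tid <- truth$pairs$tumor_id[pi]
    tv <- truth$variants[truth$variants$tumor_id == tid, , drop = FALSE]
    ## one set of underlying read counts per variant per pair (same "BAM")
    n <- nrow(tv)
    t_dp <- stats::rnbinom(n, mu = cfg$mean_depth, size = cfg$depth_dispersion)
    g_dp <- stats::rnbinom(n, mu = cfg$mean_depth, size = cfg$depth_dispersion)
    g_vaf <- ifelse(tv$origin == "somatic", cfg$germline_noise,
                    tv$true_germline_vaf)
    t_alt <- stats::rbinom(n, t_dp, tv$true_tumor_vaf)
    g_alt <- stats::rbinom(n, g_dp, g_vaf)
    callsets <- list()
    for (ci in seq_len(nrow(profiles))) {
      p <- profiles[ci, ]
      eligible <- if (p$calls_germline_separately) rep(TRUE, n)
                  else tv$origin == "somatic"
      sens <- ifelse(tv$vclass == "snv", p$sens_snv, p$sens_indel)
      detected <- eligible & stats::runif(n) < sens
      calls <- if (any(detected)) {
        caller_calls(tv[detected, c("chrom", "pos", "ref", "alt", "vclass")],
                     p$caller, t_alt[detected], t_dp[detected],
                     g_alt[detected], g_dp[detected])
      } else empty_calls()
      ## false positives, caller-private, uniform over the genome
      n_fp <- stats::rpois(1, p$fp_per_mb * genome_mb)
      if (n_fp > 0) {
        fp <- random_false_positives(n_fp, ref, p, cfg)
        calls <- rbind(calls, fp)
      }
      calls <- calls[!duplicated(sprintf("%s:%d:%s>%s", calls$chrom, calls$pos,
                                         calls$ref, calls$alt)), , drop = FALSE]
      callsets[[p$caller]] <- calls
    }
    germ <- tv[tv$origin == "germline",
               c("chrom", "pos", "ref", "alt", "vclass"), drop = FALSE]
    out[[tid]] <- list(callsets = callsets, germline = germ)
  }
  out
}

random_false_positives <- function(n_fp, ref, profile, cfg) {
  glen <- contig_lengths(ref)
  chrom <- sample(names(glen), n_fp, replace = TRUE, prob = glen / sum(glen))
  pos <- vapply(chrom, function(ch) sample.int(glen[[ch]] - 6L, 1) + 1L,
                integer(1))
  want_snv <- if (profile$handles_snv && profile$handles_indel)
    stats::runif(n_fp) < 0.85 else rep(profile$handles_snv, n_fp)
  refA <- altA <- character(n_fp)
  for (i in seq_len(n_fp)) {
    b <- ref_seq(ref, chrom[i], pos[i])
    if (want_snv[i]) {
      refA[i] <- b
      altA[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    } else if (stats::runif(1) < 0.5) {
      refA[i] <- ref_seq(ref, chrom[i], pos[i], pos[i] + sample(1:2, 1))
      altA[i] <- b
    } else {
      refA[i] <- b
      altA[i] <- paste0(b, paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                                        replace = TRUE), collapse = ""))
    }
  }
  v <- normalize_variants(variant_table(chrom, pos, refA, altA), ref)
  t_dp <- stats::rnbinom(n_fp, mu = cfg$mean_depth, size = cfg$depth_dispersion)
  g_dp <- stats::rnbinom(n_fp, mu = cfg$mean_depth, size = cfg$depth_dispersion)
  fp_vaf <- stats::rbeta(n_fp, 1.5, 10)
  caller_calls(v, profile$caller,
               stats::rbinom(n_fp, t_dp, fp_vaf), t_dp,
               stats::rbinom(n_fp, g_dp, 0.01), g_dp)
}

#' Write a complete synthetic cohort to a directory
#'
#' Produces `reference.fa`, `genes.gff3`, `metadata.tsv`, `popfreq.tsv`,
#' `external_panel.tsv`, `truth.tsv`, `config.yaml`, per-pair per-caller
#' VCFs under `pairs/<tumor_id>/<caller>.vcf` and cohort germline panel
#' VCFs under `panel/<germline_id>.vcf`. Byte-identical for identical
#' configurations.
#'
#' @param cfg [sim_config()].
#' @param dir Output directory (created).
#' @param profiles Caller profiles; default [caller_profiles()].
#' @return Invisibly, a list with `truth`, `ref`, `genes`, `profiles`, `dir`.
#' @export
simulate_cohort <- function(cfg, dir, profiles = caller_profiles()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(cfg)
  genes <- generate_gene_models(cfg, ref)
  truth <- simulate_truth(cfg, ref, genes)
  calls <- emulate_calls(truth, profiles, cfg, ref)

  write_reference(ref, file.path(dir, "reference.fa"))
  write_gene_models(genes, file.path(dir, "genes.gff3"))
  utils::write.table(truth$pairs, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$pop_freq, file.path(dir, "popfreq.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$external_counts, file.path(dir, "external_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$variants, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))

  dir.create(file.path(dir, "panel"), showWarnings = FALSE)
  for (pi in seq_len(nrow(truth$pairs))) {
    tid <- truth$pairs$tumor_id[pi]
    gid <- truth$pairs$germline_id[pi]
    pdir <- file.path(dir, "pairs", tid)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (cl in names(calls[[tid]]$callsets))
      write_caller_vcf(calls[[tid]]$callsets[[cl]],
                       file.path(pdir, paste0(cl, ".vcf")),
                       tumor_id = tid, germline_id = gid)
    write_panel_vcf(calls[[tid]]$germline, file.path(dir, "panel",
                                                     paste0(gid, ".vcf")), gid)
  }
  invisible(list(truth = truth, ref = ref, genes = genes,
                 profiles = profiles, dir = dir))
}
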
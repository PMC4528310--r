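#' Pipeline configuration
#'
#' @param cohort_dir Directory holding a cohort as written by
#'   [simulate_cohort()] (`reference.fa`, `genes.gff3`, `metadata.tsv`,
#'   `popfreq.tsv`, `external_panel.tsv`, `pairs/`, `panel/`; `truth.tsv`
#'   optional).
#' @param output_dir Where result tables are written.
#' @param seed Integer seed (used by the `simulate` stage).
#' @param simulate Logical: generate the cohort into `cohort_dir` first.
#' @param sim [sim_config()] for the simulate stage.
#' @param filter [filter_config()].
#' @return Classed list (`pipeline_config`).
#' @export
pipeline_config <- function(cohort_dir, output_dir, seed = 1L,
                            simulate = FALSE, sim = NULL, filter = NULL) {
  structure(list(cohort_dir = cohort_dir, output_dir = output_dir,
                 seed = as.integer(seed), simulate = simulate,
                 sim = sim %||% sim_config(seed = seed),
                 filter = filter %||% filter_config()),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys `cohort_dir`, `output_dir`,
#'   `seed`, `simulate`, and optional `sim` / `filter` blocks overriding
#'   [sim_config()] / [filter_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("cohort_dir", "output_dir"))
    if (is.null(y[[f]])) stop("config missing required field: ", f)
  sim <- do.call(sim_config, c(list(seed = y$seed %||% 1L), y$sim))
  filter <- do.call(filter_config, y$filter %||% list())
  pipeline_config(y$cohort_dir, y$output_dir, seed = y$seed %||% 1L,
                  simulate = isTRUE(y$simulate), sim = sim, filter = filter)
}

#' Load a cohort directory
#'
#' @param dir Cohort directory (layout of [simulate_cohort()]).
#' @return List: `ref`, `genes`, `metadata`, `pop_freq` / `external_counts`
#'   (named vectors), `panel` (germline variant tables), `callsets`
#'   (per tumor_id, per caller), `truth` (or `NULL`).
#' @export
load_cohort <- function(dir) {
  need <- c("reference.fa", "genes.gff3", "metadata.tsv", "popfreq.tsv",
            "external_panel.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("cohort dir missing: ", paste(missing, collapse = ", "))
  ref <- read_reference(file.path(dir, "reference.fa"))
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  metadata <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  pf <- utils::read.table(file.path(dir, "popfreq.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  pop_freq <- stats::setNames(pf$maf, pf$key)
  ec <- utils::read.table(file.path(dir, "external_panel.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  external_counts <- stats::setNames(as.integer(ec$carriers), ec$key)
  panel_files <- list.files(file.path(dir, "panel"), pattern = "\\.vcf$",
                            full.names = TRUE)
  panel <- lapply(panel_files, read_panel_vcf)
  names(panel) <- vapply(panel, attr, character(1), "sample_id")
  callsets <- list()
  for (tid in metadata$tumor_id) {
    pdir <- file.path(dir, "pairs", tid)
    files <- list.files(pdir, pattern = "\\.vcf$", full.names = TRUE)
    cs <- lapply(files, read_caller_vcf, ref = ref)
    names(cs) <- vapply(cs, function(x)
      if (nrow(x)) x$caller[1] else sub("\\.vcf$", "", basename(files[1])),
      character(1))
    names(cs) <- sub("\\.vcf$", "", basename(files))
    callsets[[tid]] <- cs
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv"))) {
    tv <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    truth <- structure(list(variants = tv, pairs = metadata,
                            pop_freq = pf, external_counts = ec,
                            territory_mb = metadata$territory_mb[1]),
                       class = "truth_set")
  }
  list(ref = ref, genes = genes, metadata = metadata, pop_freq = pop_freq,
       external_counts = external_counts, panel = panel, callsets = callsets,
       truth = truth)
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate -> consolidate -> annotate -> spectrum ->
#' stats -> report. Writes `decisions.tsv`, `consequences.tsv`,
#' `spectrum.tsv`, `contexts.tsv`, `burden.tsv`, `recurrence.tsv`,
#' `stats.json`, `report.md` and `manifest.json` (seed, config, md5 of
#' every output) into `output_dir`. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  if (!cfg$simulate && !dir.exists(cfg$cohort_dir))
    stop("configuration error: cohort_dir does not exist: ", cfg$cohort_dir)

  stage <- function(name, expr) {
    message(sprintf("[%s] start", name))
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if (cfg$simulate)
    stage("simulate", simulate_cohort(cfg$sim, cfg$cohort_dir))
  cohort <- stage("load", load_cohort(cfg$cohort_dir))
  md <- cohort$metadata

  decisions <- stage("consolidate", {
    res <- lapply(seq_len(nrow(md)), function(i) {
      pc <- panel_counts(cohort$panel, exclude = md$germline_id[i])
      d <- consolidate(cohort$callsets[[md$tumor_id[i]]], pc,
                       cohort$external_counts, cohort$pop_freq,
                       cohort$genes, cohort$ref, cfg$filter)
      if (nrow(d)) d$tumor_id <- md$tumor_id[i]
      d
    })
    do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
  })
  retained <- decisions[decisions$retained, , drop = FALSE]

  consequences <- stage("annotate", {
    cs <- consequence_summary(retained$consequence)
    attr(cs, "by_sample") <- table(retained$tumor_id, retained$consequence)
    cs
  })

  spectra <- stage("spectrum", {
    per_sample <- lapply(split(retained, retained$tumor_id),
                         spectrum_profile, ref = cohort$ref)
    overall <- spectrum_profile(retained, cohort$ref)
    list(per_sample = per_sample, overall = overall)
  })

  burden <- stage("burden", {
    counts <- table(factor(retained$tumor_id, levels = md$tumor_id))
    mutation_burden(as.integer(counts), md$territory_mb,
                    sample_id = md$tumor_id, histology = md$histology)
  })

  statsres <- stage("stats", {
    pa <- retained[retained$consequence %in% PROTEIN_ALTERING, , drop = FALSE]
    rec <- recurrence_table(
      data.frame(tumor_id = pa$tumor_id, gene_id = pa$gene_id,
                 stringsAsFactors = FALSE), md)
    tests <- group_tests(burden, rec, md)
    evalres <- if (!is.null(cohort$truth))
      evaluate_against_truth(decisions, cohort$truth) else NULL
    list(recurrence = rec, tests = tests, evaluation = evalres)
  })

  outputs <- stage("write", {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_outputs(cfg, decisions, consequences, spectra, burden, statsres, md)
  })

  invisible(list(decisions = decisions, consequences = consequences,
                 spectra = spectra, burden = burden, stats = statsres,
                 outputs = outputs, cohort = cohort))
}

## burden comparisons between histology groups and a recurrence test for the
## most-mutated gene (carcinoma vs rest), mirroring the cohort analyses
group_tests <- function(burden, rec, md) {
  tests <- list()
  groups <- split(burden$mutations_per_mb, burden$histology)
  combs <- utils::combn(names(groups), 2, simplify = FALSE)
  for (cmb in combs) {
    rs <- rank_sum(groups[[cmb[1]]], groups[[cmb[2]]])
    tests[[paste0("burden_", cmb[1], "_vs_", cmb[2])]] <-
      list(test = rs$test, statistic = rs$statistic, p_value = rs$p_value)
  }
  if (nrow(rec) && all(c("mutated_carcinoma", "tested_carcinoma") %in% names(rec))) {
    top <- rec[1, ]
    in_c <- c(top$mutated_carcinoma, top$tested_carcinoma - top$mutated_carcinoma)
    out_m <- top$mutated_discovery - top$mutated_carcinoma
    out_t <- top$tested_discovery - top$tested_carcinoma
    if (all(is.finite(c(in_c, out_m, out_t))) && out_t > 0 && sum(in_c) > 0) {
      tab <- rbind(carcinoma = in_c, other = c(out_m, out_t - out_m))
      fe <- fisher_exact_2x2(tab)
      tests[[paste0("recurrence_", top$gene_id, "_carcinoma_vs_other")]] <-
        list(test = fe$test, table = as.vector(tab), statistic = fe$statistic,
             p_value = fe$p_value)
    }
  }
  tests
}

write_outputs <- function(cfg, decisions, consequences, spectra, burden,
                          statsres, md) {
  out <- character(0)
  p <- function(f) file.path(cfg$output_dir, f)
  write_variant_table(decisions, p("decisions.tsv")); out <- c(out, "decisions.tsv")
  utils::write.table(consequences, p("consequences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- c(out, "consequences.tsv")

  ids <- names(spectra$per_sample)
  six <- matrix(0L, length(ids), 6, dimnames = list(ids, SIX_CLASSES))
  ctx <- matrix(0L, length(ids), 96, dimnames = list(ids, all_context_classes()))
  for (id in ids) {
    six[id, ] <- spectra$per_sample[[id]]$six_class_counts
    ctx[id, ] <- spectra$per_sample[[id]]$context_counts
  }
  spec_tab <- data.frame(sample_id = ids, six,
                         n_substitutions = vapply(spectra$per_sample,
                                                  `[[`, integer(1), "n_substitutions"),
                         ct_at_cpg = vapply(spectra$per_sample,
                                            `[[`, integer(1), "ct_at_cpg"),
                         check.names = FALSE, row.names = NULL)
  utils::write.table(spec_tab, p("spectrum.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(out, "spectrum.tsv")
  utils::write.table(data.frame(sample_id = ids, ctx, check.names = FALSE,
                                row.names = NULL),
                     p("contexts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(out, "contexts.tsv")

  utils::write.table(burden, p("burden.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(out, "burden.tsv")
  utils::write.table(statsres$recurrence, p("recurrence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- c(out, "recurrence.tsv")
  jsonlite::write_json(statsres$tests, p("stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- c(out, "stats.json")

  report <- render_report(list(decisions = decisions,
                               consequences = consequences,
                               spectra = spectra, burden = burden,
                               stats = statsres))
  writeLines(report, p("report.md"))
  out <- c(out, "report.md")

  manifest <- list(package = "somaticsieve",
                   version = as.character(utils::packageVersion("somaticsieve")),
                   seed = cfg$seed,
                   filter = unclass(cfg$filter),
                   sim = if (cfg$simulate) unclass(cfg$sim) else NULL,
                   md5 = as.list(tools::md5sum(file.path(cfg$output_dir, out))))
  names(manifest$md5) <- out
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  c(out, "manifest.json")
}

#' Render a text landscape report
#'
#' Markdown summary: per-group burden, six-class substitution fractions,
#' the NpCpG C>T fraction, top recurrent genes, the filter-cascade funnel
#' (first-failure counts; candidates = retained + sum of first failures)
#' and, when truth is available, pipeline sensitivity/precision.
#'
#' @param outputs List with `decisions`, `consequences`, `spectra`,
#'   `burden`, `stats` as assembled by [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(outputs) {
  d <- outputs$decisions
  lines <- c("# Somatic mutational landscape report", "")

  lines <- c(lines, "## Filter cascade funnel", "")
  first_fail <- vapply(strsplit(d$failed_rules, ",", fixed = TRUE),
                       function(x) if (length(x)) x[1] else "", character(1))
  n_cand <- nrow(d)
  lines <- c(lines, sprintf("- candidate variants: %d", n_cand))
  remaining <- n_cand
  for (r in RULES) {
    remaining <- remaining - sum(first_fail == r)
    lines <- c(lines, sprintf("- after %s: %d", r, remaining))
  }
  lines <- c(lines, sprintf("- retained: %d", sum(d$retained)), "")

  lines <- c(lines, "## Burden by histology", "")
  gb <- group_burden(outputs$burden)
  for (i in seq_len(nrow(gb)))
    lines <- c(lines, sprintf(
      "- %s (n=%d): mean %.1f coding mutations (range %d-%d), %.2f/Mb pooled, %d hypermutated",
      gb$histology[i], gb$n_samples[i], gb$mean_count[i], gb$min_count[i],
      gb$max_count[i], gb$pooled_rate_per_mb[i], gb$n_hypermutated[i]))

  lines <- c(lines, "", "## Substitution spectrum", "")
  ov <- outputs$spectra$overall
  if (ov$n_substitutions > 0) {
    fr <- ov$six_class_counts / ov$n_substitutions
    lines <- c(lines, paste(sprintf("%s %.1f%%", names(fr), 100 * fr),
                            collapse = ", "))
    np <- npcpg_fraction(ov)
    lines <- c(lines, sprintf("- C>T at NpCpG: %.1f%% of C>T, %.1f%% of all substitutions",
                              100 * (np$of_ct %||% NA), 100 * (np$of_all %||% NA)))
  } else lines <- c(lines, "- no substitutions retained")

  lines <- c(lines, "", "## Top recurrent genes", "")
  rec <- outputs$stats$recurrence
  if (nrow(rec)) {
    top <- utils::head(rec, 10)
    for (i in seq_len(nrow(top)))
      lines <- c(lines, sprintf("- %s: %d/%d samples (%.1f%%)",
                                top$gene_id[i], top$mutated_total[i],
                                top$denominator[i], top$frequency_pct[i]))
  } else lines <- c(lines, "- none")

  ev <- outputs$stats$evaluation
  if (!is.null(ev)) {
    lines <- c(lines, "", "## Truth-set evaluation", "")
    for (i in seq_len(nrow(ev)))
      lines <- c(lines, sprintf(
        "- %s: sensitivity %.3f (%d/%d), precision %.3f (%d/%d)",
        ev$class[i], ev$sensitivity[i], ev$detected[i], ev$total_true[i],
        ev$precision[i], ev$true_retained[i], ev$retained[i]))
  }
  lines
}
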
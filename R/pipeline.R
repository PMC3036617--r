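#' Recovery statistics against a simulation truth table
#'
#' Compares a species' significant-EST calls with the generator's ground
#' truth: sensitivity over planted effects that were testable (present in
#' the species and surviving the filters), the false-direction rate among
#' called planted ESTs, the number of calls on truly null ESTs, and a
#' Fisher exact test of whether the male-biased call set is enriched for
#' planted uncompensated Z ESTs.
#'
#' @param est_calls data frame of significant ESTs (`est_id`, `direction`,
#'   `fc`).
#' @param truth truth table from [simulate_experiment()].
#' @param species_flag name of the truth column flagging presence of the
#'   effect in this species (`"in_speciesA"` or `"in_speciesB"`).
#' @param tested_ests EST ids that entered the test (after filtering).
#' @return list with `n_planted_testable`, `n_recovered`, `sensitivity`,
#'   `false_direction_rate`, `n_false_calls`, `mean_fc_true_male`,
#'   `enrichment_p` (calls vs planted male Z effects, among tested ESTs).
#' @export
recovery_stats <- function(est_calls, truth, species_flag, tested_ests) {
  tr <- truth[truth$est_id %in% tested_ests, , drop = FALSE]
  planted <- tr$direction != "none" & tr[[species_flag]]
  called <- tr$est_id %in% est_calls$est_id
  dir_call <- est_calls$direction[match(tr$est_id, est_calls$est_id)]
  hit <- called & planted
  n_rec <- sum(hit)
  fdirr <- if (n_rec) sum(dir_call[hit] != tr$direction[hit]) / n_rec
           else NA_real_
  male_z <- planted & tr$chromosome == "Z" & tr$direction == "male"
  enr <- if (sum(called) && sum(male_z)) {
    k <- sum(called & male_z)
    .fisher_p_two_sided(k, sum(male_z), sum(!male_z), sum(called))
  } else NA_real_
  true_male_called <- hit & tr$direction == "male"
  fc_tm <- est_calls$fc[match(tr$est_id[true_male_called],
                              est_calls$est_id)]
  list(n_planted_testable = sum(planted),
       n_recovered = n_rec,
       sensitivity = if (sum(planted)) n_rec / sum(planted) else NA_real_,
       false_direction_rate = fdirr,
       n_false_calls = sum(called & !planted),
       mean_fc_true_male = if (length(fc_tm)) mean(fc_tm) else NA_real_,
       enrichment_p = enr)
}

#' Run the full two-species analysis on simulated data
#'
#' Orchestrates simulate -> normalize -> summarize -> QC -> filter -> SAM ->
#' gene collapse -> Z enrichment for each species, then the cross-species
#' comparison and the population-vs-sex confounding check for species B.
#' Everything is driven by one seed, so reruns are reproducible.
#'
#' Species A is analysed on the full design; species B has the CGH probe
#' mask removed before normalization and the probe-retention rule applied in
#' filtering, mirroring a cross-species hybridization. Genes significant in
#' A whose ESTs were all filtered away in B are classed as untestable in B
#' rather than A-specific.
#'
#' @param sim a [sim_config()] (or an existing [simulate_experiment()]
#'   result to reuse).
#' @param sam_cfg a [sam_config()]; per-species permutation seeds are salted
#'   from it.
#' @param sd_threshold,min_probes filter settings.
#' @param qc_threshold replicate-correlation flag threshold.
#' @param drop_flagged drop QC-flagged samples before testing.
#' @param out_dir optional directory; when given, all intermediate TSV/JSON
#'   artifacts are written there.
#' @return object of class `pipeline_report`: list with `species` (per
#'   species: `qc`, `filter_report`, `sam`, `est_calls`, `gene_calls`,
#'   `table1`, `enrichment`, `recovery`), `comparison`,
#'   `population_check`, `sim_config`, `sam_config`, `truth`.
#' @export
run_pipeline <- function(sim = sim_config(), sam_cfg = sam_config(),
                         sd_threshold = 0.30, min_probes = 8,
                         qc_threshold = 0.9, drop_flagged = FALSE,
                         out_dir = NULL) {
  exp <- if (inherits(sim, "sim_config")) simulate_experiment(sim) else sim
  cfg <- if (inherits(sim, "sim_config")) sim else exp$sim_config
  species <- names(exp$probes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_design(exp$design, file.path(out_dir, "design.tsv"))
    write_sample_sheet(exp$sheet, file.path(out_dir, "samples.tsv"))
    write_mask(exp$cgh_mask, file.path(out_dir, "cgh_mask.txt"))
    write_truth(exp$truth, file.path(out_dir, "truth.tsv"))
  }
  res <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    mask <- if (k == 2) exp$cgh_mask else character()
    m <- exp$probes[[sp]]
    m <- m[!(rownames(m) %in% mask), , drop = FALSE]
    norm <- quantile_normalize(m)
    des_sp <- subset_design(exp$design, drop_probes = mask)
    des_sp <- subset_design(des_sp,
                            est_ids = des_sp$est$est_id[des_sp$est$n_probes > 0])
    expr <- median_polish_summarize(norm, des_sp)
    sheet_sp <- exp$sheet[exp$sheet$species == sp, , drop = FALSE]
    qc <- sample_qc(expr, sheet_sp, qc_threshold)
    if (drop_flagged && length(qc$flagged)) {
      expr <- expr[, setdiff(colnames(expr), qc$flagged), drop = FALSE]
      sheet_sp <- sheet_sp[!sheet_sp$sample_id %in% qc$flagged, , drop = FALSE]
    }
    filt <- filter_ests(expr, exp$design, mask = mask,
                        sd_threshold = sd_threshold,
                        min_probes = min_probes)
    sex <- sheet_sp$sex[match(colnames(filt$expr), sheet_sp$sample_id)]
    cfg_sp <- sam_cfg
    cfg_sp$seed <- sam_cfg$seed + k
    samres <- sam(filt$expr, sex, cfg_sp)
    est_calls <- samres$est[samres$est$significant,
                            c("est_id", "direction", "fc"), drop = FALSE]
    gcalls <- collapse_genes(est_calls, exp$design)
    res[[sp]] <- list(
      qc = qc,
      expr = filt$expr,
      filter_report = filt$report,
      sam = samres,
      est_calls = est_calls,
      gene_calls = gcalls,
      table1 = summarize_table1(gcalls, est_calls),
      enrichment = distribution_report(gcalls, exp$design),
      recovery = recovery_stats(est_calls, exp$truth,
                                c("in_speciesA", "in_speciesB")[k],
                                filt$kept)
    )
    if (!is.null(out_dir)) {
      write_expression(filt$expr,
                       file.path(out_dir, paste0("expression_", sp, ".tsv")))
      utils::write.table(samres$est,
                         file.path(out_dir, paste0("sam_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(gcalls$genes,
                         file.path(out_dir, paste0("genes_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  # genes of A untestable in B: all member ESTs filtered away in B
  a_calls <- res[[species[1]]]$gene_calls$genes
  kept_b_ests <- res[[species[2]]]$sam$est$est_id
  untestable <- a_calls$gene_id[vapply(strsplit(a_calls$est_ids, ","),
                                       function(e) !any(e %in% kept_b_ests),
                                       logical(1))]
  comparison <- compare_species(res[[species[1]]]$gene_calls,
                                res[[species[2]]]$gene_calls,
                                untestable_b = untestable)
  # population-vs-sex check on species B (balanced populations by design)
  sheet_b <- exp$sheet[exp$sheet$species == species[2], , drop = FALSE]
  pop_check <- NULL
  if (!anyNA(sheet_b$population) &&
      length(unique(sheet_b$population)) == 2) {
    pops <- unique(sheet_b$population)
    cfg_pop <- sam_cfg
    cfg_pop$control_label <- pops[1]
    cfg_pop$treatment_label <- pops[2]
    cfg_pop$seed <- sam_cfg$seed + 97L
    # same filtered matrix as the sex test, grouped by population instead
    eb <- res[[species[2]]]$expr
    grp <- sheet_b$population[match(colnames(eb), sheet_b$sample_id)]
    sam_pop <- sam(eb, grp, cfg_pop,
                   sex = sheet_b$sex[match(colnames(eb), sheet_b$sample_id)])
    ov <- overlap_check(sam_pop$est$est_id[sam_pop$est$significant],
                        res[[species[2]]]$est_calls$est_id)
    pop_check <- list(n_population_biased = sum(sam_pop$est$significant),
                      overlap_with_sex = ov)
  }
  report <- structure(list(species = res, comparison = comparison,
                           population_check = pop_check,
                           sim_config = cfg, sam_config = sam_cfg,
                           truth = exp$truth),
                      class = "pipeline_report")
  if (!is.null(out_dir))
    jsonlite::write_json(pipeline_summary(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Plain-list summary of a pipeline report (JSON-ready)
#'
#' @param report a [run_pipeline()] result.
#' @return nested list of counts and statistics mirroring the report.
#' @export
pipeline_summary <- function(report) {
  out <- list()
  for (sp in names(report$species)) {
    r <- report$species[[sp]]
    enr_m <- r$enrichment$male$test
    out[[sp]] <- list(
      n_input = r$filter_report$n_input,
      n_removed_sd = r$filter_report$n_removed_sd,
      n_removed_retention = r$filter_report$n_removed_retention,
      n_analysed = r$filter_report$n_remaining,
      n_significant_ests = nrow(r$est_calls),
      delta = r$sam$delta,
      estimated_fdr = r$sam$fdr,
      s0 = r$sam$s0,
      n_genes = r$gene_calls$n_genes,
      n_multi_est_genes = r$gene_calls$n_multi,
      n_ambiguous_genes = r$gene_calls$n_ambiguous,
      pct_male_ests = r$table1$pct_ests[r$table1$direction == "male"],
      mean_fc_male_genes =
        r$table1$mean_fc_genes[r$table1$direction == "male"],
      observed_prop_z_male =
        if (!is.null(enr_m)) enr_m$observed_prop_z else NA,
      expected_prop_z = r$enrichment$expected_prop_z,
      fisher_p_male = if (!is.null(enr_m)) enr_m$p_value else NA,
      sensitivity = r$recovery$sensitivity,
      false_direction_rate = r$recovery$false_direction_rate
    )
  }
  out$comparison <- lapply(
    report$comparison[c("shared_same_direction", "reversed",
                        "shared_ambiguous", "discordant_ambiguous",
                        "unique_a", "unique_b", "untestable_in_b")],
    length)
  if (!is.null(report$population_check))
    out$population_check <- list(
      n_population_biased = report$population_check$n_population_biased,
      overlap_with_sex = report$population_check$overlap_with_sex$count)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  for (sp in names(x$species)) {
    r <- x$species[[sp]]
    cat(sprintf(
      "%s: %d ESTs analysed, %d significant (delta %.2f, est. FDR %.1f%%), %d genes (%d ambiguous)\n",
      sp, r$filter_report$n_remaining, nrow(r$est_calls), r$sam$delta,
      100 * r$sam$fdr, r$gene_calls$n_genes, r$gene_calls$n_ambiguous))
  }
  cat(sprintf("shared same-direction genes: %d; unique to A: %d; unique to B: %d\n",
              length(x$comparison$shared_same_direction),
              length(x$comparison$unique_a),
              length(x$comparison$unique_b)))
  invisible(x)
}
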
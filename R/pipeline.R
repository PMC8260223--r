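# End-to-end orchestration: simulate (or load) -> events -> PSI -> dual
# differential tests -> TSS/CAGE -> promoter attribution -> motif scan ->
# DE cross-reference, with a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Paths (when given)
#' replace the corresponding simulation stage and must exist at run start.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_genes,afe_fraction,n_first_exons,effect_fraction,delta_psi
#'   Annotation generator parameters ([make_toy_annotation()]).
#' @param n_per_condition,depth,phi Junction-count generator parameters.
#' @param count_threshold,jcn_seq_len PSI parameters ([psi_table()]).
#' @param delta_thresh,alpha,delta Testing gate and significance filter.
#' @param select_alpha Raw-p cutoff for AFE coordinate selection.
#' @param upstream Promoter window size in bases.
#' @param assays,diff_fraction,effect_lfc Peak generator parameters.
#' @param cage_true_rate,cage_decoy_rate CAGE generator parameters.
#' @param n_utrs,utr_length,ire_rate 5'UTR generator parameters.
#' @param de_fraction Planted DE fraction for the gene-expression table.
#' @param conditions Condition labels, control first; the second label is
#'   the treated group.
#' @param dm_filters DM test expression filters (list; defaults 6/3/10/0).
#' @param annotation_path,counts_path,conditions_path Optional input files
#'   replacing simulation.
#' @return A `pipeline_config` list.
#' @export
afe_config <- function(outdir, seed = 1, n_genes = 60, afe_fraction = 0.5,
                       n_first_exons = 2, effect_fraction = 0.4,
                       delta_psi = 30, n_per_condition = 3, depth = 300,
                       phi = 50, count_threshold = 10, jcn_seq_len = 88,
                       delta_thresh = 5, alpha = 0.25, delta = 10,
                       select_alpha = 0.05, upstream = 10000,
                       assays = c("accessibility", "p65", "IRF3"),
                       diff_fraction = 0.25, effect_lfc = 4,
                       cage_true_rate = 0.45, cage_decoy_rate = 0.5,
                       n_utrs = 100, utr_length = 150, ire_rate = 0.3,
                       de_fraction = 0.5, conditions = c("control", "LPS"),
                       dm_filters = list(min_samps_gene_expr = 6,
                                         min_samps_feature_expr = 3,
                                         min_gene_expr = 10,
                                         min_feature_expr = 0),
                       annotation_path = NULL, counts_path = NULL,
                       conditions_path = NULL) {
  cfg <- as.list(environment())
  for (p in c("annotation_path", "counts_path", "conditions_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop(sprintf("config path %s does not exist: %s", p, cfg[[p]]),
           call. = FALSE)
    }
  }
  stop_if_not(seed == round(seed), "seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

#' Run the full AFE analysis pipeline
#'
#' Executes the stages in order, writes every intermediate table under
#' `config$outdir`, and finishes with a JSON manifest recording parameters,
#' seed, package version and per-output row counts. Reruns with identical
#' inputs and seed produce byte-identical output bundles.
#'
#' @param config A [afe_config()].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"), "need an afe_config()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  log_msg <- function(stage, msg) {
    message(sprintf("[afetools:%s] %s", stage, msg))
  }
  log_msg("init", sprintf("seed=%d outdir=%s", config$seed, config$outdir))
  treated <- config$conditions[2]

  # stage 1: inputs ---------------------------------------------------------
  if (is.null(config$annotation_path)) {
    toy <- make_toy_annotation(
      n_genes = config$n_genes, afe_fraction = config$afe_fraction,
      n_first_exons = config$n_first_exons,
      effect_fraction = config$effect_fraction,
      delta_psi = config$delta_psi, seed = config$seed)
    annotation <- toy$annotation
    truth <- toy$truth
  } else {
    annotation <- read_gtf(config$annotation_path)
    truth <- NULL
  }
  write_gtf(annotation, out("annotation.gtf"))
  events <- build_events(annotation)
  if (is.null(config$counts_path)) {
    counts <- simulate_junction_counts(
      annotation, truth, n_per_condition = config$n_per_condition,
      depth = config$depth, precision = config$phi, seed = config$seed + 1,
      conditions = config$conditions, events = events)
  } else {
    counts <- read_count_table(config$counts_path, config$conditions_path)
  }
  write_count_table(counts, out("junction_counts.tsv"),
                    out("sample_conditions.tsv"))
  log_msg("simulate", sprintf("%d exons, %d count rows",
                              nrow(annotation), nrow(counts$counts)))

  # stage 2: events + PSI ---------------------------------------------------
  write_event_table(events, counts, out("events.tsv"))
  psi <- psi_table(events, counts, count_threshold = config$count_threshold,
                   jcn_seq_len = config$jcn_seq_len)
  psi_df <- data.frame(row_id = rownames(psi$psi),
                       psi$psi, check.names = FALSE)
  write_tsv(psi_df, out("psi.tsv"))
  log_msg("events", sprintf("%d events (%d candidate rows)",
                            length(unique(events$event_id)), nrow(events)))

  # stage 3: differential splicing -----------------------------------------
  res_t <- ttest_diff(psi, treated = treated,
                      delta_thresh = config$delta_thresh)
  res_d <- do.call(dm_lrt, c(list(events = events, counts = counts,
                                  treated = treated), config$dm_filters))
  write_tsv(res_t, out("diff_ttest.tsv"))
  write_tsv(res_d, out("diff_dm.tsv"))
  sig_t <- significant_events(res_t, alpha = config$alpha,
                              delta = config$delta)
  sig_d <- significant_events(res_d, alpha = config$alpha,
                              delta = config$delta)
  genes_union <- union_genes(sig_t, sig_d)
  write_tsv(data.frame(
    event_type = rep(names(genes_union),
                     vapply(genes_union, length, integer(1))),
    gene_id = unlist(genes_union, use.names = FALSE)),
    out("significant_union_genes.tsv"))
  ranking <- ranking_composition(res_t)
  write_tsv(ranking, out("ranking_composition.tsv"))
  log_msg("diff", sprintf("significant: %d (t-test rows), %d (DM rows)",
                          nrow(sig_t), nrow(sig_d)))

  # stage 4: TSS / CAGE -----------------------------------------------------
  tss <- classify_tss(extract_tss(annotation), reference_tss(annotation))
  cage <- if (is.null(truth)) NULL else
    simulate_cage_peaks(annotation, truth,
                        true_rate = config$cage_true_rate,
                        decoy_rate = config$cage_decoy_rate,
                        seed = config$seed + 2)
  support <- if (is.null(cage)) NULL else
    cage_support(tss, cage$peaks,
                 truth_peaks = cage$peaks[
                   cage$peaks$name %in% cage$truth$true_peaks, , drop = FALSE])
  if (!is.null(support)) {
    write_tss_bed(support$records, out("tss.bed"))
    tss_summary <- lapply(support$summary, function(s)
      list(n = s$n, supported = s$supported,
           true_fraction = s$true_fraction))
    jsonlite::write_json(tss_summary, out("tss_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # stage 5: promoter attribution -------------------------------------------
  pooled <- rbind(res_t, res_d)
  sel <- select_afe_coordinates(pooled, alpha = config$select_alpha,
                                delta = config$delta)
  win <- promoter_windows(sel, upstream = config$upstream)
  write_bed(stats::setNames(
    sel[, c("chrom", "start", "end", "strand", "event_id")],
    c("chrom", "start", "end", "strand", "name")), out("afe_exons.bed"))
  write_bed(stats::setNames(
    win[, c("chrom", "start", "end", "strand", "event_id")],
    c("chrom", "start", "end", "strand", "name")),
    out("promoter_windows.bed"))
  peak_sim <- if (is.null(truth)) NULL else
    simulate_peak_counts(annotation, truth, assays = config$assays,
                         diff_fraction = config$diff_fraction,
                         effect_lfc = config$effect_lfc,
                         n_per_condition = config$n_per_condition,
                         seed = config$seed + 3,
                         conditions = config$conditions)
  attribution <- NULL
  if (!is.null(peak_sim)) {
    diffs <- lapply(names(peak_sim), function(assay) {
      preset <- peak_preset(
        if (grepl("access", assay, ignore.case = TRUE)) "accessibility"
        else "tf")
      pm <- merge_near(peak_sim[[assay]]$peaks, max_gap = 10)
      # merged consensus peaks inherit the names of their members
      nm <- intersect_intervals(pm, peak_sim[[assay]]$peaks)
      pm$name <- tapply(peak_sim[[assay]]$peaks$name[nm$b_idx], nm$a_idx,
                        function(x) sort(x)[1])[as.character(seq_len(nrow(pm)))]
      counts_pm <- regroup_counts(peak_sim[[assay]], nm, pm)
      do.call(differential_peaks,
              c(list(peaks = pm, counts = counts_pm, treated = treated),
                preset))
    })
    names(diffs) <- names(peak_sim)
    for (assay in names(diffs)) {
      write_tsv(diffs[[assay]], out(sprintf("peaks_%s.tsv", assay)))
    }
    attribution <- attribute_regulation(win, diffs)
    write_tsv(attribution$attribution, out("attribution.tsv"))
    write_tsv(attribution$upset, out("upset_counts.tsv"))
  }
  log_msg("attribute", sprintf("%d selected AFE exons", nrow(sel)))

  # stage 6: motifs ---------------------------------------------------------
  utrs <- plant_utr_motifs(n_seqs = config$n_utrs,
                           length = config$utr_length,
                           ire_rate = config$ire_rate,
                           seed = config$seed + 4)
  write_fasta(utrs$seqs, out("utrs.fa"))
  hits <- do.call(rbind, lapply(names(utrs$seqs), function(id) {
    h <- scan_ire(utrs$seqs[[id]])
    if (!nrow(h)) return(NULL)
    cbind(data.frame(seq_id = id, motif = "IRE"), h)
  }))
  hits <- hits %||% data.frame(seq_id = character(0), motif = character(0))
  write_tsv(hits, out("motif_hits.tsv"))
  log_msg("motifs", sprintf("%d IRE hits in %d sequences", nrow(hits),
                            length(utrs$seqs)))

  # stage 7: DE cross-reference ---------------------------------------------
  afe_genes_sig <- genes_union$AFE %||% character(0)
  de <- if (is.null(truth)) NULL else
    simulate_de_table(unique(annotation$gene_id),
                      de_fraction = config$de_fraction,
                      seed = config$seed + 5)
  crossref <- if (is.null(de) || !length(afe_genes_sig)) NULL else
    crossref_de(afe_genes_sig, de$table)
  if (!is.null(crossref)) {
    jsonlite::write_json(crossref[c("n_de", "n_non_de", "fraction_de")],
                         out("crossref_de.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  # manifest -----------------------------------------------------------------
  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    package = "afetools",
    version = as.character(utils::packageVersion("afetools")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config),
                                         c("outdir"))],
    outputs = lapply(setNames(files, files), function(f) {
      list(lines = length(readLines(out(f), warn = FALSE)))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("done", sprintf("%d output files", length(files)))
  invisible(list(annotation = annotation, truth = truth, counts = counts,
                 events = events, psi = psi, res_ttest = res_t,
                 res_dm = res_d, sig_ttest = sig_t, sig_dm = sig_d,
                 genes_union = genes_union, ranking = ranking, tss = tss,
                 cage = cage, cage_support = support, selected = sel,
                 windows = win, peak_sim = peak_sim,
                 attribution = attribution, utrs = utrs, motif_hits = hits,
                 de = de, crossref = crossref, manifest = manifest))
}

# Re-key an assay's counts onto merged peaks (sums member rows).
regroup_counts <- function(assay_sim, name_map, merged) {
  m <- assay_sim$counts$counts
  grp <- rep(NA_integer_, nrow(m))
  grp[match(assay_sim$peaks$name[name_map$b_idx], rownames(m))] <-
    name_map$a_idx
  mm <- rowsum(m, group = grp, reorder = FALSE)
  rownames(mm) <- merged$name[as.integer(rownames(mm))]
  count_table(mm[merged$name, , drop = FALSE], assay_sim$counts$condition)
}

#' Cross-reference AFE genes against a differential-expression table
#'
#' Partitions the AFE gene set into DE (`|log2FC| >= lfc_min` and
#' `p_adj <= alpha`) versus non-DE; genes absent from the table count as
#' non-DE (recorded in `missing`).
#'
#' @param afe_genes Character vector of genes with AFE events.
#' @param de_table `data.frame` with columns `gene`, `log2fc`, `p_adj`.
#' @param lfc_min,alpha DE thresholds (defaults 2 and 0.05).
#' @return List: `n_afe`, `n_de`, `n_non_de`, `fraction_de`, `de_genes`,
#'   `missing`.
#' @export
crossref_de <- function(afe_genes, de_table, lfc_min = 2, alpha = 0.05) {
  stop_if_not(all(c("gene", "log2fc", "p_adj") %in% names(de_table)),
              "de_table needs columns gene, log2fc, p_adj")
  afe_genes <- unique(afe_genes)
  idx <- match(afe_genes, de_table$gene)
  missing <- afe_genes[is.na(idx)]
  is_de <- !is.na(idx) &
    abs(de_table$log2fc[idx]) >= lfc_min &
    de_table$p_adj[idx] <= alpha
  is_de[is.na(is_de)] <- FALSE
  list(n_afe = length(afe_genes),
       n_de = sum(is_de),
       n_non_de = sum(!is_de),
       fraction_de = mean(is_de),
       de_genes = sort(afe_genes[is_de]),
       missing = missing)
}
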
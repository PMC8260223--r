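# Promoter regulatory attribution of alternative first exons: coordinate
# selection by the delta-PSI sign rule, 10-kb upstream windows, differential
# peak calling on count matrices, and the UpSet partition of events by the
# exact combination of differential assays at their promoter.

#' Select AFE exon coordinates by the delta-PSI sign rule
#'
#' For each significant AFE event: if the inclusion candidate's delta PSI
#' exceeds `delta`, its own exon coordinates are emitted; if it is below
#' `-delta`, every sibling candidate of the event with delta PSI above
#' `delta` is emitted instead. Events whose candidates all sit inside
#' `[-delta, delta]` contribute nothing (recorded in `attr(, "skipped")`).
#' Exons duplicated across events are emitted once, in deterministic
#' coordinate order.
#'
#' @param results Candidate-level results ([ttest_diff()]/[dm_lrt()] rows,
#'   possibly pooled across tests).
#' @param alpha Significance cutoff applied to the event (default 0.05).
#' @param use_adjusted Apply `alpha` to `p_adj` instead of `p_raw`
#'   (default `FALSE`, the raw-p selection convention for this step).
#' @param delta Sign-rule threshold in percent (default 10).
#' @return Interval table of selected exons with `event_id`, `gene_id`.
#' @export
select_afe_coordinates <- function(results, alpha = 0.05,
                                   use_adjusted = FALSE, delta = 10) {
  afe <- results[results$event_type == "AFE", , drop = FALSE]
  pcol <- if (use_adjusted) afe$p_adj else afe$p_raw
  sig_events <- unique(afe$event_id[!is.na(pcol) & pcol <= alpha])
  out <- list()
  skipped <- character(0)
  for (eid in sig_events) {
    ev <- afe[afe$event_id == eid, , drop = FALSE]
    inc <- ev[ev$inclusion, , drop = FALSE]
    pick <- NULL
    for (k in seq_len(nrow(inc))) {
      d <- inc$delta_psi[k]
      if (is.na(d)) next
      if (d > delta) {
        pick <- rbind(pick, inc[k, , drop = FALSE])
      } else if (d < -delta) {
        sib <- ev[ev$candidate != inc$candidate[k] &
                    !is.na(ev$delta_psi) & ev$delta_psi > delta, ,
                  drop = FALSE]
        pick <- rbind(pick, sib)
      }
    }
    if (is.null(pick) || nrow(pick) == 0) {
      skipped <- c(skipped, eid)
      next
    }
    out[[eid]] <- pick
  }
  sel <- if (length(out)) do.call(rbind, out) else afe[0, , drop = FALSE]
  sel <- data.frame(chrom = sel$chrom, start = sel$exon_start,
                    end = sel$exon_end, strand = sel$strand,
                    event_id = sel$event_id, gene_id = sel$gene_id,
                    stringsAsFactors = FALSE)
  sel <- sel[!is.na(sel$start), , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start, sel$end, sel$event_id), , drop = FALSE]
  sel <- sel[!duplicated(sel[, c("chrom", "start", "end")]), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "skipped") <- skipped
  sel
}

#' Promoter windows upstream of exons
#'
#' Extends each exon to include `upstream` bases of promoter sequence:
#' 5' of the exon in transcription direction when `stranded` (the default —
#' genomic left on `+`, genomic right on `-`), always genomic left
#' otherwise. Starts are clipped at zero. The window contains the exon.
#'
#' @param exons Interval table (extra columns carried through).
#' @param upstream Extension in bases (default 10000).
#' @param stranded Strand-aware extension (default `TRUE`).
#' @return Interval table of windows.
#' @export
promoter_windows <- function(exons, upstream = 10000, stranded = TRUE) {
  stop_if_not(upstream >= 0, "upstream must be >= 0")
  win <- exons
  left <- if (stranded) exons$strand != "-" else rep(TRUE, nrow(exons))
  win$start <- ifelse(left, pmax(0, exons$start - upstream), exons$start)
  win$end <- ifelse(left, exons$end, exons$end + upstream)
  win
}

#' Peak-calling presets for differential peak thresholds
#'
#' `"accessibility"`: log2FC > 0.8 at raw p < 0.15;
#' `"tf"`: log2FC > 1 at BH-adjusted p < 0.25. The two rules are asymmetric
#' (raw vs adjusted p) on purpose, mirroring the respective upstream
#' pipelines' conventions.
#'
#' @param assay `"accessibility"` or `"tf"`.
#' @return List with `lfc_min`, `p_min`, `use_adjusted`.
#' @export
peak_preset <- function(assay = c("accessibility", "tf")) {
  assay <- match.arg(assay)
  if (assay == "accessibility") {
    list(lfc_min = 0.8, p_min = 0.15, use_adjusted = FALSE)
  } else {
    list(lfc_min = 1.0, p_min = 0.25, use_adjusted = TRUE)
  }
}

#' Differential peaks from a peak count matrix
#'
#' Library sizes are normalized to counts per million; the log2 fold change
#' compares mean CPM (+0.5 pseudocount) between conditions and the p-value
#' is a two-sample t-test on per-sample `log2(CPM + 0.5)`, BH-adjusted
#' across peaks. A peak is differential when `log2fc > lfc_min` and the
#' chosen p-value (raw or adjusted) is below `p_min`. This is a declared
#' simple fold-change/t statistic for thresholding merged consensus peaks,
#' not a count-model fit.
#'
#' @param peaks Interval table of (pre-merged) peaks with a `name` column
#'   matching the count rows.
#' @param counts [count_table()] over peaks.
#' @param treated,control Condition labels as in [ttest_diff()].
#' @param lfc_min,p_min,use_adjusted Thresholds; see [peak_preset()].
#' @return `peaks` with `log2fc`, `p_raw`, `p_adj`, `differential`.
#' @export
differential_peaks <- function(peaks, counts, treated = "LPS",
                               control = NULL, lfc_min = 0.8, p_min = 0.15,
                               use_adjusted = FALSE) {
  grp <- split_samples(counts$condition, treated, control)
  stop_if_not(length(grp$treated) >= 1 && length(grp$control) >= 1,
              "each condition needs >= 1 replicate")
  m <- counts$counts[peaks$name, , drop = FALSE]
  lib <- colSums(counts$counts)
  cpm <- sweep(m, 2, lib / 1e6, "/")
  mt <- rowMeans(cpm[, grp$treated, drop = FALSE])
  mc <- rowMeans(cpm[, grp$control, drop = FALSE])
  lfc <- log2((mt + 0.5) / (mc + 0.5))
  lcpm <- log2(cpm + 0.5)
  p <- vapply(seq_len(nrow(lcpm)), function(i) {
    tryCatch(t.test(lcpm[i, grp$treated], lcpm[i, grp$control],
                    var.equal = TRUE)$p.value,
             error = function(e) if (lfc[i] != 0) 0 else 1)
  }, numeric(1))
  padj <- bh_adjust(p)
  peaks$log2fc <- unname(lfc)
  peaks$p_raw <- p
  peaks$p_adj <- padj
  pcheck <- if (use_adjusted) padj else p
  peaks$differential <- peaks$log2fc > lfc_min & pcheck < p_min
  peaks
}

#' Attribute promoter regulation to AFE events
#'
#' For every promoter window and assay, the event is flagged when at least
#' one differential peak of that assay overlaps the window (>= 1 bp). The
#' partition label is the exact set of flagged assays (`"none"` when empty),
#' so labels partition the events — the UpSet decomposition.
#'
#' @param windows Promoter-window table with `event_id`, `gene_id`
#'   ([promoter_windows()] over [select_afe_coordinates()]).
#' @param diff_peaks_by_assay Named list of [differential_peaks()] outputs.
#' @return List: `attribution` (per event: flags per assay and
#'   `partition`), `upset` (counts per partition label), and `fractions`
#'   (share of events with any accessibility flag / any TF flag).
#' @export
attribute_regulation <- function(windows, diff_peaks_by_assay) {
  flags <- matrix(FALSE, nrow = nrow(windows),
                  ncol = length(diff_peaks_by_assay),
                  dimnames = list(NULL, names(diff_peaks_by_assay)))
  for (assay in names(diff_peaks_by_assay)) {
    pk <- diff_peaks_by_assay[[assay]]
    pk <- pk[pk$differential, , drop = FALSE]
    if (!nrow(pk)) next
    hits <- intersect_intervals(windows, pk, mode = "overlap")
    flags[unique(hits$a_idx), assay] <- TRUE
  }
  label <- apply(flags, 1, function(f) {
    if (!any(f)) "none" else paste(colnames(flags)[f], collapse = "+")
  })
  attribution <- cbind(windows[, c("event_id", "gene_id", "chrom", "start",
                                   "end", "strand")],
                       as.data.frame(flags),
                       data.frame(partition = label, stringsAsFactors = FALSE))
  tab <- table(label)
  upset <- data.frame(partition = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
  upset <- upset[order(-upset$count, upset$partition), , drop = FALSE]
  rownames(upset) <- NULL
  acc <- grepl("access", names(diff_peaks_by_assay), ignore.case = TRUE)
  fractions <- c(
    accessibility = if (any(acc))
      mean(apply(flags[, acc, drop = FALSE], 1, any)) else NA_real_,
    tf = if (any(!acc))
      mean(apply(flags[, !acc, drop = FALSE], 1, any)) else NA_real_)
  list(attribution = attribution, upset = upset, fractions = fractions)
}
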
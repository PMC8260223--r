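#' Length-normalized isoform abundance
#'
#' Abundance is the read count divided by the effective isoform length. The
#' effective length of an exon part is its width; a junction part contributes
#' a fixed `jcn_seq_len` (the junction-spanning sequence length, 88 for
#' short-read runs, 238 for merged long-read annotation runs); a multi-part
#' candidate sums its part lengths.
#'
#' @param count Read counts (>= 0).
#' @param effective_length Effective lengths (> 0), recycled.
#' @return `count / effective_length`.
#' @export
isoform_abundance <- function(count, effective_length) {
  stop_if_not(all(effective_length > 0), "effective_length must be > 0")
  stop_if_not(all(count >= 0), "count must be >= 0")
  count / effective_length
}

#' Percent spliced in from inclusion/exclusion abundances
#'
#' `PSI = 100 * inclusion / (inclusion + exclusion)`, missing when both
#' abundances are zero.
#'
#' @param inclusion_abundance,exclusion_abundance Non-negative abundances.
#' @return PSI in percent, `NA` where undefined.
#' @export
compute_psi <- function(inclusion_abundance, exclusion_abundance) {
  stop_if_not(all(inclusion_abundance >= 0) && all(exclusion_abundance >= 0),
              "abundances must be >= 0")
  tot <- inclusion_abundance + exclusion_abundance
  ifelse(tot == 0, NA_real_, 100 * inclusion_abundance / tot)
}

#' Effective candidate lengths for a configured junction sequence length
#'
#' @param events Event table ([build_events()]).
#' @param jcn_seq_len Effective length of one junction part.
#' @return Numeric vector aligned with `events` rows.
#' @export
event_effective_lengths <- function(events, jcn_seq_len = 88) {
  stop_if_not(jcn_seq_len > 0, "jcn_seq_len must be > 0")
  events$exon_len + events$n_jcn * jcn_seq_len
}

#' Per-sample PSI table for all events
#'
#' For each event and sample, candidate PSI is the candidate's
#' length-normalized abundance as a percentage of the event's total
#' abundance; all of a sample's PSIs for an event are set missing when the
#' event's total raw count in that sample is below `count_threshold`
#' (the per-sample read-support filter).
#'
#' @param events Event table.
#' @param counts [count_table()] keyed by `row_id` (every candidate needs a
#'   count row).
#' @param count_threshold Minimum per-sample event total (default 10).
#' @param jcn_seq_len See [event_effective_lengths()].
#' @return A `psi_table`: list with matrices `psi` and `abundance`
#'   (candidate rows x samples), `total` (event x sample raw totals), the
#'   `events` table and the parameters used.
#' @export
psi_table <- function(events, counts, count_threshold = 10,
                      jcn_seq_len = 88) {
  missing_rows <- setdiff(events$row_id, rownames(counts$counts))
  if (length(missing_rows)) {
    stop(paste0("no count row for candidate(s): ",
                paste(utils::head(missing_rows, 5), collapse = ", ")),
         call. = FALSE)
  }
  m <- counts$counts[events$row_id, , drop = FALSE]
  eff <- event_effective_lengths(events, jcn_seq_len)
  ab <- m / eff
  ev_ids <- unique(events$event_id)
  total <- rowsum(m, group = events$event_id, reorder = FALSE)
  ab_tot <- rowsum(ab, group = events$event_id, reorder = FALSE)
  idx <- match(events$event_id, rownames(total))
  psi <- 100 * ab / ab_tot[idx, , drop = FALSE]
  psi[ab_tot[idx, , drop = FALSE] == 0] <- NA_real_
  psi[total[idx, , drop = FALSE] < count_threshold] <- NA_real_
  structure(list(psi = psi, abundance = ab, total = total,
                 events = events, condition = counts$condition,
                 count_threshold = count_threshold,
                 jcn_seq_len = jcn_seq_len),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat(sprintf("psi_table: %d candidates / %d events x %d samples (thresh %g)\n",
              nrow(x$psi), nrow(x$total), ncol(x$psi), x$count_threshold))
  invisible(x)
}

#' Per-transcript isoform usage and predominance
#'
#' Usage is a transcript's share of its gene's total counts per sample, in
#' percent; a transcript is predominant in a sample when its usage is at
#' least `predominance_min` percent of the gene total. Optional promoter
#' groups report summed member usage (usage categorized by promoter).
#'
#' @param counts [count_table()] over transcripts.
#' @param gene_of Named vector mapping transcript id to gene id.
#' @param promoter_of Optional named vector mapping transcript id to a
#'   promoter-group label.
#' @param predominance_min Predominance cutoff in percent (default 10).
#' @return List with `usage` (long `data.frame`: transcript, gene, sample,
#'   usage, predominant) and, when groups are given, `promoter_usage`.
#' @export
isoform_usage <- function(counts, gene_of, promoter_of = NULL,
                          predominance_min = 10) {
  m <- counts$counts
  stop_if_not(all(rownames(m) %in% names(gene_of)),
              "every transcript needs a gene mapping")
  gene <- gene_of[rownames(m)]
  tot <- rowsum(m, group = gene, reorder = FALSE)
  denom <- tot[match(gene, rownames(tot)), , drop = FALSE]
  usage <- 100 * m / denom
  usage[denom == 0] <- NA_real_
  long <- data.frame(
    transcript_id = rep(rownames(m), ncol(m)),
    gene_id = rep(unname(gene), ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    usage = as.vector(usage),
    stringsAsFactors = FALSE)
  long$predominant <- !is.na(long$usage) & long$usage >= predominance_min
  out <- list(usage = long)
  if (!is.null(promoter_of)) {
    grp <- promoter_of[rownames(m)]
    gu <- rowsum(usage, group = paste(gene, grp, sep = "\r"), reorder = FALSE)
    keys <- strsplit(rownames(gu), "\r", fixed = TRUE)
    out$promoter_usage <- data.frame(
      gene_id = rep(vapply(keys, `[`, character(1), 1), ncol(gu)),
      promoter = rep(vapply(keys, `[`, character(1), 2), ncol(gu)),
      sample = rep(colnames(gu), each = nrow(gu)),
      usage = as.vector(gu),
      stringsAsFactors = FALSE)
  }
  out
}
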
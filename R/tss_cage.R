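# Transcript start sites: extraction, known/novel classification against a
# reference start set, and CAGE peak support.

#' Extract transcript start sites
#'
#' The TSS is the single 5'-most transcribed base: the genomic start of the
#' rank-1 exon on `+`, the genomic `end - 1` of the rank-1 exon on `-`.
#'
#' @param annotation Annotation table ([read_gtf()]).
#' @return One row per transcript: `chrom`, `start`, `end` (width-1
#'   interval), `strand`, `transcript_id`, `gene_id`, `source`.
#' @export
extract_tss <- function(annotation) {
  stop_if_not(all(annotation$strand %in% c("+", "-")),
              "TSS is undefined for unstranded transcripts")
  fe <- annotation[annotation$rank == 1, , drop = FALSE]
  pos <- ifelse(fe$strand == "+", fe$start, fe$end - 1)
  out <- data.frame(chrom = fe$chrom, start = pos, end = pos + 1,
                    strand = fe$strand, transcript_id = fe$transcript_id,
                    gene_id = fe$gene_id, source = fe$source,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference TSS set of an annotation
#'
#' Distinct 1-bp start positions of all `source == "reference"` transcripts.
#'
#' @param annotation Annotation table.
#' @return Interval table of unique reference TSS bases.
#' @export
reference_tss <- function(annotation) {
  ref <- annotation[annotation$source == "reference", , drop = FALSE]
  tss <- extract_tss(ref)
  tss <- tss[!duplicated(tss[, c("chrom", "start", "strand")]), , drop = FALSE]
  rownames(tss) <- NULL
  tss
}

#' Classify TSSs as known or novel
#'
#' A TSS is `known` when its 1-bp interval, widened by `slack` bases on each
#' side, overlaps any reference TSS base; otherwise `novel`. The comparison
#' is strand-aware by default (a minus-strand start cannot be validated by a
#' plus-strand reference start).
#'
#' @param tss TSS table ([extract_tss()]).
#' @param ref Reference TSS table ([reference_tss()]).
#' @param slack Positional tolerance in bases (default 0, plain
#'   single-base intersection).
#' @param stranded Require matching strand (default `TRUE`).
#' @return `tss` with a `status` column (`"known"`/`"novel"`).
#' @export
classify_tss <- function(tss, ref, slack = 0, stranded = TRUE) {
  stop_if_not(slack >= 0, "slack must be >= 0")
  wide <- tss
  wide$start <- pmax(0, wide$start - slack)
  wide$end <- wide$end + slack
  hits <- intersect_intervals(wide, ref, mode = "overlap",
                              stranded = stranded)
  tss$status <- ifelse(seq_len(nrow(tss)) %in% hits$a_idx, "known", "novel")
  tss
}

#' CAGE peak support for TSSs
#'
#' Per TSS: the number of overlapping CAGE peaks and the best (maximum)
#' score among them. The summary stratifies the score distribution by
#' known/novel status and, when a set of classifier-validated "true" peaks
#' is supplied, reports the fraction of known and of novel TSSs that overlap
#' a true peak.
#'
#' @param tss Classified TSS table ([classify_tss()]).
#' @param cage_peaks Scored interval table (`score` column required).
#' @param truth_peaks Optional interval table of peaks classified as true
#'   TSS signals.
#' @return List with the per-record table (`records`: `cage_peaks` count,
#'   `best_cage_score`, `true_overlap`) and a `summary` list (score vectors
#'   and true-overlap fractions per status).
#' @export
cage_support <- function(tss, cage_peaks, truth_peaks = NULL) {
  stop_if_not(!is.null(cage_peaks$score), "cage_peaks must carry a score")
  hits <- intersect_intervals(tss, cage_peaks, mode = "overlap")
  tss$cage_peaks <- 0L
  tss$best_cage_score <- 0
  if (nrow(hits)) {
    cnt <- table(hits$a_idx)
    tss$cage_peaks[as.integer(names(cnt))] <- as.integer(cnt)
    best <- tapply(cage_peaks$score[hits$b_idx], hits$a_idx, max)
    tss$best_cage_score[as.integer(names(best))] <- as.numeric(best)
  }
  tss$true_overlap <- NA
  if (!is.null(truth_peaks)) {
    th <- intersect_intervals(tss, truth_peaks, mode = "overlap")
    tss$true_overlap <- seq_len(nrow(tss)) %in% th$a_idx
  }
  summ <- lapply(split(seq_len(nrow(tss)), tss$status), function(idx) {
    scores <- tss$best_cage_score[idx][tss$cage_peaks[idx] > 0]
    list(n = length(idx),
         supported = sum(tss$cage_peaks[idx] > 0),
         scores = scores,
         true_fraction = if (is.null(truth_peaks)) NA_real_ else
           mean(tss$true_overlap[idx]))
  })
  list(records = tss, summary = summ)
}

#' Write classified TSSs as BED6
#'
#' Name is the transcript id; score is the best CAGE score (0 when
#' unsupported).
#'
#' @param records Per-record table from [cage_support()].
#' @param path Output path.
#' @export
write_tss_bed <- function(records, path) {
  x <- records[, c("chrom", "start", "end", "strand")]
  x$name <- records$transcript_id
  x$score <- records$best_cage_score %||% 0
  write_bed(x, path)
}
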
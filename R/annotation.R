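#' Derive splice junctions from an annotation table
#'
#' A junction joins the genomic end of one exon (donor end, 0-based
#' exclusive) to the genomic start of the next (acceptor start, 0-based
#' inclusive) within a transcript, in genomic orientation.
#'
#' @param annotation Annotation table (see [read_gtf()]).
#' @return `data.frame` with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `strand`, `transcript_id`, `gene_id`, `source`.
#' @export
junctions_from_annotation <- function(annotation) {
  pieces <- split(annotation, annotation$transcript_id)
  out <- lapply(pieces, function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    m <- nrow(tx)
    if (m < 2) return(NULL)
    data.frame(chrom = tx$chrom[1],
               donor_end = tx$end[-m],
               acceptor_start = tx$start[-1],
               strand = tx$strand[1],
               transcript_id = tx$transcript_id[1],
               gene_id = tx$gene_id[1],
               source = tx$source[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), donor_end = numeric(0),
                      acceptor_start = numeric(0), strand = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      source = character(0), stringsAsFactors = FALSE)
  }
  stop_if_not(all(out$donor_end < out$acceptor_start),
              "junction donor_end must precede acceptor_start")
  rownames(out) <- NULL
  out
}

#' Transcript spans of an annotation table
#'
#' @param annotation Annotation table.
#' @return One interval row per transcript covering min exon start to max
#'   exon end.
#' @export
transcript_spans <- function(annotation) {
  pieces <- split(annotation, annotation$transcript_id)
  out <- lapply(pieces, function(tx) {
    data.frame(chrom = tx$chrom[1], start = min(tx$start), end = max(tx$end),
               strand = tx$strand[1], transcript_id = tx$transcript_id[1],
               gene_id = tx$gene_id[1], source = tx$source[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
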
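#' Construct a table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' exclusive end, strand one of `"+"`, `"-"`, `"."`.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`start < end`).
#' @param strand Strand characters, recycled; default unstranded (`"."`).
#' @param ... Further equal-length columns (e.g. `name`, `score`) carried
#'   along as metadata.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand` and
#'   any extra columns supplied.
#' @export
genome_intervals <- function(chrom, start, end, strand = ".", ...) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(x) {
  stop_if_not(all(c("chrom", "start", "end", "strand") %in% names(x)),
              "interval table needs columns chrom, start, end, strand")
  stop_if_not(all(x$start >= 0), "interval start must be >= 0")
  stop_if_not(all(x$start < x$end), "interval start must be < end")
  stop_if_not(all(x$strand %in% c("+", "-", ".")),
              "strand must be one of '+', '-', '.'")
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed).
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

granges_to_df <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             strand = ifelse(s == "*", ".", s),
             stringsAsFactors = FALSE)
}

#' Intersect two interval sets
#'
#' Overlap means at least one shared base under half-open semantics
#' (`a.start < b.end && b.start < a.end` on the same chromosome). Strand is
#' ignored unless `stranded = TRUE` (the bedtools `intersectBed` default);
#' under `stranded`, unstranded (`"."`) intervals match either strand;
#' `mode = "no_overlap"` mirrors `intersectBed -v` and returns the rows of
#' `a` that match nothing in `b`.
#'
#' @param a,b Interval tables (see [genome_intervals()]).
#' @param mode `"overlap"` returns the matching index pairs; `"no_overlap"`
#'   returns the unmatched rows of `a`.
#' @param stranded Require matching strand?
#' @return For `"overlap"`, a `data.frame` with columns `a_idx`, `b_idx`
#'   (row indices into `a` and `b`); for `"no_overlap"`, the subset of `a`
#'   with zero matches.
#' @export
intersect_intervals <- function(a, b, mode = c("overlap", "no_overlap"),
                                stranded = FALSE) {
  mode <- match.arg(mode)
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0 || (mode == "overlap" && nrow(b) == 0)) {
    if (mode == "overlap") {
      return(data.frame(a_idx = integer(0), b_idx = integer(0)))
    }
    return(a)
  }
  if (nrow(b) == 0) return(a)
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      ignore.strand = !stranded)
  if (mode == "overlap") {
    data.frame(a_idx = S4Vectors::queryHits(hits),
               b_idx = S4Vectors::subjectHits(hits))
  } else {
    a[setdiff(seq_len(nrow(a)), unique(S4Vectors::queryHits(hits))), ,
      drop = FALSE]
  }
}

#' Merge intervals whose gap is below a threshold
#'
#' Intervals closer than `max_gap` bases (strictly `gap < max_gap`, per the
#' "less than 10 bp" consensus-peak rule) are merged transitively; set
#' `closed = TRUE` for the bedtools `merge -d` convention (`gap <= max_gap`).
#' Merging is strand-blind and the result is sorted and disjoint.
#'
#' @param x Interval table.
#' @param max_gap Maximum gap in bases (>= 0).
#' @param closed Use `<=` instead of the default strict `<` on the gap.
#' @return Merged interval table (strand `"."`).
#' @export
merge_near <- function(x, max_gap, closed = FALSE) {
  stop_if_not(is.numeric(max_gap) && max_gap >= 0, "max_gap must be >= 0")
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end", "strand")])
  gr <- as_granges(x)
  BiocGenerics::strand(gr) <- "*"
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + as.integer(closed))
  out <- granges_to_df(BiocGenerics::sort(merged))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment with first-class missing values
#'
#' Step-up FDR adjustment over the non-missing entries only (missing values
#' do not count toward the number of tests and stay missing); original order
#' is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
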
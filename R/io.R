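#' Read transcript models from a GTF file
#'
#' Reads `exon` features from a Gencode-dialect GTF (attributes
#' `gene_id "x"; transcript_id "y";`), converts the 1-based inclusive
#' coordinates to the package's 0-based half-open convention, and ranks the
#' exons of each transcript in transcription direction (reverse genomic order
#' on the minus strand).
#'
#' @param path GTF file path.
#' @param source Provenance label attached to every transcript, either
#'   `"reference"` (curated annotation) or `"longread"` (e.g. isoforms
#'   assembled from native RNA reads).
#' @return An annotation `data.frame` with one row per exon and columns
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `start`, `end`, `rank`,
#'   `source`.
#' @export
read_gtf <- function(path, source = c("reference", "longread")) {
  source <- match.arg(source)
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", i),
           call. = FALSE)
    }
    if (is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5])))) {
      stop(sprintf("malformed GTF line %d: non-numeric coordinates", i),
           call. = FALSE)
    }
    if (f[3] == "exon" &&
        (!grepl("transcript_id", f[9], fixed = TRUE) ||
         !grepl("gene_id", f[9], fixed = TRUE))) {
      stop(sprintf("rejected record at GTF line %d: exon lacks gene_id/transcript_id", i),
           call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- granges_to_df(gr)
  df$gene_id <- as.character(gr$gene_id)
  df$transcript_id <- as.character(gr$transcript_id)
  df$source <- source
  rank_exons(df)
}

# Assign transcription-direction exon ranks and validate per-transcript
# consistency (single chrom/strand, non-overlapping exons). Vectorized:
# annotations can carry tens of thousands of exon rows.
rank_exons <- function(df) {
  stop_if_not(all(df$strand %in% c("+", "-")),
              "exons must be stranded (+ or -)")
  df <- df[order(df$gene_id, df$transcript_id, df$start, df$end), ,
           drop = FALSE]
  n <- nrow(df)
  tx <- df$transcript_id
  same <- if (n > 1) tx[-1] == tx[-n] else logical(0)
  if (any(same & (df$chrom[-1] != df$chrom[-n] |
                  df$strand[-1] != df$strand[-n]))) {
    bad <- tx[-1][same & (df$chrom[-1] != df$chrom[-n] |
                            df$strand[-1] != df$strand[-n])][1]
    stop(paste0("transcript ", bad, " mixes chromosomes or strands"),
         call. = FALSE)
  }
  if (any(same & df$start[-1] < df$end[-n])) {
    bad <- tx[-1][same & df$start[-1] < df$end[-n]][1]
    stop(paste0("transcript ", bad, " has overlapping exons"), call. = FALSE)
  }
  first <- c(TRUE, !same)
  grp_start <- which(first)
  grp_len <- diff(c(grp_start, n + 1))
  pos <- sequence(grp_len)
  m <- rep(grp_len, grp_len)
  df$rank <- as.integer(ifelse(df$strand == "+", pos, m - pos + 1))
  rownames(df) <- NULL
  df[, c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
         "rank", "source")]
}

#' Write an annotation table as GTF
#'
#' Emits one `exon` line per row in Gencode attribute dialect; coordinates are
#' converted back to 1-based inclusive. Output is deterministic (sorted by
#' gene, transcript, genomic start).
#'
#' @param annotation Annotation table as returned by [read_gtf()].
#' @param path Output file path.
#' @export
write_gtf <- function(annotation, path) {
  ann <- annotation[order(annotation$gene_id, annotation$transcript_id,
                          annotation$start), , drop = FALSE]
  lines <- sprintf(
    "%s\tafetools\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ann$chrom, as.integer(ann$start + 1), as.integer(ann$end), ann$strand,
    ann$gene_id, ann$transcript_id)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED coordinates are taken verbatim as 0-based half-open. With
#' `scored = TRUE` column 5 is parsed as a numeric score.
#'
#' @param path BED file path.
#' @param scored Require and parse the score column?
#' @return Interval table with columns `chrom`, `start`, `end`, `strand`,
#'   `name` (BED6 only) and `score` (when `scored`).
#' @export
read_bed <- function(path, scored = FALSE) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i), call. = FALSE)
    }
    if (as.numeric(f[2]) >= as.numeric(f[3])) {
      stop(sprintf("rejected record at BED line %d: start >= end", i), call. = FALSE)
    }
    if (scored && length(f) < 5) {
      stop(sprintf("rejected record at BED line %d: no score column", i), call. = FALSE)
    }
  }
  gr <- rtracklayer::import(path, format = "bed")
  df <- granges_to_df(gr)
  if (!is.null(gr$name)) df$name <- as.character(gr$name)
  if (scored) df$score <- as.numeric(gr$score)
  df
}

#' Write intervals as BED
#'
#' Writes BED6 when `name`/`score`/strand information is present, BED3
#' otherwise.
#'
#' @param x Interval table.
#' @param path Output file path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  bed6 <- !is.null(x$name) || !is.null(x$score) || any(x$strand != ".")
  lines <- if (bed6) {
    nm <- x$name %||% rep(".", nrow(x))
    sc <- x$score %||% rep(0, nrow(x))
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), nm,
            format(sc, scientific = FALSE, trim = TRUE), x$strand)
  } else {
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a count table
#'
#' @param counts Non-negative integer matrix, features in rows (unique
#'   rownames), samples in columns.
#' @param condition Named character vector mapping every sample (column) to a
#'   condition label.
#' @return A `count_table` object (list with `counts` and `condition`).
#' @export
count_table <- function(counts, condition) {
  counts <- as.matrix(counts)
  stop_if_not(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique rownames")
  stop_if_not(!is.null(colnames(counts)), "counts must have column names")
  stop_if_not(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  stop_if_not(all(colnames(counts) %in% names(condition)),
              "every sample needs a condition label")
  structure(list(counts = counts,
                 condition = condition[colnames(counts)]),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Write a count table and its sample-condition sidecar
#'
#' @param x A [count_table()].
#' @param counts_path TSV output: header `feature_id` then sample ids.
#' @param conditions_path Two-column TSV `sample`, `condition`.
#' @export
write_count_table <- function(x, counts_path, conditions_path) {
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample = names(x$condition),
                       condition = unname(x$condition),
                       stringsAsFactors = FALSE), conditions_path)
  invisible(counts_path)
}

#' Read a count table and its sample-condition sidecar
#'
#' @param counts_path TSV with header `feature_id` then sample ids.
#' @param conditions_path Two-column TSV mapping sample to condition.
#' @return A [count_table()].
#' @export
read_count_table <- function(counts_path, conditions_path) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  cond <- read_tsv(conditions_path)
  count_table(m, setNames(cond$condition, cond$sample))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
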
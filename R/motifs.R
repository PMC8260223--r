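# 5'UTR regulatory-motif scanning: iron-responsive element (IRE) stem-loops,
# Musashi binding elements (MBE), a motif census over sequence sets, and a
# base-pair-maximization hairpin support score.

norm_seq <- function(seq) {
  s <- chartr("uU", "TT", toupper(seq))
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(paste0("illegal sequence characters: ", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  chars
}

# Watson-Crick or G.U wobble pairing on DNA-spelled RNA; N never pairs.
base_pairs <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Scan a sequence for IRE-like stem-loops
#'
#' The detector models the IRE upper element: a 6-nt apical loop matching
#' C-A-G-N-G-N (`canonical_loop = TRUE` restricts to the canonical CAGUGH,
#' H = not G), a 5-bp upper stem formed by the 5 nt on each side of the loop
#' paired antiparallel (Watson-Crick or G·U; at least `min_pairs` of 5
#' paired), and an unpaired C bulge as the single nucleotide immediately 5'
#' of the stem. Overlapping hits are all reported; scanning is
#' sense-strand only and case/T-U-spelling invariant.
#'
#' @param seq Nucleotide string over `A,C,G,T,U,N`.
#' @param min_pairs Minimum paired stem positions of 5 (default 4, i.e. at
#'   most one mismatch).
#' @param canonical_loop Require the canonical CAGUGH loop?
#' @return `data.frame` of hits: `loop_start` (0-based), `loop_seq`,
#'   `stem_pairs`, `mismatches`, `bulge_c_offset`, `start`, `end` (0-based
#'   half-open span of bulge + stem + loop).
#' @export
scan_ire <- function(seq, min_pairs = 4, canonical_loop = FALSE) {
  empty <- data.frame(loop_start = integer(0), loop_seq = character(0),
                      stem_pairs = integer(0), mismatches = integer(0),
                      bulge_c_offset = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  s <- norm_seq(seq)
  n <- length(s)
  if (n < 18) return(empty)
  # candidate loop starts i (1-based): need bulge at i-6 and 3' arm to i+10
  idx <- which(s == "C")
  idx <- idx[idx >= 7 & idx + 10 <= n]
  if (canonical_loop) {
    ok <- s[idx + 1] == "A" & s[idx + 2] == "G" & s[idx + 3] == "T" &
      s[idx + 4] == "G" & s[idx + 5] != "G" & s[idx + 5] != "N"
  } else {
    ok <- s[idx + 1] == "A" & s[idx + 2] == "G" & s[idx + 4] == "G" &
      s[idx + 3] != "N" & s[idx + 5] != "N"
  }
  idx <- idx[ok]
  hits <- lapply(idx, function(i) {
    arm5 <- s[(i - 5):(i - 1)]
    arm3 <- s[(i + 6):(i + 10)]
    np <- sum(base_pairs(arm5, rev(arm3)))
    if (np < min_pairs || s[i - 6] != "C") return(NULL)
    data.frame(loop_start = i - 1L,
               loop_seq = paste(s[i:(i + 5)], collapse = ""),
               stem_pairs = as.integer(np),
               mismatches = 5L - as.integer(np),
               bulge_c_offset = i - 7L,
               start = i - 7L, end = i + 10L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits %||% empty
}

#' Scan for Musashi binding elements
#'
#' All (possibly overlapping) matches of the degenerate consensus
#' `(G|A) U{1,3} A G U` on the given strand, T and U equivalent.
#'
#' @param seq Nucleotide string.
#' @return `data.frame` of hits: `start` (0-based), `end`, `match`.
#' @export
scan_mbe <- function(seq) {
  s <- norm_seq(seq)
  txt <- paste(s, collapse = "")
  m <- gregexpr("(?=([GA]T{1,3}AGT))", txt, perl = TRUE)[[1]]
  empty <- data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1]
  data.frame(start = starts - 1L, end = starts - 1L + lens,
             match = substring(txt, starts, starts + lens - 1),
             stringsAsFactors = FALSE)
}

#' Motif census over inclusion vs exclusion sequence sets
#'
#' Applies each scanner to both labelled sequence sets and tabulates total
#' and per-sequence hit counts plus the inclusion:exclusion ratio.
#'
#' @param inclusion_seqs,exclusion_seqs Named character vectors.
#' @param scanners Named list of scanner functions returning a hit
#'   `data.frame` (default IRE and MBE).
#' @return List per motif class: `inclusion_total`, `exclusion_total`,
#'   `ratio`, and per-sequence count tables.
#' @export
motif_census <- function(inclusion_seqs, exclusion_seqs,
                         scanners = list(IRE = scan_ire, MBE = scan_mbe)) {
  count_set <- function(seqs, scanner) {
    if (!length(seqs)) {
      return(data.frame(seq_id = character(0), hits = integer(0)))
    }
    data.frame(seq_id = names(seqs),
               hits = vapply(seqs, function(x) nrow(scanner(x)), integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- lapply(scanners, function(sc) {
    inc <- count_set(inclusion_seqs, sc)
    exc <- count_set(exclusion_seqs, sc)
    list(inclusion_total = sum(inc$hits),
         exclusion_total = sum(exc$hits),
         ratio = if (sum(exc$hits) == 0) NA_real_ else
           sum(inc$hits) / sum(exc$hits),
         inclusion = inc, exclusion = exc)
  })
  out
}

#' Maximum base-pair hairpin support score
#'
#' Nussinov-style dynamic program returning the maximum number of
#' non-crossing base pairs (Watson-Crick plus G·U) with a minimum loop of 3
#' unpaired nucleotides. A structural support score for short windows, not
#' a thermodynamic fold.
#'
#' @param seq Nucleotide string (window length <= 200).
#' @return Integer maximum pair count.
#' @export
hairpin_support <- function(seq) {
  s <- norm_seq(seq)
  n <- length(s)
  stop_if_not(n <= 200, "window length must be <= 200")
  if (n < 5) return(0L)
  dp <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i, j - 1]
      for (k in i:(j - 4)) {
        if (base_pairs(s[k], s[j])) {
          left <- if (k > i) dp[i, k - 1] else 0L
          inner <- dp[k + 1, j - 1]
          best <- max(best, left + inner + 1L)
        }
      }
      dp[i, j] <- best
    }
  }
  as.integer(dp[1, n])
}
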
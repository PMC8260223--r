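# Shared fixture builders and independent oracles used across test files.

# Minimal exon-table constructor (coordinates 0-based half-open).
make_annotation <- function(...) {
  recs <- list(...)
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(gene_id = r$gene, transcript_id = r$tx, chrom = r$chrom %||% "chr1",
               strand = r$strand, start = r$exons[, 1], end = r$exons[, 2],
               rank = NA_integer_, source = r$source %||% "reference",
               stringsAsFactors = FALSE)
  }))
  afetools:::rank_exons(df)
}

ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quadratic all-pairs overlap scan (independent of GenomicRanges).
brute_overlaps <- function(a, b, stranded = FALSE) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (stranded && a$strand[i] != "." && b$strand[j] != "." &&
          a$strand[i] != b$strand[j]) next
      if (a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a_idx = m[, 1], b_idx = m[, 2])
}

# Direct BH step-up reference (sort, cummin from the top, restore order).
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin((m / (m:1)) * p[o][m:1])[m:1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# DM pmf by the rising-factorial product form (no lgamma): independent of
# the implementation's log-gamma evaluation.
dm_loglik_product <- function(y, pi, phi) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  total <- 0
  for (s in seq_len(nrow(y))) {
    ys <- y[s, ]
    n <- sum(ys)
    lc <- lgamma(n + 1) - sum(lgamma(ys + 1))  # multinomial coefficient
    num <- 0
    for (j in seq_along(ys)) {
      if (ys[j] > 0) {
        if (pi[j] == 0) return(-Inf)
        num <- num + sum(log(phi * pi[j] + seq_len(ys[j]) - 1))
      }
    }
    den <- if (n > 0) sum(log(phi + seq_len(n) - 1)) else 0
    total <- total + lc + num - den
  }
  total
}

# Multinomial log-likelihood (the large-phi DM limit).
multinomial_loglik <- function(y, pi) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  tot <- 0
  for (s in seq_len(nrow(y))) {
    ys <- y[s, ]
    keep <- ys > 0
    if (any(keep & pi == 0)) return(-Inf)
    tot <- tot + lgamma(sum(ys) + 1) - sum(lgamma(ys + 1)) +
      sum(ys[keep] * log(pi[keep]))
  }
  tot
}

# Method-of-moments DM precision estimate from two-candidate count matrices
# (list of samples x 2 matrices, one per event), used to check the
# generator's planted phi.
mom_phi <- function(count_mats) {
  num <- 0; den <- 0
  for (y in count_mats) {
    n <- rowSums(y)
    keep <- n > 0
    y <- y[keep, , drop = FALSE]; n <- n[keep]
    if (nrow(y) < 2) next
    p <- y[, 1] / n
    pbar <- mean(p)
    if (pbar <= 0 || pbar >= 1) next
    v <- var(p)
    nbar <- mean(n)
    # var(p_s) ~ pbar(1-pbar) * (1/nbar + (1 - 1/nbar) * rho)
    rho <- (v / (pbar * (1 - pbar)) - 1 / nbar) / (1 - 1 / nbar)
    if (is.finite(rho)) { num <- num + rho; den <- den + 1 }
  }
  rho_hat <- num / den
  1 / rho_hat - 1  # rho = 1/(phi+1)
}

# Naive sliding-window MBE scan: at each offset try U-run lengths 1..3.
mbe_naive <- function(seq) {
  s <- strsplit(chartr("uUtT", "TTTT", toupper(seq)), "")[[1]]
  hits <- 0
  for (i in seq_along(s)) {
    for (r in 1:3) {
      len <- 1 + r + 3
      if (i + len - 1 > length(s)) next
      w <- s[i:(i + len - 1)]
      if (w[1] %in% c("G", "A") && all(w[2:(1 + r)] == "T") &&
          identical(w[(2 + r):(4 + r)], c("A", "G", "T"))) {
        hits <- hits + 1
        break  # one hit per start (run length is forced by the next base)
      }
    }
  }
  hits
}

# Exhaustive non-crossing pairing maximum for short sequences (oracle for
# the hairpin DP). Enumerates all legal pairings recursively.
hairpin_brute <- function(seq) {
  s <- strsplit(chartr("uUtT", "TTTT", toupper(seq)), "")[[1]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  best <- function(i, j) {
    if (j - i < 4) return(0L)
    b <- best(i, j - 1)
    for (k in i:(j - 4)) {
      if (pairs_ok(s[k], s[j])) {
        left <- if (k > i) best(i, k - 1) else 0L
        b <- max(b, left + best(k + 1, j - 1) + 1L)
      }
    }
    b
  }
  if (length(s) < 5) return(0L)
  best(1L, length(s))
}

toy_cache <- new.env(parent = emptyenv())

# One moderately sized mixed-type synthetic dataset, reused across files.
shared_toy <- function() {
  if (is.null(toy_cache$toy)) {
    toy <- make_toy_annotation(n_genes = 40, afe_fraction = 0.5,
                               n_first_exons = 2, effect_fraction = 0.5,
                               delta_psi = 30, novel_fraction = 0.2,
                               novel_ir_fraction = 0.5, seed = 42)
    toy$events <- build_events(toy$annotation)
    toy$counts <- simulate_junction_counts(toy$annotation, toy$truth,
                                           seed = 43, events = toy$events)
    toy_cache$toy <- toy
  }
  toy_cache$toy
}

read_tsv_file <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Fixture for the coordinate-selection sign rule: three AFE events covering
# the three rule branches (own exon, sibling substitution, deduplication).
selection_fixture <- function() {
  row <- function(eid, cand, incl, delta, s, e, p = 0.01) {
    data.frame(event_id = eid, event_type = "AFE", novelty = "K",
               gene_id = paste0("g_", eid), chrom = "chr1", strand = "+",
               candidate = cand, inclusion = incl, exon_start = s,
               exon_end = e, mean_psi_control = 50,
               mean_psi_treated = 50 + delta, delta_psi = delta,
               p_raw = p, p_adj = p, test = "ttest", significant = NA,
               stringsAsFactors = FALSE)
  }
  rbind(
    # case 1: inclusion candidate up by 30 -> its own exon
    row("ev_up", 1, TRUE, 30, 1000, 1200),
    row("ev_up", 2, FALSE, -30, 5000, 5200),
    # case 2: inclusion candidate down by 30 -> the sibling's exon
    row("ev_down", 1, TRUE, -30, 11000, 11200),
    row("ev_down", 2, FALSE, 30, 15000, 15200),
    # case 3: duplicates case 1's selected exon -> emitted once
    row("ev_dup", 1, TRUE, 25, 1000, 1200),
    row("ev_dup", 2, FALSE, -25, 21000, 21200),
    # below the significance cutoff: ignored entirely
    row("ev_ns", 1, TRUE, 40, 31000, 31200, p = 0.2),
    row("ev_ns", 2, FALSE, -40, 35000, 35200, p = 0.2),
    # significant but all deltas inside [-10, 10]: contributes nothing
    row("ev_flat", 1, TRUE, 4, 41000, 41200),
    row("ev_flat", 2, FALSE, -4, 45000, 45200))
}

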
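# Synthetic-data generators with a complete ground-truth ledger. A single
# toy chromosome carries genes tiled at fixed spacing; every planted effect
# (PSI shifts, differential peaks, true TSS peaks, IRE motifs, DE genes) is
# recorded so downstream discoveries can be scored as TP/FP.

GENE_SPACING <- 50000
GENE_OFFSET <- 10000
TOY_CHROM <- "chrS"

#' Generate a toy annotation with planted splicing structures
#'
#' A fraction `afe_fraction` of genes carries `n_first_exons` distinct first
#' exons (each 200 bp, so candidate effective lengths are equal) splicing to
#' a shared downstream acceptor; the remaining genes cycle through cassette,
#' A5SS, A3SS, intron-retention, ALE and MXE structures in equal shares.
#' Strands alternate. A fraction `effect_fraction` of AFE genes receives a
#' planted delta PSI of `delta_psi` percent on candidate 2 (the
#' treatment-induced first exon, mirroring an inflammation-activated
#' promoter); all other events have identical proportions in both
#' conditions. `novel_fraction` of AFE genes have their candidate-2
#' transcript labelled `longread` (a novel first exon absent from the
#' reference); `novel_ir_fraction` of IR genes likewise get a long-read-only
#' retained form.
#'
#' @param n_genes Number of genes (>= 1).
#' @param afe_fraction Fraction of genes with an AFE structure.
#' @param n_first_exons First exons per AFE gene (>= 2).
#' @param effect_fraction Fraction of AFE genes with a planted effect.
#' @param delta_psi Planted delta PSI in percent (treated minus control on
#'   candidate 2; `<= 60` so proportions stay centered).
#' @param novel_fraction Fraction of AFE genes with a long-read-only first
#'   exon.
#' @param novel_ir_fraction Fraction of IR genes with a long-read-only
#'   retained form.
#' @param seed RNG seed.
#' @return List with `annotation` (exon table) and `truth` (ledger: per-event
#'   condition proportions and delta PSI, affected/novel gene sets, true TSS
#'   table, parameters).
#' @export
make_toy_annotation <- function(n_genes = 100, afe_fraction = 0.5,
                                n_first_exons = 2, effect_fraction = 0.3,
                                delta_psi = 30, novel_fraction = 0,
                                novel_ir_fraction = 0, seed = 1) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(afe_fraction >= 0 && afe_fraction <= 1,
              "afe_fraction must be in [0, 1]")
  stop_if_not(n_first_exons >= 2,
              "AFE genes need n_first_exons >= 2")
  stop_if_not(n_first_exons <= 3,
              "n_first_exons > 3 does not fit the fixed gene tiling")
  stop_if_not(delta_psi >= 0 && delta_psi <= 60,
              "delta_psi must be in [0, 60]")
  with_seed(seed, {
    n_afe <- round(afe_fraction * n_genes)
    other_types <- c("CASSETTE", "A5SS", "A3SS", "IR", "ALE", "MXE")
    types <- c(rep("AFE", n_afe),
               rep_len(other_types, n_genes - n_afe))
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    strands <- rep_len(c("+", "-"), n_genes)
    rows <- list()
    effects <- list()
    afe_genes <- gene_ids[types == "AFE"]
    affected <- sort(sample(afe_genes, round(effect_fraction * n_afe)))
    novel_afe <- sort(sample(afe_genes, round(novel_fraction * n_afe)))
    ir_genes <- gene_ids[types == "IR"]
    novel_ir <- sort(sample(ir_genes,
                            round(novel_ir_fraction * length(ir_genes))))
    add_tx <- function(gene, tx, strand, exons, source = "reference") {
      list(gene_id = gene, transcript_id = tx, strand = strand,
           start = exons[, 1], end = exons[, 2], source = source)
    }
    for (gi in seq_len(n_genes)) {
      g <- gene_ids[gi]
      ty <- types[gi]
      st <- strands[gi]
      o <- GENE_OFFSET + (gi - 1) * GENE_SPACING
      mk <- function(s, e) cbind(o + s, o + e)
      tx_rows <- switch(ty,
        AFE = {
          # first exons are spaced beyond the 10-kb promoter window so each
          # candidate's window covers only its own promoter
          J <- n_first_exons
          lapply(seq_len(J), function(k) {
            src <- if (g %in% novel_afe && k >= 2) "longread" else "reference"
            if (st == "+") {
              fe <- mk((k - 1) * 12000, (k - 1) * 12000 + 200)
              add_tx(g, sprintf("%s_t%d", g, k), st,
                     rbind(fe, mk(J * 12000, J * 12000 + 400),
                           mk(J * 12000 + 3000, J * 12000 + 3400)), src)
            } else {
              fe <- mk(15000 + (k - 1) * 12000, 15000 + (k - 1) * 12000 + 200)
              add_tx(g, sprintf("%s_t%d", g, k), st,
                     rbind(mk(0, 400), mk(3000, 3400), fe), src)
            }
          })
        },
        CASSETTE = list(
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(6000, 6200))),
          add_tx(g, paste0(g, "_t2"), st, rbind(mk(0, 200), mk(6000, 6200)))),
        A5SS = if (st == "+") list(
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(3000, 3400), mk(6000, 6200))),
          add_tx(g, paste0(g, "_t2"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(6000, 6200)))
        ) else list(
          # on minus strand the transcription-5' splice site varies at the
          # genomic-right end of the middle exon's intron boundary
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(2800, 3200), mk(6000, 6200))),
          add_tx(g, paste0(g, "_t2"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(6000, 6200)))),
        A3SS = if (st == "+") list(
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(2800, 3200), mk(6000, 6200))),
          add_tx(g, paste0(g, "_t2"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(6000, 6200)))
        ) else list(
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(3000, 3400), mk(6000, 6200))),
          add_tx(g, paste0(g, "_t2"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(6000, 6200)))),
        IR = list(
          add_tx(g, paste0(g, "_t1"), st, rbind(mk(0, 200), mk(3000, 3200))),
          add_tx(g, paste0(g, "_t2"), st, mk(0, 3200),
                 source = if (g %in% novel_ir) "longread" else "reference")),
        ALE = lapply(1:2, function(k) {
          if (st == "+") {
            le <- mk(6000 + (k - 1) * 3000, 6000 + (k - 1) * 3000 + 200)
            add_tx(g, sprintf("%s_t%d", g, k), st,
                   rbind(mk(0, 200), mk(3000, 3200), le))
          } else {
            le <- mk((k - 1) * 3000, (k - 1) * 3000 + 200)
            add_tx(g, sprintf("%s_t%d", g, k), st,
                   rbind(le, mk(9000, 9200), mk(12000, 12200)))
          }
        }),
        MXE = list(
          add_tx(g, paste0(g, "_t1"), st,
                 rbind(mk(0, 200), mk(3000, 3200), mk(9000, 9200))),
          add_tx(g, paste0(g, "_t2"), st,
                 rbind(mk(0, 200), mk(6000, 6200), mk(9000, 9200)))))
      rows[[g]] <- tx_rows

      # planted condition proportions over event candidates (count space;
      # AFE candidates share one effective length so PSI equals proportion)
      J <- if (ty == "AFE") n_first_exons else 2
      if (ty == "AFE" && g %in% affected) {
        rest_c <- (100 - (50 - delta_psi / 2)) / (J - 1)
        rest_t <- (100 - (50 + delta_psi / 2)) / (J - 1)
        psi_control <- c(rep(rest_c, J)); psi_control[2] <- 50 - delta_psi / 2
        psi_control[1] <- 100 - sum(psi_control[-1])
        psi_treated <- c(rep(rest_t, J)); psi_treated[2] <- 50 + delta_psi / 2
        psi_treated[1] <- 100 - sum(psi_treated[-1])
        d <- delta_psi
      } else {
        base <- runif(1, 20, 80)
        psi_control <- c(base, rep((100 - base) / (J - 1), J - 1))
        psi_treated <- psi_control
        d <- 0
      }
      effects[[paste(g, ty, sep = ":")]] <- list(
        gene_id = g, event_type = ty,
        psi = rbind(control = psi_control, treated = psi_treated),
        delta_psi = d, affected = ty == "AFE" && g %in% affected)
    }
    recs <- do.call(c, rows)
    nex <- vapply(recs, function(r) length(r$start), integer(1))
    annotation <- rank_exons(data.frame(
      gene_id = rep(vapply(recs, `[[`, character(1), "gene_id"), nex),
      transcript_id = rep(vapply(recs, `[[`, character(1),
                                 "transcript_id"), nex),
      chrom = TOY_CHROM,
      strand = rep(vapply(recs, `[[`, character(1), "strand"), nex),
      start = unlist(lapply(recs, `[[`, "start")),
      end = unlist(lapply(recs, `[[`, "end")),
      rank = NA_integer_,
      source = rep(vapply(recs, `[[`, character(1), "source"), nex),
      stringsAsFactors = FALSE))
    truth <- list(event_effects = effects,
                  gene_type = setNames(types, gene_ids),
                  afe_genes = afe_genes, affected_genes = affected,
                  novel_afe_genes = novel_afe, novel_ir_genes = novel_ir,
                  true_tss = extract_tss(annotation),
                  params = list(n_genes = n_genes,
                                afe_fraction = afe_fraction,
                                n_first_exons = n_first_exons,
                                effect_fraction = effect_fraction,
                                delta_psi = delta_psi,
                                novel_fraction = novel_fraction,
                                novel_ir_fraction = novel_ir_fraction,
                                seed = seed))
    list(annotation = annotation, truth = truth)
  })
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) {
    x[which.max(alpha)] <- 1
  }
  x / sum(x)
}

#' Simulate junction counts under the Dirichlet-multinomial model
#'
#' Per event and sample, the total count is Poisson(`depth`) and the
#' candidate split is Dirichlet-multinomial with the condition's true
#' proportions (from the truth ledger) and precision `precision` — the same
#' two-stage construction (Dirichlet draw, then multinomial) the fitted
#' model assumes.
#'
#' @param annotation,truth From [make_toy_annotation()].
#' @param n_per_condition Replicates per condition (default 3).
#' @param depth Mean per-event total count (default 200).
#' @param precision DM precision phi (> 0; default 50).
#' @param seed RNG seed.
#' @param conditions Condition labels, control first (default
#'   `c("control", "LPS")`; the second label is the treated group).
#' @param events Optional prebuilt event table for `annotation` (saves
#'   rebuilding when the caller already has one).
#' @return A [count_table()] keyed by event candidate `row_id`.
#' @export
simulate_junction_counts <- function(annotation, truth, n_per_condition = 3,
                                     depth = 200, precision = 50, seed = 1,
                                     conditions = c("control", "LPS"),
                                     events = NULL) {
  stop_if_not(depth > 0, "depth must be > 0")
  stop_if_not(precision > 0, "precision (phi) must be > 0")
  if (is.null(events)) events <- build_events(annotation)
  samples <- c(paste0(conditions[1], "_", seq_len(n_per_condition)),
               paste0(conditions[2], "_", seq_len(n_per_condition)))
  cond <- setNames(rep(conditions, each = n_per_condition), samples)
  with_seed(seed, {
    out <- matrix(0, nrow = nrow(events), ncol = length(samples),
                  dimnames = list(events$row_id, samples))
    for (eid in unique(events$event_id)) {
      idx <- which(events$event_id == eid)
      ev <- events[idx[1], ]
      key <- paste(ev$gene_id, ev$event_type, sep = ":")
      eff <- truth$event_effects[[key]]
      J <- length(idx)
      prop <- if (!is.null(eff) && ncol(eff$psi) == J) {
        eff$psi / 100
      } else {
        matrix(1 / J, nrow = 2, ncol = J,
               dimnames = list(c("control", "treated"), NULL))
      }
      for (si in seq_along(samples)) {
        p_true <- if (cond[si] == conditions[1]) prop[1, ] else prop[2, ]
        n_s <- rpois(1, depth)
        if (n_s == 0) next
        p_s <- rdirichlet1(precision * p_true)
        out[idx, si] <- rmultinom(1, n_s, p_s)
      }
    }
    count_table(out, cond)
  })
}

#' Simulate CAGE-like peaks around true TSSs
#'
#' A `true_rate` fraction of distinct true TSS positions receives a
#' high-scoring peak of width 20-50 bp centered on the TSS; `decoy_rate`
#' times as many low-scoring decoy peaks are placed far from every TSS.
#' The ledger records which peaks are true and which TSSs are covered.
#'
#' @param annotation,truth From [make_toy_annotation()].
#' @param true_rate Fraction of TSSs peaked (default 0.45).
#' @param decoy_rate Decoy peaks per TSS (default 0.5).
#' @param seed RNG seed.
#' @return List: `peaks` (scored interval table) and `truth` (ledger with
#'   `true_peaks`, `supported_tss`).
#' @export
simulate_cage_peaks <- function(annotation, truth, true_rate = 0.45,
                                decoy_rate = 0.5, seed = 1) {
  stop_if_not(true_rate >= 0 && true_rate <= 1 && decoy_rate >= 0,
              "rates must be valid fractions")
  tss <- truth$true_tss
  upos <- unique(tss[, c("chrom", "start")])
  with_seed(seed, {
    n <- nrow(upos)
    is_true <- runif(n) < true_rate
    pk <- list()
    for (i in which(is_true)) {
      w <- sample(20:50, 1)
      s <- max(0, upos$start[i] - w %/% 2)
      pk[[length(pk) + 1]] <- data.frame(
        chrom = upos$chrom[i], start = s, end = s + w, strand = ".",
        name = sprintf("cage_true_%04d", i),
        score = round(runif(1, 50, 1000)), stringsAsFactors = FALSE)
    }
    n_decoy <- round(decoy_rate * n)
    # decoys live in the inter-gene gaps, >= 5 kb from any gene body
    for (k in seq_len(n_decoy)) {
      tile <- sample(seq_len(max(1, length(unique(tss$gene_id)))), 1)
      s <- GENE_OFFSET + (tile - 1) * GENE_SPACING + 30000 + k %% 1000
      w <- sample(20:50, 1)
      pk[[length(pk) + 1]] <- data.frame(
        chrom = TOY_CHROM, start = s, end = s + w, strand = ".",
        name = sprintf("cage_decoy_%04d", k),
        score = round(runif(1, 1, 10)), stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, pk) %||%
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), name = character(0),
                 score = numeric(0))
    rownames(peaks) <- NULL
    supported <- merge(tss, upos[is_true, , drop = FALSE],
                       by = c("chrom", "start"))$transcript_id
    list(peaks = peaks,
         truth = list(true_peaks = peaks$name[grepl("true", peaks$name)],
                      supported_tss = sort(supported),
                      true_rate = true_rate))
  })
}

#' Simulate promoter peak count matrices with planted differential peaks
#'
#' Every AFE gene receives one consensus peak per assay ~2 kb upstream (in
#' transcription direction) of its candidate-2 first exon; an independent
#' `diff_fraction` subset per assay is planted differential: negative
#' binomial counts (`depth` mean, size `nb_size`) with the treated-condition
#' mean scaled by `2^effect_lfc`. Background peaks far from promoters are
#' added as overlap negatives. Note the planted fold change is on raw
#' means; CPM normalization absorbs part of it when many peaks shift.
#'
#' @param annotation,truth From [make_toy_annotation()].
#' @param assays Assay names (default accessibility + two TFs).
#' @param diff_fraction Fraction of AFE promoters differential per assay
#'   (default 0.25).
#' @param effect_lfc Planted log2 fold change on raw means (>= 0,
#'   default 4).
#' @param n_per_condition Replicates per condition (default 3).
#' @param depth Mean peak count (default 2000).
#' @param nb_size Negative-binomial size (default 50).
#' @param n_background Background peaks per assay (default 20).
#' @param seed RNG seed.
#' @param conditions Condition labels, control first.
#' @return Named list per assay: `peaks` (interval table with `name`),
#'   `counts` ([count_table()]), `diff_genes` (planted differential AFE
#'   genes), `diff_peaks` (their peak names).
#' @export
simulate_peak_counts <- function(annotation, truth,
                                 assays = c("accessibility", "p65", "IRF3"),
                                 diff_fraction = 0.25, effect_lfc = 4,
                                 n_per_condition = 3, depth = 2000,
                                 nb_size = 50, n_background = 20, seed = 1,
                                 conditions = c("control", "LPS")) {
  stop_if_not(effect_lfc >= 0, "effect_lfc must be >= 0")
  afe <- truth$afe_genes
  stop_if_not(length(afe) > 0, "annotation has no AFE genes")
  fe2 <- annotation[annotation$gene_id %in% afe & annotation$rank == 1, ,
                    drop = FALSE]
  # candidate 2 = second-leftmost first exon on +, mirrored position on -
  fe2 <- do.call(rbind, lapply(split(fe2, fe2$gene_id), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    x[2, , drop = FALSE]
  }))
  samples <- c(paste0(conditions[1], "_", seq_len(n_per_condition)),
               paste0(conditions[2], "_", seq_len(n_per_condition)))
  cond <- setNames(rep(conditions, each = n_per_condition), samples)
  with_seed(seed, {
    out <- list()
    for (assay in assays) {
      prom <- data.frame(
        chrom = fe2$chrom,
        start = ifelse(fe2$strand == "+", fe2$start - 2500, fe2$end + 2100),
        end = ifelse(fe2$strand == "+", fe2$start - 2100, fe2$end + 2500),
        strand = ".",
        name = sprintf("%s_pk_%s", assay, fe2$gene_id),
        gene_id = fe2$gene_id, stringsAsFactors = FALSE)
      bg <- data.frame(
        chrom = TOY_CHROM,
        start = GENE_OFFSET + seq_len(n_background) * GENE_SPACING - 12000,
        end = GENE_OFFSET + seq_len(n_background) * GENE_SPACING - 11600,
        strand = ".",
        name = sprintf("%s_bg_%03d", assay, seq_len(n_background)),
        gene_id = NA_character_, stringsAsFactors = FALSE)
      peaks <- rbind(prom, bg)
      diff_genes <- sort(sample(afe, round(diff_fraction * length(afe))))
      differential <- peaks$gene_id %in% diff_genes
      base <- runif(nrow(peaks), 0.7, 1.3) * depth
      mu <- cbind(matrix(base, nrow(peaks), n_per_condition),
                  matrix(base * ifelse(differential, 2^effect_lfc, 1),
                         nrow(peaks), n_per_condition))
      m <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = nb_size),
                  nrow = nrow(peaks),
                  dimnames = list(peaks$name, samples))
      out[[assay]] <- list(peaks = peaks, counts = count_table(m, cond),
                           diff_genes = diff_genes,
                           diff_peaks = peaks$name[differential],
                           planted = setNames(differential, peaks$name))
    }
    out
  })
}

#' Plant IRE motifs in random 5'UTR-like sequences
#'
#' Uniform-ACGT background sequences; an `ire_rate` fraction receives one
#' embedded canonical IRE (5' unpaired C bulge, fully paired 5-bp upper
#' stem, CAGUGH apical loop) at a recorded position.
#'
#' @param n_seqs Number of sequences.
#' @param length Sequence length (>= 30).
#' @param ire_rate Fraction with a planted IRE.
#' @param seed RNG seed.
#' @return List: `seqs` (named character vector) and `truth`
#'   (`planted`: `seq_id`, `element_start`, `loop_start`, 0-based).
#' @export
plant_utr_motifs <- function(n_seqs = 200, length = 150, ire_rate = 0.3,
                             seed = 1) {
  stop_if_not(length >= 30, "sequences must be >= 30 nt to host the element")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ids <- sprintf("utr_%04d", seq_len(n_seqs))
    seqs <- vapply(ids, function(i) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
    planted <- runif(n_seqs) < ire_rate
    rec <- list()
    for (i in which(planted)) {
      arm5 <- sample(bases, 5, replace = TRUE)
      arm3 <- rev(chartr("ACGT", "TGCA", arm5))
      loop <- c("C", "A", "G", "T", "G", sample(c("A", "C", "T"), 1))
      element <- paste(c("C", arm5, loop, arm3), collapse = "")
      pos <- sample(seq_len(length - nchar(element) + 1), 1)  # 1-based
      s <- seqs[[i]]
      substr(s, pos, pos + nchar(element) - 1) <- element
      seqs[[i]] <- s
      rec[[base::length(rec) + 1]] <- data.frame(
        seq_id = ids[i], element_start = pos - 1L,
        loop_start = pos - 1L + 6L, stringsAsFactors = FALSE)
    }
    planted_df <- do.call(rbind, rec) %||%
      data.frame(seq_id = character(0), element_start = integer(0),
                 loop_start = integer(0))
    list(seqs = seqs, truth = list(planted = planted_df,
                                   ire_rate = ire_rate))
  })
}

#' Simulate a differential-expression gene table with planted DE genes
#'
#' A stand-in for an externally produced gene-level DE fit: a `de_fraction`
#' subset of genes is planted differentially expressed (`|log2FC| >=
#' lfc_min`, `p_adj <= alpha`); the rest fall below one or both thresholds.
#'
#' @param genes Gene ids.
#' @param de_fraction Planted DE fraction (default 0.5).
#' @param lfc_min,alpha Thresholds the planted genes clear (defaults 2 and
#'   0.05).
#' @param seed RNG seed.
#' @return List: `table` (`gene`, `log2fc`, `p_adj`) and `de_genes`.
#' @export
simulate_de_table <- function(genes, de_fraction = 0.5, lfc_min = 2,
                              alpha = 0.05, seed = 1) {
  with_seed(seed, {
    de <- sort(sample(genes, round(de_fraction * length(genes))))
    is_de <- genes %in% de
    lfc <- ifelse(is_de,
                  sample(c(-1, 1), length(genes), replace = TRUE) *
                    (lfc_min + rexp(length(genes), 1)),
                  rnorm(length(genes), 0, lfc_min / 4))
    lfc[!is_de] <- pmin(pmax(lfc[!is_de], -lfc_min + 0.1), lfc_min - 0.1)
    p <- ifelse(is_de, runif(length(genes), 1e-10, alpha),
                runif(length(genes), min(1, alpha * 2), 1))
    list(table = data.frame(gene = genes, log2fc = lfc, p_adj = p,
                            stringsAsFactors = FALSE),
         de_genes = de)
  })
}
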
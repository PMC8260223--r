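test_that("toy annotation generator respects structure parameters", {
  one <- make_toy_annotation(n_genes = 1, afe_fraction = 1,
                             n_first_exons = 2, seed = 3)
  ev <- build_events(one$annotation)
  expect_equal(unique(ev$event_type), "AFE")
  expect_equal(nrow(ev), 2)  # one event, two candidates
  # the two transcripts share every exon except the first
  ann <- one$annotation
  shared <- ann[ann$rank > 1, c("start", "end")]
  expect_equal(shared[ann$transcript_id[ann$rank > 1] == unique(ann$transcript_id)[1], ],
               shared[ann$transcript_id[ann$rank > 1] == unique(ann$transcript_id)[2], ],
               ignore_attr = TRUE)

  none <- make_toy_annotation(n_genes = 12, afe_fraction = 0, seed = 3)
  ev0 <- build_events(none$annotation)
  expect_false("AFE" %in% ev0$event_type)
  expect_error(make_toy_annotation(n_genes = 2, n_first_exons = 1),
               "n_first_exons")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- make_toy_annotation(n_genes = 10, seed = 99)
  b <- make_toy_annotation(n_genes = 10, seed = 99)
  expect_identical(a, b)
  ca <- simulate_junction_counts(a$annotation, a$truth, seed = 5)
  cb <- simulate_junction_counts(b$annotation, b$truth, seed = 5)
  expect_identical(ca$counts, cb$counts)
  pa <- plant_utr_motifs(n_seqs = 20, seed = 7)
  pb <- plant_utr_motifs(n_seqs = 20, seed = 7)
  expect_identical(pa, pb)
})

test_that("event detection recovers the planted event-type census exactly", {
  toy <- make_toy_annotation(n_genes = 100, afe_fraction = 0.4,
                             n_first_exons = 3, seed = 31)
  ev <- build_events(toy$annotation)
  u <- unique(ev[, c("event_id", "event_type", "gene_id")])
  expect_false(any(duplicated(u$gene_id)))  # exactly one event per toy gene
  expect_equal(unname(toy$truth$gene_type[u$gene_id]), u$event_type)
  expect_equal(as.vector(table(u$event_type)[names(table(toy$truth$gene_type))]),
               as.vector(table(toy$truth$gene_type)))
})

test_that("junction counts follow the planted DM model", {
  toy <- shared_toy()
  cnt <- toy$counts
  ev <- toy$events
  # non-negative integers; candidates sum to the drawn event total
  expect_true(all(cnt$counts >= 0))
  expect_true(all(cnt$counts == round(cnt$counts)))

  # null events: mean observed delta PSI about zero
  null_genes <- setdiff(toy$truth$afe_genes, toy$truth$affected_genes)
  psi <- psi_table(ev, cnt)
  incl <- ev$event_type == "AFE" & ev$candidate == 2 &
    ev$gene_id %in% null_genes
  d <- rowMeans(psi$psi[incl, cnt$condition == "LPS"], na.rm = TRUE) -
    rowMeans(psi$psi[incl, cnt$condition == "control"], na.rm = TRUE)
  expect_lt(abs(mean(d, na.rm = TRUE)), 6)

  # affected events: mean observed delta near the planted value
  aff <- ev$event_type == "AFE" & ev$candidate == 2 &
    ev$gene_id %in% toy$truth$affected_genes
  da <- rowMeans(psi$psi[aff, cnt$condition == "LPS"], na.rm = TRUE) -
    rowMeans(psi$psi[aff, cnt$condition == "control"], na.rm = TRUE)
  expect_lt(abs(mean(da) - 30), 8)
})

test_that("large precision concentrates sample PSI at the truth", {
  toy <- make_toy_annotation(n_genes = 30, afe_fraction = 1,
                             effect_fraction = 0, seed = 61)
  ev <- build_events(toy$annotation)
  tight <- simulate_junction_counts(toy$annotation, toy$truth,
                                    depth = 1e4, precision = 1e6, seed = 62,
                                    events = ev)
  loose <- simulate_junction_counts(toy$annotation, toy$truth,
                                    depth = 1e4, precision = 5, seed = 62,
                                    events = ev)
  spread <- function(cnt) {
    psi <- psi_table(ev, cnt)
    mean(apply(psi$psi[ev$candidate == 1, ], 1, sd), na.rm = TRUE)
  }
  expect_lt(spread(tight), 1)        # multinomial limit: tiny spread
  expect_gt(spread(loose), 5 * spread(tight))
})

test_that("method-of-moments recovers the generator's precision", {
  toy <- make_toy_annotation(n_genes = 400, afe_fraction = 1,
                             effect_fraction = 0, seed = 71)
  ev <- build_events(toy$annotation)
  cnt <- simulate_junction_counts(toy$annotation, toy$truth, depth = 500,
                                  precision = 30, seed = 72, events = ev)
  mats <- lapply(unique(ev$event_id), function(eid) {
    t(cnt$counts[ev$row_id[ev$event_id == eid], , drop = FALSE])
  })
  phi_hat <- mom_phi(mats)
  expect_gt(phi_hat, 30 * 0.8)
  expect_lt(phi_hat, 30 * 1.2)
})

test_that("CAGE peak generator matches its ledger", {
  toy <- shared_toy()
  all_on <- simulate_cage_peaks(toy$annotation, toy$truth, true_rate = 1,
                                decoy_rate = 0, seed = 5)
  n_tss <- nrow(unique(toy$truth$true_tss[, c("chrom", "start")]))
  expect_equal(length(all_on$truth$true_peaks), n_tss)
  expect_setequal(all_on$truth$supported_tss,
                  toy$truth$true_tss$transcript_id)

  off <- simulate_cage_peaks(toy$annotation, toy$truth, true_rate = 0,
                             decoy_rate = 0.5, seed = 5)
  expect_length(off$truth$true_peaks, 0)

  mixed <- simulate_cage_peaks(toy$annotation, toy$truth, true_rate = 0.6,
                               decoy_rate = 0.4, seed = 6)
  # every true peak covers its TSS; decoys cover none
  tsspos <- unique(toy$truth$true_tss[, c("chrom", "start", "end", "strand")])
  hits <- intersect_intervals(mixed$peaks, tsspos)
  covered <- mixed$peaks$name[unique(hits$a_idx)]
  expect_setequal(covered, mixed$truth$true_peaks)
})

test_that("UTR motif planting matches its ledger", {
  p0 <- plant_utr_motifs(n_seqs = 50, ire_rate = 0, seed = 8)
  expect_equal(nrow(p0$truth$planted), 0)
  p1 <- plant_utr_motifs(n_seqs = 50, ire_rate = 1, seed = 8)
  expect_equal(nrow(p1$truth$planted), 50)
  # every planted element is present with a fully paired stem at its
  # recorded position
  for (i in seq_len(10)) {
    h <- scan_ire(p1$seqs[[p1$truth$planted$seq_id[i]]])
    expect_true(p1$truth$planted$loop_start[i] %in% h$loop_start)
    expect_equal(h$stem_pairs[h$loop_start == p1$truth$planted$loop_start[i]], 5L)
  }
  expect_error(plant_utr_motifs(n_seqs = 5, length = 20), ">= 30")
})

test_that("peak count generator plants recoverable differential peaks", {
  toy <- shared_toy()
  sims <- simulate_peak_counts(toy$annotation, toy$truth,
                               assays = c("accessibility", "p65"),
                               seed = 9)
  expect_named(sims, c("accessibility", "p65"))
  for (assay in names(sims)) {
    sim <- sims[[assay]]
    dp <- differential_peaks(sim$peaks, sim$counts,
                             lfc_min = 0.8, p_min = 0.15)
    # sensitivity >= 90% on planted peaks under the accessibility preset
    sens <- mean(dp$differential[dp$name %in% sim$diff_peaks])
    expect_gte(sens, 0.9)
    # no spurious calls among unplanted peaks
    fp <- mean(dp$differential[!dp$name %in% sim$diff_peaks])
    expect_lte(fp, 0.05)
  }
  # an effect-free run yields no calls above the threshold noise floor
  null_sim <- simulate_peak_counts(toy$annotation, toy$truth,
                                   assays = "accessibility",
                                   effect_lfc = 0, seed = 10)$accessibility
  dp0 <- differential_peaks(null_sim$peaks, null_sim$counts,
                            lfc_min = 0.8, p_min = 0.15)
  expect_lte(mean(dp0$differential), 0.05)
})

test_that("planted DE table clears exactly the configured thresholds", {
  genes <- sprintf("g%03d", 1:80)
  de <- simulate_de_table(genes, de_fraction = 0.5, seed = 12)
  tab <- de$table
  called <- tab$gene[abs(tab$log2fc) >= 2 & tab$p_adj <= 0.05]
  expect_setequal(called, de$de_genes)
  expect_equal(length(de$de_genes), 40)
})
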
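# afetools

Alternative first exon (AFE) usage analysis from splice-junction counts.

Inflammatory stimulation of macrophages shifts which promoter — and hence
which first exon and 5′UTR — many immune genes use, without necessarily
changing overall expression. `afetools` implements the full analysis chain
for studying such events: splicing-event construction and classification,
percent-spliced-in (PSI) quantification, dual differential-usage testing,
transcription-start-site (TSS) validation against CAGE peaks, promoter
regulatory attribution against differential chromatin-accessibility and
transcription-factor-binding peaks, and 5′UTR scanning for iron-responsive
elements (IRE) and Musashi binding elements (MBE). A synthetic-data
generator with a complete ground-truth ledger makes every stage testable
without external sequencing data.

## The model in brief

For a splicing event with candidates indexed by *j*, per-sample abundance
is the read count divided by the candidate's effective length (exon widths
plus a fixed junction sequence length), and

```
PSI_j = 100 · abundance_j / Σ_k abundance_k
```

Differential usage between control and treated (LPS) conditions is tested
two ways:

* **t-test route** — pooled-variance two-sample t-test on per-sample PSI,
  gated at an observed |ΔPSI| ≥ 5, BH-adjusted;
* **Dirichlet-multinomial route** — candidate counts *y*ₛ are modelled as
  DM(*n*ₛ; π, φ); the likelihood-ratio statistic compares per-condition
  proportions against shared proportions, each model maximized over its
  own precision φ, with a small-sample F reference that converges to the
  χ² tail as replicates grow.

Events are reported significant at adjusted p ≤ 0.25 and |ΔPSI| ≥ 10, and
gene sets are taken as the union over the two routes. Significant AFE
exons, selected by a ΔPSI sign rule, get 10-kb upstream promoter windows
that are intersected with differential peaks per assay (accessibility:
log2FC > 0.8, raw p < 0.15; TF: log2FC > 1, adjusted p < 0.25) to form an
UpSet partition of regulatory attributions.

## Worked example

A synthetic cohort with known truth: 60 genes, half with AFE structures,
12 genes planted with a ΔPSI of +30 on the treatment-induced first exon,
3 + 3 replicates at depth 300 and DM precision 50.

```r
library(afetools)

toy    <- make_toy_annotation(n_genes = 60, afe_fraction = 0.5,
                              effect_fraction = 0.4, delta_psi = 30, seed = 1)
counts <- simulate_junction_counts(toy$annotation, toy$truth,
                                   n_per_condition = 3, depth = 300,
                                   precision = 50, seed = 2)
events <- build_events(toy$annotation)
res    <- dm_lrt(events, counts, treated = "LPS")
sig    <- significant_events(res, alpha = 0.25, delta = 10)
head(sig[sig$candidate == 2,
         c("event_id", "gene_id", "mean_psi_control", "mean_psi_treated",
           "delta_psi", "p_adj")], 5)
```

```
      event_id gene_id mean_psi_control mean_psi_treated delta_psi  p_adj
2  AFE_g0001_1   g0001             30.5             68.7      38.3 0.0663
4  AFE_g0002_1   g0002             29.4             59.0      29.6 0.0135
6  AFE_g0004_1   g0004             37.8             63.3      25.5 0.0663
8  AFE_g0007_1   g0007             27.1             69.5      42.4 0.0188
10 AFE_g0010_1   g0010             43.6             63.4      19.8 0.0192
```

Each row is the treatment-induced first exon of one gene: its mean PSI in
control and LPS samples, the shift (all near the planted +30), and the
BH-adjusted DM p-value.

The motif scanner applied to the two packaged Aim2 5′UTR sequences (a
canonical and an unannotated, inflammation-induced 5′UTR) finds exactly
one IRE-like stem-loop, in the unannotated sequence only:

```r
utrs <- read_fasta(system.file("extdata", "aim2_5utr.fa", package = "afetools"))
scan_ire(utrs[["Aim2_5UTR_unannotated"]])
```

```
  loop_start loop_seq stem_pairs mismatches bulge_c_offset start end
1         95   CAGAGC          5          0             89    89 106
```

— a C-A-G-N-G-N loop on a fully paired 5-bp stem (three Watson–Crick plus
two G·U pairs) with the required 5′ C bulge. `scan_ire` of the annotated
5′UTR returns zero rows.

The end-to-end pipeline (`afe_config()` + `run_pipeline()`) chains all
stages, writes every intermediate table plus a JSON manifest, and is
byte-identical across reruns with the same seed. A thin command-line
wrapper lives in `inst/scripts/run_afe_pipeline.R`:

```sh
Rscript inst/scripts/run_afe_pipeline.R --outdir afe_run --seed 1 --n-genes 60
```

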
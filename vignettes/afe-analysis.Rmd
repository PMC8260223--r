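---
title: "Quantifying and attributing alternative first exon usage"
author: "afetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and attributing alternative first exon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afetools)
```

## The problem

Inflammatory stimulation of macrophages changes not only how much of each
gene is transcribed but *which isoform* is made. A large share of
stimulus-induced splicing changes are alternative first exon (AFE) events:
the same gene transcribed from two or more promoters, each contributing a
distinct first exon spliced onto a shared downstream acceptor. Because the
first exon carries the 5'UTR, switching it can rewire post-transcriptional
control — the motivating example being an inflammation-induced isoform whose
longer 5'UTR contains an iron-responsive element (IRE) that represses
translation under iron-replete conditions.

`afetools` implements that analysis chain as testable components:

1. event construction and classification from transcript annotation
   (AFE, ALE, cassette, mutually exclusive exons, A5'SS/A3'SS, intron
   retention), with known/novel labelling against the reference source;
2. percent-spliced-in (PSI) quantification from length-normalized
   candidate abundances;
3. differential isoform usage by two routes: a per-candidate t-test on PSI
   and a per-event Dirichlet-multinomial (DM) likelihood-ratio test;
4. transcription start site (TSS) extraction, known/novel classification
   and CAGE-peak support scoring;
5. promoter regulatory attribution of significant AFE events against
   differential chromatin-accessibility and TF-binding peaks (the UpSet
   partition);
6. 5'UTR motif scanning (IRE stem-loops, Musashi binding elements) and a
   base-pair-maximization hairpin support score.

A synthetic-data generator with a complete ground-truth ledger stands in
for sequencing data, so every stage is verifiable end to end.

## Coordinates and events

All internal coordinates are 0-based half-open (BED convention); GTF input
is converted on read and back on write. A single convention everywhere
avoids off-by-one drift between the exon, junction, peak and window
arithmetic.

An event is a set of two or more *candidates* for one gene. For AFE events
the candidates are the distinct, mutually non-overlapping first exons whose
first junctions share one downstream acceptor; overlapping first-exon
variants are A5'SS/A3'SS events instead, which is what distinguishes a
promoter switch from a splice-site shift. Each candidate's parts (exons and
junctions) determine its effective length: exon parts contribute their
width, junction parts a fixed `jcn_seq_len` (default 88 nt, the
junction-spanning sequence length of a short-read run; 238 for runs against
a long-read-merged annotation). PSI for a candidate in a sample is its
length-normalized abundance as a percentage of the event total, and is set
missing when the event's raw total in that sample is below
`count_threshold` (default 10 reads) — a per-sample support rule, the
simplest reading of the usual read-support flag.

## The Dirichlet-multinomial test

Candidate counts \(y_s\) for sample \(s\) (total \(n_s\)) are modelled as
DM with proportions \(\pi\) and precision \(\phi\): samples first draw
\(p_s \sim \mathrm{Dirichlet}(\phi\pi)\), then
\(y_s \sim \mathrm{Multinomial}(n_s, p_s)\). Large \(\phi\) recovers the
multinomial; small \(\phi\) adds the between-replicate overdispersion real
junction counts show. The alternative model gives each condition its own
\(\pi\) with a shared \(\phi\); the null shares one \(\pi\).

Fitting profiles \(\phi\) on a log-spaced grid refined by golden-section
search. At fixed \(\phi\) the proportion estimate is the
expected-proportion fixpoint — the stationary point of
\(\pi \mapsto \mathrm{mean}_s[(y_s + \phi\pi)/(n_s + \phi)]\), which has
the closed form \(\pi_j \propto \sum_s y_{sj}/(n_s + \phi)\) — polished at
the selected \(\phi\) by direct likelihood maximization (`optimize` for
two candidates, Nelder–Mead otherwise), because the fixpoint is a
posterior-mean heuristic rather than the exact MLE. Both nested models are
maximized over their *own* precision, so the likelihood-ratio statistic
compares two fully maximized models.

**Reference distribution.** With the few replicates this design targets
(3 + 3 is typical), the asymptotic \(\chi^2\) tail of the LRT is
substantially anticonservative: the statistic behaves like a two-group
location comparison with an estimated variance component, for which the
normal-theory ML ratio satisfies
\(\mathrm{LRT} = S\log(1 + t^2/(S - C))\) with \(t\) the pooled
t-statistic, \(S\) samples and \(C\) conditions. `dm_lrt` therefore inverts
that relation and refers
\(F = \frac{S - C}{\mathrm{df}}\,(e^{\mathrm{LRT}/S} - 1)\) to
\(F(\mathrm{df},\, S - C)\), which converges to the \(\chi^2\) tail as
\(S\) grows. The plain asymptotic tail remains available via
`reference = "chisq"`. The package's calibration suite (2,000 null events,
3 + 3 replicates, depth 200, \(\phi = 50\)) verifies near-uniform null
p-values under the F reference.

Expression filters mirror the standard two-level rule: an event is tested
only if enough samples express it (`min_samps_gene_expr` samples at
`min_gene_expr` reads; defaults 6 and 10 — the mouse preset; a human-style
8/4 preset is a matter of passing different values), and every candidate
must reach `min_feature_expr` in `min_samps_feature_expr` samples.

## The t-test route and the two thresholds

`ttest_diff` runs a pooled-variance two-sample t-test on per-sample PSI
(Welch by flag). Two distinct knobs exist on purpose: `delta_thresh`
(default 5 percentage points) gates *testing* — candidates with a smaller
observed shift get no p-value — while the significance filter
(`significant_events`, default adjusted p \(\le 0.25\) and
\(|\Delta\mathrm{PSI}| \ge 10\), strict preset \(\alpha = 0.05\)) gates
*reporting*. Novel intron-retention rows are removed at the significance
step, reflecting the low confidence of unannotated retention calls.
Benjamini–Hochberg adjustment runs over assigned p-values only; missing
values are first-class and excluded from the test count. Note that the
testing gate selects on the observed effect, so null-calibration checks in
this package always lift it (`delta_thresh = 0`): calibration is a property
of the statistic, not of the gated pipeline.

BH adjustment is applied globally per test, not within event-type strata;
stratified adjustment would change the AFE share only marginally and the
global rule matches the single result table the pipeline emits.

## AFE promoter attribution

Significant AFE events (raw p \(< 0.05\) for this step, a deliberately
stricter gate than the discovery threshold) are reduced to exon
coordinates by a sign rule: an inclusion candidate shifted up by more than
10 points contributes its own exon; one shifted down by more than 10
contributes every sibling candidate shifted up by more than 10 (the
exon that gained usage); duplicate coordinates collapse. Windows extend
10 kb 5' of the exon — strand-aware by default, because promoters lie 5'
of the TSS even though a literal genomic-left reading is available
(`stranded = FALSE`).

Differential peaks are called from consensus-peak count matrices with a
deliberately simple statistic: CPM normalization, log2 fold change of mean
CPM (+0.5 pseudocount), and a t-test on per-sample log-CPM with BH
adjustment. This is a thresholding device for pre-called peaks, not a
count-model fit; the quoted thresholds are applied verbatim and are
asymmetric by design — accessibility: log2FC \(> 0.8\) at raw
p \(< 0.15\); TF binding: log2FC \(> 1\) at adjusted p \(< 0.25\).
Accessibility peaks are pre-merged when closer than 10 bp (strict `<`,
with a flag for the closed-gap convention); peaks are treated as
unstranded. An event's partition label is the exact set of assays with at
least one differential peak (\(\ge\) 1 bp) in its window — the UpSet
decomposition.

## Motif scanning

The IRE detector models the element's upper part: a 6-nt apical loop
matching C-A-G-N-G-N, a 5-bp upper stem formed by the flanking 5-mers
paired antiparallel (Watson–Crick or G·U, at least `min_pairs` of 5;
default 4, i.e. one tolerated mismatch), and an unpaired C immediately 5'
of the stem. The loop consensus is deliberately degenerate: the canonical
CAGUGH loop is available behind `canonical_loop = TRUE`, but the default
admits near-canonical loops that full-motif-catalog predictors accept,
which is what the packaged worked example requires — scanning the two
bundled Aim2 5'UTR sequences finds exactly one element (loop CAGAGC, five
paired stem positions: three Watson–Crick and two G·U) in the unannotated
UTR and none in the annotated one. The alternative internal-loop IRE
variant (UGC/C) is not modelled. Scanning is sense-strand only: 5'UTRs are
supplied in mRNA sense, and an IRE is not reverse-complement symmetric.

`hairpin_support` is a Nussinov-style maximum base-pair dynamic program
(Watson–Crick + G·U, minimum loop 3). It is a structural support score for
short windows — deliberately not a thermodynamic folding energy.

## The synthetic generator and what passing tests mean

`make_toy_annotation` tiles genes every 50 kb on one synthetic chromosome,
alternating strands. AFE genes carry `n_first_exons` first exons spaced
12 kb apart (beyond the 10-kb promoter window, so each candidate's window
covers only its own promoter) splicing to a shared acceptor; the other
genes cycle through the six remaining event types in equal shares — equal
shares because no generative census is being imitated, and the proportions
are a free parameter. All within-event candidate parts have equal
effective length, so planted proportions and PSI coincide exactly.

Study conditions are fixed by the generator defaults and the acceptance
suite: 3 + 3 replicates, Poisson event totals of mean 200 (300 in the
end-to-end run), DM precision \(\phi = 50\), planted
\(\Delta\mathrm{PSI} = 30\) on candidate 2 of affected genes (control
35/65, treated 65/35). Peak count matrices use negative-binomial counts
(mean 2,000, size 50) with differential peaks planted at 25% of AFE
promoters per assay at a raw log2 fold change of 4; because the spec'd
statistic normalizes by library size and a quarter of the peaks shift, the
realized CPM fold change is ≈ 1.75 — still clearly above both presets'
cutoffs, and the unplanted peaks shift slightly *negative*, which keeps
false flags rare. CAGE peaks cover 45% of true TSSs with high scores plus
low-scoring decoys. The DE table plants half the genes as differentially
expressed exactly at the |log2FC| \(\ge 2\), adjusted p \(\le 0.05\)
thresholds.

Problem sizes in the test and acceptance suites — 2,000 events for null
calibration, 300 for power, a 100-gene end-to-end run — were chosen once
as the smallest sizes at which the Monte-Carlo error of each check is well
below its tolerance.

What the generator does *not* emulate: junction discovery from alignments
(counts are given per candidate), sequence-content realism (background is
uniform ACGT), peak-caller artifacts, covariate structure beyond two
conditions, or genuine biological coupling between chromatin state and
splicing. Passing tests therefore demonstrate that the statistics and the
bookkeeping are correct under the stated model, not that the model
captures every property of real macrophage data.

## Numerical and degenerate-input choices

* DM likelihoods are evaluated in log-gamma form throughout; a zero
  proportion with a positive count returns a proper \(-\infty\).
* `dm_fit` profiles \(\phi\) over \(10^{-0.3}\)–\(10^5\); events with no
  visible overdispersion simply sit at the grid top, where the fit is
  numerically the multinomial.
* All-zero events are a fit error; a condition with no positive-total
  sample is rejected.
* PSI with zero total abundance is missing, never 0/0.
* Event ids are deterministic (sorted by coordinates within gene and
  type), and every generator is bit-reproducible under a seed; pipeline
  writers emit no timestamps, so reruns are byte-identical.
* `ranking_composition` uses `ceiling` for top-\(k\%\) subsets (guaranteed
  non-empty) with ties broken by event id.
* Cross-species comparison defaults to case-insensitive symbol matching;
  an explicit ortholog map can be supplied.

## Running the pipeline

```{r pipeline, eval = FALSE}
cfg <- afe_config(outdir = "afe_run", seed = 1, n_genes = 60)
res <- run_pipeline(cfg)
res$attribution$upset
res$crossref$fraction_de
```

`run_pipeline` writes every intermediate table (GTF, count TSVs, event and
PSI tables, both results tables, TSS BED, window BED, per-assay peak
calls, the attribution and UpSet tables, motif hits) plus a JSON manifest
recording parameters, seed, package version and per-file row counts. With
file inputs (`annotation_path`, `counts_path`, `conditions_path`) the
simulation stages are replaced by readers and the same analysis runs on
user data. A thin command-line wrapper around `run_pipeline` ships in
`inst/scripts/run_afe_pipeline.R`.

## Known limitations

* The DM route fits one precision per event with no sharing of dispersion
  information across events; empirical-Bayes moderation is out of scope.
* Two-condition designs only; no covariates, no gene-level two-stage
  screening.
* The differential-peak statistic is a thresholding stand-in, not a
  negative-binomial model fit; its calibration is checked only under the
  generator's model.
* The IRE detector is a reconstruction anchored to the packaged worked
  example (one hit vs none); it is not a thermodynamic or
  binding-affinity model, and its background specificity is characterized
  empirically on uniform sequence.
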
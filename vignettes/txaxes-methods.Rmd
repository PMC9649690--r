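---
title: "Methods: lineage specificity, RBP regulation, and drug-association axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage specificity, RBP regulation, and drug-association axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txaxes)
```

# Overview

`txaxes` implements the computational core of transcript-resolution
pan-cancer analysis: scoring how lineage-specific each transcript's
expression is across a panel of cancer cell lines, building a
high-confidence RNA-binding-protein (RBP) → transcript regulatory network
from knockdown differential expression plus binding peaks, associating
transcript expression with anti-cancer drug sensitivity through an elastic
net with bootstrap sign-frequency scoring, and joining the two networks
into RBP–transcript–drug axes. Every stage can be exercised on synthetic
data with planted ground truth, so the whole pipeline is testable without
any external download.

# Lineage-specificity scoring

The atlas is a transcript × cell-line TPM matrix with a cell-line →
lineage map. Expression is first aggregated per lineage into $x_{it}$
(transcript $t$, lineage $i$) and converted to expression ratios

$$p_{it} = \frac{x_{it}}{\sum_{i=1}^{N} x_{it}},$$

and the specificity score is the log lineage count minus the Shannon
entropy of the ratio profile:

$$S_t = \log_2(N) - \left(-\sum_{i=1}^{N} p_{it}\,\log_2 p_{it}\right).$$

A uniformly expressed transcript scores 0; one confined to a single
lineage scores $\log_2 N$ (4.46 for $N = 22$ lineages). A transcript is
called lineage-specific in its top lineage when its largest ratio strictly
exceeds twice the second largest **and** $S_t > 1$; both comparisons are
strict, and the ratio clause can be disabled (`ratio_rule = FALSE`) for
analyses that call specificity on the score alone, as is done for RBP
gene-level specificity.

Numerical conventions:

* $0 \cdot \log_2 0 := 0$ (the standard entropy convention);
* transcripts with zero total expression have undefined ratios and are
  flagged, never scored;
* when the second-largest ratio is exactly 0 and the top ratio is
  positive, the 2× condition holds (top $> 2 \cdot 0$).

**Aggregation choice.** How multiple cell lines of one lineage collapse
into $x_{it}$ is genuinely open; we default to the mean TPM across the
lineage's cell lines — the conventional choice for TPM panels — and expose
`median` and `sum` as alternatives. All three leave the ratio/score
machinery unchanged; `sum` and `mean` give identical ratios when lineages
have equal sizes.

# Prevalence filtering

Two dialects of the expression-prevalence filter are in common use and
both are kept, selected by `mode`:

* *inclusive* (atlas building): keep transcripts with TPM ≥ 0.1 in at
  least one cell line;
* *strict* (drug association): keep transcripts with TPM > 0.1 in at
  least 20% of cell lines.

The boundary behavior differs (a transcript at exactly 0.1 TPM passes the
first and fails the second), which is why the mode is explicit rather than
inferred.

# Transcript classification

Assembled query transcripts are compared with a reference annotation by
their intron chains (the ordered list of splice junctions). Each query
gets exactly one category, assigned by the first matching rule against
same-strand, same-chromosome reference transcripts:

1. `annotated_match` — identical intron chain (mono-exon queries match an
   overlapping mono-exon reference);
2. `contain_Ref` — the query chain strictly contains a reference
   transcript's complete chain as a contiguous sub-chain;
3. `match_Refjunction` — at least one shared junction;
4. `retain_Refintron` — a query exon completely spans a reference intron;
5. `overlap_Refexon` — same-strand exonic overlap;
6. `within_Refintron` — the query lies entirely inside one reference
   intron;
7. `intergenic` — no overlap with any reference gene span on either
   strand.

The precedence order among the intron-retention and intron-containment
categories differs between annotation tools and versions; the order above
is this package's documented choice, fixed so that classification is total
and deterministic. A query overlapping a gene only on the opposite strand
matches none of the same-strand rules and would otherwise fall through; we
re-try rules 5–6 strand-agnostically so every transcript is classified.

A **readthrough** transcript is one whose exons overlap exons of two or
more distinct same-strand reference genes; exon-level (not gene-span)
overlap is required, so a transcript crossing a neighboring gene's intron
alone is not a readthrough.

**Naming.** Structure-matching transcripts are named `<gene>-a<k>` and all
other gene-overlapping transcripts `<gene>-u<k>`, with per-gene, per-class
counters that start at 1 and follow ascending genomic start coordinate
(the numbering order is our choice; nothing downstream depends on it).
Host genes are found by same-strand gene-span overlap so intronic
transcripts are still named by their host gene; multi-gene readthroughs
take the first overlapped gene in genomic order; transcripts overlapping
no gene keep their input identifier.

**TSS evidence.** A transcript has transcription evidence when a CAGE or
active-chromatin-state peak falls within 500 nt of its transcription start
site. The window is closed — a peak whose nearest base is exactly 500 nt
away counts, 501 nt does not — and any overlap of the peak interval with
the window qualifies (no midpoint rule). BED peaks are 0-based half-open
on disk and converted to 1-based closed coordinates on import, so
round-trips are lossless.

# RBP–transcript regulatory network

A high-confidence regulatory edge requires two independent pieces of
evidence for an (RBP, transcript) pair:

* the transcript is significantly changed upon that RBP's knockdown —
  |fold change| > 1.5 and FDR < 0.05, both strict, applied to the
  `log2fc`/`fdr` columns of the per-RBP differential-expression table
  (production of those tables is deliberately outside this package; they
  are consumed as input);
* at least one of the RBP's binding peaks overlaps the transcript.

"Overlaps the transcript" defaults to *exonic* intervals, on the rationale
that binding evidence on the mature transcript is what supports a
regulatory relationship for a spliced product; `overlap = "span"` relaxes
this to the full locus for users who want pre-mRNA binding to count.
Stranded peaks must match the transcript strand; unstranded peaks match
either. The edge direction (`up`/`down`) is the sign of the expression
change upon knockdown.

Essentiality summaries count, per gene, the cell lines whose CRISPR
dependency score is strictly below −1.

# Transcript–drug association

The procedure has four stages, all seeded:

1. **Spearman prefilter.** Every (transcript, drug) pair is tested by
   Spearman correlation over the complete observations for that drug;
   pairs with |rho| > 0.2 and BH FDR < 0.05 survive. The two-sided |rho|
   reading is the default because negatively associated transcripts are
   reported downstream; a one-sided flag exists. BH adjustment is global
   across all evaluated pairs by default (`fdr_scope = "per_drug"` is
   available). Pairs with fewer than 3 complete observations or a
   constant expression vector are flagged and skipped. Note that with
   small pair families the BH correction is noisy: a pair with rho ≈ 0.24
   can clear the correlation bar yet fail the FDR bar for some
   realizations, which bounds the end-to-end sensitivity of the whole
   procedure at small scale.
2. **Prediction matrix.** The passing transcripts for a drug form a
   cell-line × transcript matrix, each column standardized to zero mean
   and unit variance; zero-variance columns are dropped with a warning.
3. **Hyperparameter tuning.** 25 random (α, λ) candidates are evaluated
   by 5 rounds of 10-fold cross-validation, minimizing mean RMSE, with
   ties broken toward the larger λ (the sparser model). The random-search
   distributions are α uniform on [0.05, 1] and λ log-uniform over three
   decades below the pathwise λ_max for the drawn α — the standard
   pathwise-solver convention. Folds shrink with a warning when the
   sample is too small for 10 folds. Elastic-net fits go through glmnet.
4. **Bootstrap sign-frequency score.** Cell lines are resampled with
   replacement B times (default 1000; smaller B is exposed for desk-scale
   runs) and the model refit at the tuned (α, λ). For each transcript,
   $F[\beta > 0]$ and $F[\beta < 0]$ count the resamples with positive
   and negative coefficients — exact zeros count in neither — and

   $$\mathrm{Score} = \frac{\lvert F[\beta > 0] - F[\beta < 0]\rvert}{B},$$

   with the direction taken from the larger frequency and a tie scoring
   0. Pairs with score ≥ 0.7 (inclusive) are called associations. A
   transcript that never passes the prefilter never enters a model and
   therefore carries a score of 0 for that drug.

Resample indices are derived from the seed before any fitting, so
re-running with a transformed response (e.g. negated AUC) reuses the
identical resamples; negating the response exactly swaps the two
frequencies and preserves every score. Degenerate resamples (zero response
variance) are redrawn and counted.

# Axis integration

Axes are the exact relational join of regulatory edges and called
associations on transcript id: a transcript regulated by $r$ RBPs and
associated with $d$ drugs yields $r \times d$ axes. Each axis carries both
direction labels (regulation and association) but no composite sign — the
two directions live on different scales (knockdown response vs. AUC
association) and any combined interpretation is left to the user.
Summaries report the fraction of bridging transcripts that are unannotated
and the fraction of distinct (RBP, drug) connections supported only by
unannotated transcripts.

# Synthetic data and what it does (not) show

The generators plant known ground truth in inputs whose statistical shape
matches the real pipeline's substrates:

* **Atlas**: lognormal TPM (meanlog 0, sdlog 1) with per-cell
  Bernoulli dropout (default 0.3), emulating the sparse, low-TPM bulk of
  transcript-level matrices. A planted lineage-specific transcript's home
  lineage cells are boosted by the factor
  $f = r(N-1)/(1-r)$ that sets the expected home share to the target
  ratio $r$ (default 0.8 across $N = 22$ lineages, 5 cell lines each).
* **Drugs**: AUC = center + scale × (Σ effect × sign × standardized
  driver expression + Gaussian noise). Drivers are drawn from transcripts
  passing the strict prevalence filter, and because they act through
  standardized expression, `effect_size` is directly on the elastic-net
  coefficient scale (default effect 1.0, noise sd 1.0).
* **Regulome**: planted (RBP, transcript) regulation at |log2FC| = 1.5
  (comfortably above the log2(1.5) ≈ 0.585 filter bar) and FDR < 0.05,
  nulls below ±0.3 log2FC with FDR ≥ 0.2; peaks placed mid-exon for a
  configurable fraction of regulated transcripts plus decoy peaks
  elsewhere.
* **Annotation**: a fixed toy locus set with one query per classification
  category, one two-gene readthrough, and peaks at 0, exactly 500, and
  501 nt from chosen TSSs to pin the window boundary.

Each generator consumes one seed and draws all sub-structures from that
stream, so outputs are byte-reproducible. What passing these tests does
**not** show: robustness to batch effects, heteroscedastic library-size
noise, correlated transcripts (isoforms of one gene), non-linear
dose–response structure, or realistic binding-signal shapes — none of
which the generators model.

# Problem sizes and runtime choices

The bundled demo configuration runs 300 transcripts × 60 cell lines × 10
lineages, 2 drugs with B = 100 bootstrap resamples, and 6 RBPs, with the
planted drug effect set strong enough (standardized effect 2, noise sd
0.5, dropout 0.1) that the 600-pair BH family reliably admits the planted
drivers — the demo is meant to show a non-trivial axis table; the test
suite and the acceptance script use up to 2,000 transcripts for
specificity recall and B = 200 for bootstrap properties. These sizes were
chosen so a full run is interactive on a laptop while keeping every
statistical property measurable; all of them scale up by config alone.

# Known limitations

* The classifier is a simplified junction-chain comparator; it does not
  reproduce any specific annotation tool's full class-code table, and its
  intron-retention/containment precedence is a documented package choice.
* BH correction over small pair families is noisy (see above); at
  consortium scale the family is large and the effect negligible.
* The tuning random search is the package's own loop over glmnet fits;
  it matches the repeated-CV/random-search design but not any external
  wrapper's RNG, so tuned (α, λ) values are reproducible only within this
  package.
* Missing AUC values are handled by per-drug complete-case restriction;
  no imputation is attempted.
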
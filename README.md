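# txaxes

Transcript-resolution analysis of pan-cancer cell-line panels:
lineage-specificity scoring, RBP–transcript regulatory networks,
transcript–drug sensitivity association, and their integration into
RBP–transcript–drug axes.

## Who this is for

Computational biologists working with transcript-level (isoform) TPM
matrices across cancer cell-line panels who want to

* find transcripts whose expression is confined to one cell-line lineage,
* combine RBP-knockdown differential expression with binding peaks into a
  high-confidence regulatory network,
* score transcript–drug sensitivity associations with a
  stability-selection-style bootstrap on top of elastic-net regression, and
* join the two networks into candidate RBP → transcript → drug axes.

All stages also run end to end on built-in synthetic data with planted
ground truth, so the statistical behavior of every step is verifiable
without any external dataset.

## The methods in brief

**Lineage specificity.** Expression is aggregated per lineage and turned
into ratios `p_it = x_it / Σ_i x_it`; the specificity score of transcript
`t` is

```
S_t = log2(N) − ( − Σ_i p_it · log2 p_it )
```

— the log lineage count minus the Shannon entropy of the ratio profile
(0 = uniform, log2 N = single-lineage). A transcript is called
lineage-specific when its top ratio strictly exceeds twice the second and
`S_t > 1`.

**Regulatory network.** An RBP → transcript edge requires the transcript
to change significantly upon that RBP's knockdown (|fold change| > 1.5,
FDR < 0.05) *and* at least one of the RBP's binding peaks to overlap the
transcript's exons.

**Drug association.** Transcript–drug pairs passing a Spearman prefilter
(|rho| > 0.2, BH FDR < 0.05) form a standardized prediction matrix per
drug; elastic-net hyperparameters are tuned by 5× repeated 10-fold CV over
25 random (α, λ) candidates; B bootstrap resamples then count positive and
negative coefficient signs per transcript, and

```
Score = |F[β>0] − F[β<0]| / B
```

with pairs scoring ≥ 0.7 called associations.

**Axes.** The exact join of regulatory edges and called associations on
transcript id.

## Worked example

```r
library(txaxes)

# synthetic atlas: 500 transcripts, 66 cell lines, 22 lineages,
# 50 planted lineage-specific transcripts at a 0.8 home-lineage share
sim   <- simulate_expression_atlas(list(n_transcripts = 500,
                                        n_cell_lines = 66, n_lineages = 22,
                                        n_planted_specific = 50,
                                        specific_ratio = 0.8, seed = 42))
atlas <- prevalence_filter(sim$atlas, 0.1, min_count = 1, mode = "inclusive")
atlas
#> ExpressionAtlas: 500 transcripts x 66 cell lines, 22 lineages

calls <- call_lineage_specific(specificity_scores(aggregate_by_lineage(atlas)))
head(subset(calls, is_specific,
            c(transcript_id, score, top_lineage, top_ratio, second_ratio)), 4)
#>   transcript_id score top_lineage top_ratio second_ratio
#> 1       TX00001  3.27   lineage21     0.845       0.0405
#> 2       TX00002  2.00   lineage09     0.628       0.0512
#> 3       TX00003  3.08   lineage14     0.820       0.0248
#> 4       TX00004  3.50   lineage04     0.886       0.0170
```

Each called transcript concentrates most of its lineage-summed expression
in one lineage (`top_ratio`), with a score well above the calling bar of 1
(the maximum possible at 22 lineages is log2 22 ≈ 4.46). On this example
45 of the 50 planted transcripts are recovered; recovery reaches ≥ 95%
at 5 cell lines per lineage (see the acceptance script).

The full pipeline — simulation, specificity, annotation classification,
network, drug association, axes — runs from one YAML config:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "txaxes")
run_pipeline(cfg, out_dir = "demo_run")
```

writing per-stage TSV tables plus `manifest.json` with seeds, thresholds,
and per-stage row counts; the same config and seed reproduce every table
byte for byte.

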
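# ChaseDecay

Transcriptome-wide mRNA half-life estimation and differential-stability
analysis from transcription-shutoff (actinomycin D) chase time courses,
with an analysis of decay–transcription coupling ("transcriptional
buffering"). Built for experiments that compare mRNA decay between two
conditions — for example a deadenylase knockdown against its control cell
line — measured as transcript intensities over a short chase (by default
0, 10, 50, 110 and 230 minutes after transcription inhibition, three
replicates per condition).

## What it computes

For each transcript, condition and replicate the package fits first-order
decay by nonlinear least squares in linear intensity space,

    y(t) = y0 · exp(−k t),   t½ = ln2 / k,   k ≥ 0,

and attaches a one-sided Wald fit p-value (H0: k = 0; k/se_k on a t
distribution with n−2 df) and a 95% confidence interval for t½ obtained
by inverting the Wald interval on k. A replicate's half-life is
*reliable* when the fit converged, fit p < 0.05 and the CI is narrower
than 2·t½; a condition's half-life needs ≥ 2 reliable replicates and is
the mean over them. Differential stability between conditions is a
two-sided Student t-test on the reliable replicate half-lives, with the
fold change defined as the ratio of per-condition mean half-lives and
reported in the symmetric signed convention (0.5 → −2.00).

The coupling analysis estimates steady-state abundances from the time-0
arrays, censuses ≥ 1.5-fold abundance changes, correlates (Spearman)
half-life fold changes with abundance fold changes over the significant
transcripts, and uses the steady-state balance A = s·t½/ln2 to infer the
transcription-rate change fc_s = fc_A / fc_t½, cross-checked against
nascent pre-mRNA measurements. A qPCR arm converts ΔCt tables to
reference-normalized decay series and reuses the same fitter.

A fully parameterised synthetic-data generator (log-normal half-lives and
synthesis rates, planted stabilized/destabilized subsets, a buffering
exponent coupling synthesis to half-life changes, multiplicative
log-normal measurement noise, detection p-values) makes every stage
testable without external data. See the methods vignette
(`vignettes/chase-decay-methods.Rmd`) for the model, parameter defaults
and their rationale.

## Worked example

```r
library(ChaseDecay)

cfg <- defaultRunConfig(seed = 1)   # the study design: 1389 transcripts,
cfg$sim$n_transcripts <- 500L       # scaled down here; 40/1389 stabilized,
cfg$sim$noise_cv <- 0               # 24/1389 destabilized planted
cfg$sim$background_level <- 0
bundle <- runPipeline(cfg)

bundle$log$censuses$reliability
#> $n_reliable_CTRL [1] 500   $n_reliable_KD [1] 500   $n_reliable_both [1] 500
bundle$log$censuses$differential
#> $n_compared [1] 500  $n_significant [1] 23  $n_stabilized [1] 14  $n_destabilized [1] 9
head(bundle$tables$stabilized, 3)
#>   transcript_id ctrl_thalf kd_thalf ttest_p fc_thalf signed_fc_abundance
#> 1        T00004  312.51742 528.0397       0     1.69               -1.17
#> 2        T00015  235.67419 300.5171       0     1.28               -1.08
#> 3        T00052   83.11922 107.6953       0     1.30               -1.08
```

On this noiseless run every planted transcript is recovered: all 500
transcripts pass the reliability filter in both conditions, and exactly
the 14 + 9 planted stabilized/destabilized transcripts are called, with
fold changes equal to the planted multipliers. The negative signed
abundance fold changes alongside *stabilized* transcripts are the
buffering-overshoot phenotype (default buffering exponent 1.3): slower
decay is met by a larger opposing drop in synthesis, so abundance falls
slightly even as the half-life rises.

With `cfg$sim$noise_cv <- 0.15` (the realistic default) the censuses take
the shape seen in real chase experiments: fewer transcripts pass the
reliability filter than are expressed, and the significant set is far
smaller than the reliable set.

Individual stages are available as plain functions operating on a
`ChaseExperiment` (a `SummarizedExperiment` of transcripts × arrays):
`medianScale()`, `percentileFloorScale()`, `detectionFilter()`,
`fitAll()`, `summarizeStability()`, `compareHalfLives()`,
`stabilityTable()`, `abundanceAtT0()`, `couplingScatter()`,
`premrnaConsistency()`, `relativeAbundance()`, `qpcrHalfLife()`, with
`readExpressionTsv()` / `writeExpressionTsv()` for the long-format TSV
interchange format and `readRunConfig()` / `writeRunConfig()` for YAML
run configurations.

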
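# spliceRetention

Quantifies selective splicing defects between a wild-type and a mutant
RNA-seq sample — the characteristic signature of a partial spliceosome
impairment in an intron-rich genome such as fission yeast, where ~43%
of genes contain introns. The design it targets has **one library per
condition**, so instead of replicate-based testing it implements
robust descriptive statistics with explicit noise filters, plus the
qPCR arithmetic used to validate individual calls.

## What it computes

**Junction ratios (dot plot).** For junction *j* with raw counts
*c<sub>j,s</sub>* and library sizes *N<sub>s</sub>*, counts per million
are CPM = *c* · 10⁶ / *N*. Junctions are filtered in order: (i) raw
count zero in any sample (mapping noise; the ratio would be
undefined), then (ii) CPM < 0.5 in both samples (small-count
randomness). Survivors get the ratio
CPM<sub>mut</sub> / CPM<sub>wt</sub>; a ratio of 1 means no difference
and the sub-1 tail flags missplicing.

**Intron retention.** For intron *i* of length *L*, the retention
index is intron-body reads per kb per million mapped,
RI = (*c* · 10⁶ / *N*) / (*L* / 1000). The fold change adds a 0.5-read
pseudocount to both counts, F = RI′<sub>mut</sub> / RI′<sub>wt</sub>,
and an intron is called **misspliced** when F is *strictly* greater
than 2 (a fold of exactly 2 is not a call). The misspliced fraction is
quoted against all annotated introns.

**qPCR support.** Standard-curve quantification (least-squares line of
Ct on log₁₀ amount; efficiency 10^(−1/slope) − 1; unknowns via the
inverted line), *act1*-normalized relative expression with the
wild-type sample set to 1, and ChIP enrichment as
[(ChIP target)/(WCE target)] / [(ChIP act1)/(WCE act1)].

**Synthetic experiments.** A seeded generator
(`simulateExperiment()`) builds a paired experiment with the assumed
structure — 43% intron-containing genes, heavy-tailed log-normal
expression, unequal library sizes (2,020,800 vs 3,178,960 mapped
reads), Poisson count noise, and 7.3% of introns implanted with a
4-fold retention increase in the mutant — together with its ground
truth, so recovery of the implanted fraction is testable end to end.

## Worked example

```r
library(spliceRetention)

cfg <- simConfig(nGenes = 100, seed = 7)
sim <- simulateExperiment(cfg)
sim
#> SpliceSimulation: 100 genes, 69 introns, 5 implanted misspliced
#>   samples: wt, mut

filt <- filterJunctions(simJunctions(sim))
ret  <- retentionFoldChanges(introns(sim), simIntronCounts(sim),
                             totalMapped(simJunctions(sim)))
summarizeSplicing(filt, ret)
#> SplicingSummary
#>   junctions: 69 input -> 69 after zero filter -> 69 after CPM filter
#>   misspliced introns: 5 / 69 (7.2%)

confusionTable(simTruth(sim), ret)
#> TP FP FN TN
#>  5  0  0 64
```

All 69 junctions survive both filters at this coverage; the five
implanted misspliced introns are recovered exactly (fold > 2), with no
false positives among the 64 unaffected introns. `exportDotplot()`
writes the ranked ratio scatter with its reference line at 1, and
`runFull(cfg, outdir = "run1")` performs the same analysis end to end,
writing `summary.tsv`, `retention.tsv`, `dotplot.tsv`, the
truth-vs-detected confusion table and a parameter-echoing `run.log`
(byte-identical for identical config and seed).

Real data enter through `readAnnotation()` (GTF),
`readJunctionBed()` (TopHat-style BED12 junctions),
`readIntronCounts()` / `readSampleStats()` (TSV), and
`runAnalysis()` ties them together. A thin command-line wrapper lives
at `inst/scripts/splice-pipeline.R`.

## Documentation

The methods vignette
(`vignettes/splicing-retention-methods.Rmd`) describes the model and
its assumptions, the filter semantics, what the simulator does and
does not emulate, and the package's numerical choices.
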
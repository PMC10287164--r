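# decapDiag

Tools for a recurring question in mRNA decay genetics: when a transcript's
abundance rises in a decapping-compromised yeast mutant, did its
**degradation slow** or did its **transcription increase**?  The two
explanations are distinguishable with parallel assays — CAGE (capped 5'
ends only), RNA-Seq (total pool), ribosome profiling (translation), and
spike-in normalized RNA-Seq / Pol II ChIP-Seq (absolute changes) — and
decapDiag implements the complete quantitative machinery, from a synthetic
multi-omic generator with planted ground truth through promoter calling,
normalization, differential testing, and mechanistic classification.

## The model at the core

Each gene carries a two-pool steady state: capped molecules `C` made at
rate α are decapped at rate δ into an uncapped pool `U`, degraded 5'→3' at
rate γ, with background turnover μ > 0 on both pools:

    C = α/(δ + μ),   U = δC/(γ + μ),   T = C + U

The capped fraction `C/T` is the diagnostic: genes preferentially decapped
in wild type sit at `C/T ≪ 1` and jump to exactly 1 when decapping is
abolished, whereas genes up-regulated transcriptionally keep an average
`C/T`.  CAGE-TPM over RNA-TPM proxies `C/T` (relatively, per library).
Translation is modelled as competition of capped mRNAs for a limiting pool
of preinitiation complexes: occupancy `θᵢ = sᵢF/(1 + sᵢF)` with the free
level `F` solving `P_total = F + Σᵢ mᵢ sᵢF/(1 + sᵢF)` (bisection,
residual < 1e-9·P_total).  Shrinking the pool while bulk mRNA rises favours
strongly initiating mRNAs — the competition signature the classifier reads
out across TE deciles.

Main entry points: `generateDataset()` / `simConfig()` (simulator),
`tpm()` / `ctRatio()` / `teTable()` (quantification), `peakCluster()` /
`consensusClusters()` / `assignClustersToGenes()` (CAGE promoters),
`sizeFactorsMOR()` / `sizeFactorsERCC()` / `sizeFactorsPombe()` and
`nbDiff()` / `deltaTETest()` (normalization and NB Wald testing),
`callGroups()` / `callDependence()` / `diagnoseMechanism()` /
`teDeciles()` (classification), and `runPipeline()` (everything,
end-to-end).  A thin command-line wrapper lives in
`inst/scripts/pipeline.R`.

## Worked example

```r
library(decapDiag)

# one gene through the kinetic model
p <- data.frame(alpha = 10, delta0 = 0.4, gamma = 0.9, mu = 0.1,
                dep_class = "BASAL")
steadyState(p, genotypeEffect("WT"))
#>        C U  T cappedFraction alphaEff
#> BASAL 20 8 28      0.7142857       10
steadyState(p, genotypeEffect("dcp2"))   # decapping-null: C/T = 1
#>              C U        T cappedFraction alphaEff
#> BASAL 76.92308 0 76.92308              1 7.692308

# a 1000-gene dataset through the whole pipeline
res <- runPipeline(simConfig(nGenes = 1000), seed = 42, outDir = "out")
s <- res$summary
```

which prints, via the summary fields:

```
UP genes: 166 (median FC 2.04)
DN genes: 121 (median FC 0.55)
dependence recovery: 0.87
mechanism recovery:  0.60
median Rpb1 FC:      0.66
bulk mRNA log2 change (spike-in): 0.89
```

Reading: 166 genes are derepressed >1.4-fold (FDR < 0.1) in the simulated
decapping-null mutant with a median 2.04-fold increase; 87% of them are
assigned their planted activator-dependence class from the activator-null
comparisons (the per-gene mechanism rule is noisier at this depth — it is
exact on noiseless data); spike-normalized Pol II occupancy falls
(transcriptional buffering) while ERCC-normalized bulk mRNA rises, the
hallmark that the derepression is decay-driven, not transcriptional.
`res$teDecile` shows the limiting-PIC competition signature: median TE
change falls from the best-translated decile (+0.25 log2) to the worst
(−0.08).  `out/` contains every intermediate table (counts, CTSS, size
factors, differential results, group calls) as TSV plus a
machine-readable `summary.json` with the seed and config hash.

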
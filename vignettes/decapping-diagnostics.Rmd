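---
title: "Diagnosing decay-driven versus transcription-driven mRNA changes"
author: "decapDiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing decay-driven versus transcription-driven mRNA changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decapDiag)
```

# The problem

In budding yeast, turnover of most mRNAs begins when the Dcp1/Dcp2
holoenzyme removes the 5' m7G cap, committing the molecule to 5'->3'
digestion by Xrn1.  When decapping is lost, hundreds of transcripts rise in
abundance.  For any one of them, two mechanisms can explain the rise:
(i) the transcript was preferentially decapped in wild type, so blocking
decapping stabilizes it; or (ii) its transcription increased (for example
through stress-response activation in a slow-growing mutant).  The two
mechanisms are distinguishable with parallel measurements: CAGE sequences
only capped 5' ends, RNA-Seq measures the total pool, ribosome profiling
measures translation, and spike-in normalized RNA-Seq and Pol II ChIP-Seq
recover absolute changes that depth normalization erases.  decapDiag
implements the full quantitative machinery for this diagnosis, driven by a
synthetic data generator with planted ground truth so every inference step
can be tested against a known answer.

# The kinetic model

Each gene is described by a two-pool steady state.  Capped molecules $C$
are produced by transcription at rate $\alpha$ (molecules/min), decapped at
rate $\delta$ (1/min) into an uncapped pool $U$, which is degraded 5'->3'
at rate $\gamma$ (1/min).  A background turnover $\mu > 0$ (1/min) acts on
both pools and keeps them finite in every genotype:

$$C = \frac{\alpha}{\delta + \mu}, \qquad
  U = \frac{\delta\,C}{\gamma + \mu}, \qquad T = C + U.$$

The capped fraction $C/T$ is the quantity that CAGE/RNA-Seq ratios proxy.
Three limits anchor the model:

* wild type: genes targeted for decapping (large $\delta$) carry a standing
  uncapped pool, so $C/T < 1$;
* decapping-null ($\delta \to 0$): $U = 0$ and $C/T = 1$ exactly, for every
  gene — the analytic identity the test suite asserts;
* exonuclease-null ($\gamma \to 0$): uncapped intermediates accumulate
  ($U = \delta C/\mu$), so totals rise while capped pools do not.

This closed form is the package's own minimal realization of the
capped-fraction diagnostic; no kinetic equations are inherited from
elsewhere, and the model makes no claim about deadenylation, poly(A)
status, or 3'->5' decay.

## Genotype effects

A genotype acts through multipliers (`genotypeEffect()`): a map from
dependence class to a factor on $\delta$ (activator-null genotypes relieve
only their dependent class, decapping-null sets every class to zero), a
factor on $\gamma$ (zero in the exonuclease-null), a global transcription
buffering factor $b$ on $\alpha$, a per-gene induction factor for
stress-induced genes, and a factor on the PIC pool.  Wild type maps to all
ones.

Two layers of transcriptional buffering are simulated.  The global factor
defaults to $b = 1/1.3$ in decay-compromised genotypes, the scale of the
median Pol II occupancy reduction such mutants show.  On top of it, a
per-gene homeostatic feedback couples effective transcription to the
gene's own total pool: the realized total solves
$T = A\,(T_0/T)^{\kappa}$, where $A$ is the feedback-free total, $T_0$ the
wild-type reference, and $\kappa \ge 0$ (default 0.25) the feedback
strength; the closed form is
$T = (A\,T_0^{\kappa})^{1/(1+\kappa)}$.  The per-gene layer is what makes
the two validation signatures coexist: in the decapping-null mutant both
capped and total pools of a stabilized gene rise together (positive
capped-vs-total correlation), while in the exonuclease-null mutant the
genes whose uncapped intermediates accumulate have their transcription
damped, so capped signal falls exactly where totals rise (negative
correlation).  With $\kappa = 0$ the plain closed form is recovered;
`steadyState()` defaults to that contract and the generator opts in.

## Limiting-PIC translation

Translation initiation is modelled as competition of capped mRNAs for a
limiting pool of 43S preinitiation complexes (PICs).  With per-gene
initiation strength $s_i$ (dimensionless) and free-PIC level $F$,
occupancy follows a binding isotherm
$\theta_i = s_i F / (1 + s_i F)$, and $F$ solves the conservation
equation

$$P_{\mathrm{total}} = F + \sum_i m_i\,\frac{s_i F}{1 + s_i F},$$

found by bisection on $[0, P_{\mathrm{total}}]$ to a residual below
$10^{-9} P_{\mathrm{total}}$ (`solveFreePICs()`; the one-gene case
$m = s = 1$, $P = 2$ has the closed-form root $F = \sqrt 2$ used as an
anchor test).  Ribosome-footprint output per gene is proportional to
$\theta_i C_i \times$ CDS length.  Uncapped molecules produce no
footprints by default — decapped species cannot recruit the cap-binding
machinery — though a configuration switch (`rpf$uncappedRPF`) lets a
residual fraction translate, since the in-vivo fate of decapped-but-intact
mRNAs is genuinely open.  The decapping-null genotype carries a reduced
pool (`picFactor` 0.7, matching the scale of the ~30% ribosome reduction
such mutants show) while bulk capped mRNA rises, so competition sharpens
and efficiently initiating mRNAs win: median TE changes fall monotonically
across wild-type TE deciles, which is the signature the classifier's
decile summary tests.

# The generator and its defaults

`generateDataset(simConfig(), seed)` draws per-gene parameters, evaluates
steady states for every configured genotype, solves the PIC competition,
and emits negative-binomial counts per assay:

| quantity | default | rationale |
|---|---|---|
| genes | 5000 | order of the expressed yeast transcriptome |
| replicates | 2 | the paired-replicate design the tests assume |
| $\alpha$ | lognormal, median 5/min, sdlog 0.8 | wide expression range |
| basal $\delta$ | lognormal, median 0.03/min, sdlog 0.5 | half-lives of tens of minutes |
| activator boost on $\delta$ | 4 | targeted genes decap several-fold faster |
| $\gamma$ | lognormal, median 0.5/min | uncapped decay faster than decapping |
| $\mu$ | 0.02/min | dilution/minor pathways; keeps pools finite |
| dependence classes | 14% activator-dependent, 11% NMD-dependent | roughly the observed split of derepressed genes |
| induced (iESR-like) genes | 5% of basal, 3-fold induction | stress-response activation in the mutant |
| buffering $b$ | 1/1.3 (decay-null genotypes) | median Pol II reduction scale |
| feedback $\kappa$ | 0.25 | mild per-gene homeostasis (see above) |
| PIC pool | 0.3 of wild-type capped pool; 0.7x in decapping-null | limiting-initiation regime |
| NB dispersion | 0.05 per assay | typical bulk RNA-Seq overdispersion |
| CAGE spread | two-sided geometric, p = 0.25 | sharp yeast TSS peaks |

ERCC-like spike-ins enter RNA libraries as a fixed aliquot competing with
the cellular mRNA mass, so genotypes with more bulk mRNA yield fewer spike
reads at equal depth — the mechanism that lets spike normalization recover
absolute changes.  The bundled definition table
(`inst/extdata/ercc_synthetic_def.tsv`, `erccDefinition()`) is a
synthetic stand-in with the layout of the commercial ExFold design (92
spikes, four subgroups, subgroup B equal in both mixes); the vendor's
concentrations are not redistributed.  ChIP samples carry a fixed
foreign-genome chromatin aliquot multiplied by each sample's simulated IP
efficiency, so the mean-over-total spike factor cancels efficiency
differences.

What the generator does **not** emulate: read-level artifacts (mappability,
GC bias, PCR duplicates), isoform and UTR-length variation, multi-TSS
promoter architecture unless enabled, deadenylation or 3'->5' decay,
gene-specific dispersion differences, and any coupling between codon
composition and decay.  Tests passing on this generator therefore validate
the inference machinery, not the biology of real libraries.

# Quantification conventions

TPM follows the reads-per-kilobase-then-per-million construction;
CAGE tags use unit length, making tags-per-million directly comparable to
RNA TPM.  The C/T ratio divides CAGE TPM by RNA TPM per gene and strain
after removing genes with zero CAGE reads in either strain of a
comparison (no pseudocount; `ctRatio()` flags rather than imputes), and is
a relative, not absolute, capped proportion because each assay is
normalized to its own library.  TE divides footprint RPKM (CDS length;
footprints map to coding sequence) by mRNA RPKM (transcript length);
replicates are merged by summing raw counts before any normalization,
while differential testing keeps replicates separate.  Zero denominators
flag a gene as undefined, never as zero.

# CAGE promoter inference

TSSs with TPM below 0.1 (inclusive threshold retained) are discarded, and
the remaining positions are clustered per chromosome and strand by an
explicit greedy peak procedure: highest-TPM unassigned TSS becomes a peak
(ties to the leftmost); unassigned TSSs within 50 bp join it; members
below 0.01 of the peak TPM are dropped unless within 25 bp; repeat.  The
parameterization matches the established promoter-calling convention, but
the upstream tool's internal algorithm is not published as a spec, so this
five-step procedure is decapDiag's own tested contract — an approximation,
flagged as such — with a brute-force oracle equivalence test on random
instances.  Whether the local filter should apply inside the extension
window is ambiguous in the convention; both orders are implemented
(`extensionExempt`), defaulting to the exempt-near-members order.
Consensus clusters merge same-strand spans separated by at most 100 bp and
are quantified per sample as the sum of member-TSS TPMs; clusters are
assigned to a gene when the dominant position lies within 1000 bp upstream
to 50 bp downstream of the start codon on the same strand, nearest start
codon winning and exact ties going to the gene the cluster is upstream of.
Coordinates are 1-based inclusive internally and 0-based half-open in BED
output.

# Normalization and testing

Median-of-ratios factors (geometric mean 1) give the relative view in
which the median gene is unchanged; spike factors computed over the
equal-concentration subgroup give the absolute view; ChIP factors are
mean-over-total of foreign-genome reads.  Differential testing is a
negative binomial Wald test written for transparency rather than parity
with heavier machinery: per-gene method-of-moments dispersions within
design cells, a `a0 + a1/mean` trend fitted to the positive estimates,
and geometric interpolation toward the trend with an adaptive
empirical-Bayes weight (trigamma-based sampling variance against
between-gene variance).  Two deliberate calibration choices follow from
measuring the few-replicate Wald statistic: the trend is fitted to
positive-only estimates, whose selection bias absorbs the statistic's
heavy tails and keeps the false-discovery proportion at or below the
adjusted-p threshold (at the cost of mild conservatism near
$\alpha = 0.05$); and the four-cell TE interaction test uses a t
reference with moderated degrees of freedom (residual plus prior df from
the trigamma inverse), without which its global-null error rate is badly
inflated.  Dispersions are floored at $10^{-8}$, degenerate fits fall
back to Poisson and are flagged, fold changes are unshrunk, and BH
adjustment runs over tested genes only.  Genes with fewer than 10 total
mRNA reads across the compared samples are excluded before testing.
Default thresholds: 1.4-fold with FDR < 0.1 for relative calls, FDR <
0.01 for spike-normalized absolute calls.

# Classification

Dependence of a derepressed gene on a decapping activator is called by an
explicit threshold rule — derepressed in the activator-null comparison at
the same 1.4-fold/FDR bar — rather than by clustering fold-change
patterns, because a clustering split is not reproducible as a
deterministic rule; the complete-linkage clustering view
(`hclusterFoldChanges()`, Euclidean distance, rows beyond |log2| = 4
excluded) is reported alongside for inspection.  An epistasis flag marks
genes whose double-mutant fold change strays more than the threshold from
the single-mutant one.  Mechanism calls combine the two absolute
modalities: DECAY when the C/T increase exceeds the all-gene median and
Pol II occupancy did not rise; TXN when occupancy rose more than 1.4-fold
regardless of C/T; AMBIGUOUS otherwise.  The median split and the
1.4-fold bar are package defaults (configurable), chosen because the
underlying argument is a group-level one and per-gene thresholds must be
explicit to be testable.  Group summaries report medians, quartiles,
$1.58\,\mathrm{IQR}/\sqrt n$ notches (suppressed below $n = 3$) and
two-sided Mann-Whitney p-values against a reference group.

# Numerical choices and degenerate inputs

Bisection tolerance $10^{-9} P_{\mathrm{total}}$ with 200 iterations; an
all-zero initiation vector returns $F = P_{\mathrm{total}}$ and zero
occupancy.  IRLS for the NB GLM runs at most 50 iterations to a
$10^{-8}$ coefficient tolerance with means clamped at $10^{-10}$;
singular fits retry as Poisson and are flagged.  Equal-TPM clustering
peaks break ties leftmost; equal-distance gene assignment prefers the
upstream gene; decile ties break by gene identifier.  Empty CTSS input,
all-zero samples, zero spike totals, fewer than two replicates, and
unknown configuration keys are rejected with explicit errors.

# Problem sizes

The shipped tests and the acceptance script run the same machinery at
reduced scale, a package choice to keep the suite fast while leaving the
generator's study conditions untouched: noiseless recovery at 800 genes,
the mostly-null normalization check at the full 5000, FDP estimation on
twenty 2000-gene replicates, sign-correlation checks at 1500–2000 genes.
Only `nGenes` and the noise switch differ from the defaults.

# Known limitations

The NB test trades a little power for FDR safety with two replicates and
makes no claim of numerical parity with reference DE implementations
(one is used as an independent cross-check in the tests).  The C/T ratio
is relative; only the simulator knows absolute capped fractions, and the
unity limit is asserted on those.  The peak-clustering contract is this
package's definition of an otherwise under-specified convention.  The
dependence rule approximates a clustering-based split only in spirit;
exact membership counts are data-dependent.  Real-data features the
generator omits (isoform structure, gene-specific dispersion, library
artifacts) bound what green tests can certify.
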
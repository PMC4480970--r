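---
title: "Dissecting transcription-factor domain function from RNA-seq counts: models and methods"
author: "TregDissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting transcription-factor domain function from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(TregDissect))
```

# The problem this package addresses

Regulatory T (T~Reg~) cells depend on the transcription factor Foxp3, a
multi-domain protein whose N-terminal proline-rich region (ProR), zinc
finger/coiled-coil and forkhead (FKH) DNA-binding domain can each be mutated
separately. Transducing conventional helper T cells with wild-type Foxp3 or
with a panel of domain mutants, and sequencing the resulting transcriptomes,
turns domain dissection into a well-posed statistical problem: which of the
genes that Foxp3 normally regulates does each mutant still control
("retained"), and which revert toward the control state ("dysregulated")?

TregDissect implements that analysis framework as reusable, tested
components: robust FPKM normalisation, bimodal expression classification
with FDR class boundaries, a negative-binomial Wald differential-expression
stage with moderated log2 fold changes, the direction-aware
retained/dysregulated caller, the exact binomial/Fisher statistics used on
the resulting gene-set summaries, and a proline-framed conservation and
selection scan over protein alignments. A seeded generator produces
synthetic studies with planted ground truth so that every stage — and the
pipeline end to end — is testable without access to the original sequencing
data.

# Expression classes: the bimodal model

The log2 FPKM distribution of expressed genes in a bulk RNA-seq replicate is
bimodal: a low-expression (LE) mode of transcriptional noise and barely
transcribed loci, and a high-expression (HE) mode of functionally relevant
transcription. Genes with zero counts are a separate non-expressed (NE)
class handled outside the fit.

`fitBimodal()` fits an unequal-variance two-component Gaussian mixture to
the log2 FPKM of expressed genes by EM. Numerical choices:

* **No pseudocount.** NE genes are removed rather than pulled in at an
  arbitrary offset, so the LE mode is estimated from genuinely expressed
  genes only. Whether barely-expressed genes should be merged with NE
  before fitting is ambiguous in principle; excluding only exact zeros is
  the default because it requires no tuning parameter.
* **Unequal variances.** The two modes have visibly different widths in
  real data; the unequal-variance family costs one parameter and removes a
  systematic misfit.
* **Initialisation and restarts.** EM is started from a median split plus
  five random restarts drawn from a fixed internal substream; the best
  log-likelihood wins and components are reported ordered by mean, so
  label switching cannot occur and the fit is reproducible without
  touching the caller's RNG. The per-iteration log-likelihood trace is
  retained and is checked (in the tests) to be non-decreasing.
* **Degenerate input** (all values equal, or a collapsing component) is an
  error, not a silent one-component fit.

## FDR class boundaries

The HE boundary is the smallest $x$ at which the expected LE contamination
among genes called HE,
$$\mathrm{FDR}_{HE}(x) = \frac{\pi_{LE}\,(1-\Phi_{LE}(x))}
 {\pi_{LE}(1-\Phi_{LE}(x)) + \pi_{HE}(1-\Phi_{HE}(x))},$$
falls to the target level (default 0.05); the LE boundary is the mirror
image on the left tails. Both are monotone in $x$ and found by bisection to
an absolute tolerance of $10^{-6}$. Genes strictly between the bounds are
intermediate (INT).

This *tail-overlap* definition is the default; a *local posterior* variant
(`method = "posterior"`) is also implemented, because the boundary-setting
procedure this reimplements is described only as an FDR on the overlap
between the classes and either reading is defensible. When the two modes
are widely separated the FDR constraint holds everywhere between the means
and the two thresholds would cross; in that case both collapse to the
crossing of the weighted component densities and the result is flagged
`degenerate` — classification then has an empty INT zone, which is the
correct limit of the model.

The kernel-bandwidth doubling sometimes used when displaying these
distributions affects plotting only (`plotMixtureFit()`); classification
never sees a kernel density estimate.

# Normalisation

Size factors are median-of-ratios: the per-gene reference is the geometric
mean across samples over genes with no zero anywhere, and a sample's factor
is the median ratio to that reference. FPKM then divides the normalised
count by transcript kilobases and by the normalised column total in
millions, so doubling every count of a sample leaves its FPKM unchanged.
For sample distances, clustering and PCA the package uses a deliberately
simple regularising transform, $\log_2(\text{normalised count} + 1)$
(`regLog()`); heavier variance-stabilising transforms are out of scope and
these outputs are qualitative.

# The differential-expression stage

The DE stage honours a standard contract — moderated log2 fold changes,
Wald p-values, Benjamini–Hochberg adjustment — with a deliberately compact
implementation. It does not attempt to reproduce any external engine
numerically, and no acceptance-grade conclusion in this package depends on
per-gene agreement with one.

**Dispersions.** Per gene, a method-of-moments estimate
$\hat\alpha = (s^2-\bar\mu)/\bar\mu^2$ pools within-condition variances of
normalised counts. A trend $\alpha_{tr}(\mu) = b_0 + b_1/\mu$ is regressed
over well-expressed genes using the *untruncated* moment statistic, so the
trend is not biased upward by the $\max(0,\cdot)$ floor. The final
dispersion shrinks the per-gene estimate toward the trend with weights
(residual df) : (prior df). With two replicates per condition the per-gene
statistic carries only a few degrees of freedom, and feeding that noise
into a Wald statistic inflates the null rejection rate (the tail is convex
in $1/\alpha$, so errors do not cancel); the default prior weight of 20
therefore lets the trend dominate at this design size. All-zero genes are
untestable: NA statistics, excluded from the multiple-testing correction.

**Moderated fold changes and the Wald test.** For one contrast the model is
$\log_2 \mu_{gj} = a_g + b_g x_j$ plus the log size-factor offset, with a
zero-centred normal prior on $b_g$ (sd 2.0 by default — the scale of fold
changes seen in strong transcription-factor responses; the historical
engine's empirical prior is not reproduced, keeping the stage free of
data-dependent prior fitting). The reported `log2fc` is the posterior mode,
found by vectorised Fisher scoring with step halving across all genes at
once; it is finite even when one condition has only zeros, which is the
point of the moderation. The standard error is the sandwich (curvature-
corrected) standard error of the penalised estimator, built from the
observed NB information at the penalised optimum:
$V = H_g^{-1} H_{\ell\ell} H_g^{-1}$ with
$H_g = H_{\ell\ell} + \mathrm{diag}(0, 1/\sigma^2)$. Dividing the shrunken
estimate by the naive penalised-information standard error would be
systematically conservative for low-information genes, because the prior
shrinks the estimator more than it shrinks that naive standard error; the
sandwich form estimates the actual sampling variability of the moderated
estimate, and the resulting Wald test is calibrated under the null (this is
verified by simulation in the test suite). Shrinkage still guarantees
$|\text{moderated lfc}| \le |\text{unshrunk lfc}|$ per gene.

# Regulation calling

The caller implements the published set logic verbatim:

1. **Differentially expressed** (per contrast): BH-adjusted $p < 0.05$
   *and* classified INT or HE in at least one replicate of at least one of
   the two conditions. Genes NE/LE everywhere in both conditions are
   ignored as noise.
2. **Regulated and lineage-relevant**: differentially expressed in *both*
   the lineage contrast (T~Reg~ vs naive helper) and the factor contrast
   (factor vs control); direction is the sign of the factor-vs-control
   fold change.
3. **Dysregulated in a mutant**: regulated, differentially expressed
   between the factor condition and the mutant, *and* changed in the
   direction of control — i.e. opposite to the factor's own effect. A
   significant change in the same direction as the factor's effect
   (enhanced regulation) counts as retained, as does no significant
   change. The criterion is directional only; no magnitude of reversion is
   required, matching the binary retained/dysregulated call. Whether the
   mutant must additionally be indistinguishable from control is left
   unspecified in the three-clause published rule, so exactly those three
   clauses are implemented.

Called dysregulated sets are subsets of the regulated set by construction,
and `summarizeSets()` emits the per-mutant direction-split counts and the
pairwise intersections used for Venn-style reporting.

# Set statistics

Direction splits are compared with an exact two-sided binomial test using
the minimum-likelihood convention (sum of all point masses not exceeding
the observed one); the tail-doubling convention is available behind a flag,
and the two never differ by more than a factor of two. Point masses are
evaluated on the log scale, so enrichment p-values at the $10^{-70}$ scale
do not underflow. The 2x2 Fisher test enumerates the hypergeometric support
the same way. Both are checked against independent enumeration oracles over
thousands of random instances in the test suite, and the published
direction-split and GO-category p-values are reproduced from their printed
inputs to printed precision.

# Conservation and selection scan

Proline residues punctuate the intrinsically disordered ProR; the maximal
proline-free runs of the reference sequence are the natural subdomain
candidates. Over a protein MSA the package computes, in ungapped reference
coordinates:

* **windowed pairwise identity** (default window 4): per column, the
  fraction of ungapped sequence pairs that agree; gapped pairs leave the
  denominator rather than counting as mismatches.
* **windowed similarity** (default window 20): mean pairwise
  substitution-matrix score. Each pair score is rescaled between the
  global matrix minimum and the larger of the two diagonal entries, which
  keeps every value in [0, 1] and makes identical residues score exactly 1
  — a pure min/max rescaling would leave identical low-diagonal residues
  (e.g. serine) looking imperfectly conserved, an artifact of the matrix
  rather than the alignment.
* **windowed Bayes factors** (default window 4 codons): the per-codon
  purifying-selection evidence is consumed as an input table (the
  selection tests that produce it are external); missing codons are
  renormalised out of their windows.

Windows are centred and truncated at the ends — synthetic padding would
manufacture edge artifacts. A segment is *selected* when its mean windowed
Bayes factor exceeds the conventional cutoff of 40, and *conserved* when
its mean windowed identity reaches a user-chosen threshold; no universal
identity threshold exists (published usage distinguishes "relatively high"
from low identity qualitatively), so the threshold is a required analysis
parameter with 0.8 as a reasonable default for closely related orthologs.

# The synthetic-data generator

`simulateCounts()` emulates the statistical structure of the study design,
not its biology: a bimodal expressed-gene landscape (defaults: modes at -2
and 6 log2 FPKM, sd 1, half the expressed genes in each), 10% all-zero
genes, two replicates per condition, library sizes of 1-3x10^7 fragments,
transcript lengths of 0.5-5 kb, and an NB dispersion trend
$\alpha(\mu) = \min(0.5,\ 0.05 + 2/\mu)$ — dispersions of ~0.05 for deeply
counted genes rising toward 0.5 at the detection floor, the range typical
of small bulk RNA-seq designs. These defaults are fixture choices for a
plausible desk-scale study, not claims about any deposited dataset.

Regulated genes take their active level from the HE mode and sit a planted
effect (default 2-4 log2 units, a strong factor response) below it on the
inactive side; the reference lineage shares the factor condition's means
and the naive condition shares control's, so the defining intersection is
well-posed. Mutants revert their dysregulated genes fully to the control
mean (partial reversion is available via a multiplier, but the call being
tested is binary, so full reversion is the default); per-mutant sets can be
given as fractions or as explicit index sets, which is how disjoint or
strictly nested designs are planted. The true mean count inverts the FPKM
formula used downstream, so parameter-recovery tests are well-posed. One
seed drives a single stream; identical configurations are bit-identical.

What the generator does *not* emulate: outlier samples, batch effects,
correlated genes, partial reversion mixtures, GC/length biases, or
transcript-level ambiguity. Passing end-to-end tests therefore demonstrates
that the pipeline's logic and statistics are correct under the model it
assumes, not that real count data satisfy that model.

`simulateMSA()` plants conserved blocks (per-position match probability to
the reference) on a background of low identity, prolines at exact reference
positions, and a Bayes-factor table elevated above the cutoff inside the
blocks — enough structure to verify the scan's coordinate handling and
flag logic with known truth.

# Problem sizes and reproducibility

The shipped verification uses desk-scale sizes chosen to keep every run
reproducible on a laptop: mixture recovery at 10,000 genes, DE calibration
and power at 5,000 genes, and a full synthetic study of 6,000 genes with
600 regulated and planted disjoint mutant sets of 200/20/220 — echoing the
relative sizes seen in the motivating domain-dissection design. All
randomness flows from explicit seeds; `runPipeline()` rerun with the same
configuration writes byte-identical summaries.

# Known limitations

* The DE stage fits a two-group NB model only: no covariates, no outlier
  handling, no independent filtering. It is a contract-compatible stage,
  not a drop-in replacement for a full GLM engine.
* Expression classes are fitted per replicate independently; replicates
  are not pooled and no consensus fit is attempted.
* The conservation scan consumes externally computed alignments and
  per-codon Bayes factors; it does not align sequences or estimate
  selection itself, and it assumes the codon table is in frame with the
  ungapped reference (index $i$ maps to residue $i$).
* The binomial/Fisher statistics are exact but unconditional on the
  pipeline that produced the set sizes; they inherit whatever selection
  effects the upstream thresholds introduce, exactly as in the original
  analysis design.
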
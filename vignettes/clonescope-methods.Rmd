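---
title: "Models and methods behind clonescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clonescope)
```

`clonescope` re-implements, as a tested pipeline, the computational
stages used to measure clonal diversity and evolution of leukemia cells
at single-cell resolution: UMI-consensus error correction, single-cell
genotyping quality estimation, B-allele-frequency copy-number calling,
phylogeny reconstruction with time calibration and phylodynamics,
Wright–Fisher clone-dynamics inference, mutational-signature analysis,
and pre/post-treatment clone tracking. This vignette records the models,
the defaults and why they were chosen, the numerical choices, and what
the synthetic data do and do not establish.

## The synthetic study and what it emulates

Whole-genome amplification (WGA) of a single cell distorts the two
alleles of every heterozygous site. The generator reproduces the
distortions every downstream stage must cope with:

* **Clone trees with clock-like mutations.** The default design mirrors
  a serial expansion experiment: single cells are isolated weekly from
  an expanding parental culture, each founding a clone that is expanded
  for two weeks and then sampled (two cells per clone, plus a parental
  pair sampled at day 7). Each branch accumulates mutations as
  Poisson(rate × duration in days); the default rate of 8 mutations/day
  gives hundreds of mutations per cell over the 9-week experiment, a
  scale at which reconstruction is informative but matrices stay small.
  A cell's truth genotype is the union of the mutations on its
  root-to-tip path, so root-to-tip counts are proportional to culture
  time in expectation. Within-clone divergence is placed 20% into each
  clone's expansion (`clone_split_fraction`): cells drawn from an
  expanded clone coalesce close to its founding, and a strictly positive
  offset keeps the truth tree fully resolved, which is what makes
  "Robinson–Foulds distance 0" a meaningful target for a binary
  reconstruction.
* **Allelic dropout and imbalance.** At a heterozygous site each allele
  drops independently with probability q = δ/(2 − δ), so the fraction of
  covered sites showing exactly one allele — the locus-level ADO that
  the estimator reports — converges to δ. Surviving alleles split a
  Poisson(mean depth) total with a Beta(a, a) allelic balance,
  a = 0.5/dispersion: dispersion → 0 is balanced amplification,
  dispersion near 1 is the U-shaped imbalance of displacement
  amplification. Each read reports the opposite allele with the
  amplification/sequencing error rate. The two built-in profiles encode
  the chemistries' reported dropout rates — `pta_profile()` with
  δ = 0.057 (dispersion 0.05, error 0.002) and `mda_profile()` with
  δ = 0.164 (dispersion 0.5, error 0.005) — at 30× mean depth.
  Dispersion and error rates are not reported per chemistry and were
  fixed once at values that reproduce the qualitative BAF-density
  contrast (MDA visibly wider).
* **Hemizygous deletions** set the lost haplotype's depth to
  error-background reads only, with per-SNP phase drawn once.
* **UMI families** copy a molecule (variant allele with probability
  VAF) with independent per-base read errors; family sizes default to a
  truncated negative binomial (size 2, mean 4, minimum 1) — a typical
  amplicon UMI profile; the distribution is configurable because no
  single form is canonical.
* **Phenotypes** evolve by Brownian motion on the cell tree plus i.i.d.
  Gaussian tip noise, so with zero noise the trait covariance equals
  rate × shared path length. BM is the reference model under which
  Blomberg's K is calibrated (K ≈ 1); the real data only *measure*
  signal, so this is a modeling choice, not a claim about biology.

What passing tests on these synthetics do **not** show: robustness to
coverage waves along the genome, GC/capture bias, doublets, chimeric
amplification artifacts, mapping error, or non-uniform germline SNP
density. The generator's distortions are site-independent given the
profile, which real WGA is not.

## Error-corrected sequencing

Consensus calling keeps a family only if it has at least `minmem = 3`
reads; a base is emitted where at least `base_cutoff = 0.8` of reads
agree (ties at the boundary are emitted — ≥, not >), otherwise 'N'; a
consensus whose N fraction exceeds 1 − `n_cutoff` (0.7) is discarded.
Somatic testing is a one-sided Fisher's exact test (tumor enriched);
sidedness is a design choice matching the somatic intent. A site is
reported iff p < 10⁻⁴, the normal sample shows fewer than 5
variant-supporting reads (the variant-read reading of an ambiguous
rule; a total-depth reading would discard nearly every site), and
at most 90% of tumor variant reads sit on one strand. No continuity
correction is applied; the upstream tool's internal corrections are not
specified, and the plain hypergeometric tail is the defensible default
(the test suite checks it against direct enumeration).

## Genotyping quality estimators

* **ADO**: fraction of heterozygous germline sites with total depth ≥ 5
  (default; unreported upstream) showing exactly one allele with
  supporting reads. "Supporting" means ≥ 1 read — a dropped allele can
  still collect error reads, which biases the estimate down by roughly
  the per-site error escape probability; at the default error rate this
  bias is well inside the estimator's sampling noise.
* **Germline recall**: fraction of het germline sites where the variant
  allele survives the same filters used for somatic calls — germline
  hets are known true positives, so this proxies somatic recall.
* **Linked-read precision**: reads co-spanning a candidate somatic SNV
  and a germline het SNP should support exactly two haplotypes. A
  (het allele, somatic allele) combination needs ≥ 2 reads to count —
  one read is indistinguishable from a sequencing error — and a
  candidate is supported iff no germline allele carries both somatic
  alleles. WGA artifacts arise independently on both haplotypes and are
  flagged by the third/fourth combination.
* **False-het rate**: heterozygous calls inside a region known to be
  hemizygous are false; their BAF distribution is returned because
  artifact calls concentrate at low BAF.
* **Burden**: per-cell call count minus the mean of the normal cells,
  reported per cell and per megabase over a configurable callable
  genome (default 2,800 Mb; the denominator is not reported upstream).
  Negative corrected burdens are reported as-is with a warning rather
  than clamped — over-correction is information.

## Mirrored-BAF CNV calling

Per SNP with depth ≥ 8, BAF = alt/(alt+ref) and mirrored
BAF = max(BAF, 1 − BAF); a (cell, window) value is the mean over the
window's qualifying SNPs (windows are 0-based half-open, width 5 kb by
default, 25 kb for loss-of-heterozygosity clade views). A window needs
≥ 3 SNPs in a cell to pass QC (defaults chosen once; unreported
upstream) and must pass QC in ≥ 5 cells to be analysis-eligible. Calls
threshold the window value; the ROC sweeps thresholds over [0.5, 1] and
scores (cell, window) pairs inside the event region — carrier-cell
pairs are positives, non-carrier pairs negatives (the reading under
which a good caller approaches AUC 1) — with AUC by trapezoid and a
mean ± 2·sd band over 100 bootstrap resamples of cells. Per-cell calls
are used rather than clone-averaged values; averaging within clones
before thresholding is a possible variant the interface does not
preclude (pool cells upstream) but is not the default.

## Phylogeny reconstruction and calibration

Missing genotypes are treated as uninformative, never as reference:
distances use pairwise deletion. The default distance is the number of
discordant mutations between two cells among co-covered sites, rescaled
by total sites / co-covered sites. On complete noiseless data this is
exactly the tree's path metric in mutation units, so neighbor joining
recovers the generating topology and branch lengths are already
expected mutation counts (they are refit by non-negative least squares
to guard against negative NJ branches). The normalized mutation-sharing
(Jaccard) distance is available as an option; the count form was
preferred because additivity gives exact recovery and interpretable
branch lengths. Maximum parsimony (ratchet + ACCTRAN) is the
alternative method, and the two are tested against each other on
synthetics. Rooting uses a supplied normal cell or an appended
all-reference pseudo-cell, removed after rooting. Bootstrap support
resamples sites (not cells), rebuilds, and reports the percentage of
replicates containing each split.

Time calibration models each branch's mutation count as
m ~ Poisson(λt). With a flat prior on durations, t | λ, m is
Gamma(m + 1, λ) — a zero-mutation branch still has expected duration
1/λ. The rate is identified by fixing it, by a proper Gamma prior, or
by anchor tips of known age: each anchor contributes
M ~ Poisson(λA), giving λ | anchors ~ Gamma(a₀ + ΣM, b₀ + ΣA). Treating
anchor paths as independent is exact when anchors share only the root —
the premalignant-cells-descend-from-distinct-stem-cells assumption —
and anchor ages may be intervals (stem cells arise in the first year of
life; Uniform(0, 1) years by default) sampled per draw. Branch
durations are drawn independently rather than under a joint ultrametric
constraint; `make_ultrametric()` aligns tips afterwards when an
ultrametric tree is required. This two-stage conditional scheme is a
declared simplification of a joint Bayesian time-tree model: it is
exactly calibrated per branch (the coverage test exploits this) but
does not propagate between-branch constraints.

The skyline uses the classic generalized estimator on coalescent
intervals — with k lineages and pooled interval length Δt,
N̂ = k(k−1)Δt/2 — with the pooling parameter ε selected by small-sample
AIC over a grid of interval-length quantiles, and credible bands from
posterior time-tree samples. It stands in for nonparametric Bayesian
phylodynamics by design; its resolution is a step function and its
bands reflect only time-tree uncertainty, not epoch-model uncertainty.

Blomberg's K is computed from the tree's phylogenetic
variance-covariance matrix as the observed MSE₀/MSE ratio over its
Brownian-motion expectation, with significance from tip-label
permutation (one-sided: observed K against the permutation upper tail).
The implementation is cross-checked against an independent published
implementation in the test suite.

## Wright–Fisher ABC

The clone model: seeded as one cell at generation t₀ (frequency 1/N),
binomial resampling with selection-weighted expectation
p′ = p(1+s)/(1+ps); extinction is an outcome, not an error. Rejection
ABC draws (t₀, s) from uniform priors, simulates the trajectory,
samples how many of the n sequenced cells land in the clone, runs a
backward coalescent inside the clone (size freq(t)·N(t), forced to
coalesce at the founding), and keeps draws within the chosen quantile
(default 10%) of Euclidean distance on MAD-standardized summaries. The
summaries — clone tip fraction, clone MRCA age, mean within-clone
pairwise coalescent time — are this package's choice; the source
workflow does not state its own. Generation time defaults to 1 day for
leukemic blasts and is configurable. Rejection ABC only; no regression
adjustment. Calibration is checked by the prior-predictive coverage of
90% credible intervals across replicates.

## Signatures

SBS96 categories follow the canonical pyrimidine-centered order;
purine-reference variants are reverse-complemented, ambiguous contexts
skipped with a message. Fitting is per-sample non-negative least
squares with reconstruction cosine; extraction is NMF under the
generalized Kullback–Leibler objective (the Poisson-appropriate choice)
with multiplicative updates, best of 10 random restarts, signatures
L1-normalized and matched to a reference by cosine (optimal assignment
for small k). The built-in catalogue is synthetic: five constructed
profiles shaped like well-known processes (flat clock-like, CpG
deamination, APOBEC at TpC, C>T-rich, T>C-rich) for simulation and
fitting without any external file. A genuine caveat found while
validating extraction: when exposures mix signatures near-uniformly, a
flat signature and the flat background of peaked signatures trade mass
freely — the factorization is not identifiable there, and no optimizer
fixes that. Recovery tests therefore use sparse exposures (samples
dominated by distinct processes, as real patients are); users should
expect the same limitation on real data. The early/late contrast
compares shared (≥ 2 cells) versus private variant context profiles
with per-category two-proportion tests and Benjamini–Hochberg
correction (the multiple-testing rule is this package's addition).

## Treatment response

VAF matrices are clustered on both axes with correlation distance and
average linkage; missing VAFs are below-detection, imputed 0;
zero-variance rows get unit distance with a warning and a constant
matrix is flagged degenerate. Cluster counts come from the dendrogram
cut in configuration, not a hard-coded number. A post-treatment clone
is emergent iff none of its defining variants or CNVs reaches the
detection limit pre-treatment (default 0.005, the error-corrected
sensitivity); the undetected pre-treatment frequency is bounded by the
rule of three, 3/n over n sampled cells. "Recurrent across replicates"
defaults to detection in ≥ 2 of 3 replicates.

## Reproducibility and numerics

Every stochastic function takes a seed and restores the caller's RNG
stream; the pipeline fans a single seed into per-stage child seeds by a
counter scheme so toggling one stage never shifts another's stream, and
reruns are byte-identical. Coordinates are 0-based half-open for
intervals (BED, windows) and 1-based for point variants (VCF), with the
conversion confined to the I/O layer. Ties at the consensus cutoff are
emitted; boundary values in hard filters follow the strict comparators
of the filter string; NJ branch lengths are clamped at zero after NNLS;
zero-depth somatic sites are skipped and logged; polytomies entering
the skyline are resolved with zero-length branches.

Test problem sizes were chosen so the full suite runs in minutes on one
core while keeping Monte-Carlo standard errors well inside the asserted
tolerances: 16–34 cells, 2,000–50,000 het SNPs, 100 ABC coverage
replicates at 300 simulations each, 500 permutation-null replicates for
K, 10,000 neutral Wright–Fisher replicates.

## Known limitations

* The WGA model is site-independent given the profile; real amplification
  artifacts are spatially correlated.
* Single-strand UMI families only; duplex (strand-aware) consensus is
  out of scope.
* Read-depth CNV evidence, absolute copy number and breakpoint
  refinement are out of scope — only allelic imbalance is used.
* Time calibration ignores between-branch constraints (see above) and
  assumes a strict clock; no relaxed-clock variant.
* The skyline is a step-function estimator, not full nonparametric
  phylodynamics.
* ABC uses three summaries and rejection only; posterior precision is
  limited by summary informativeness, and clone onset is confounded
  with selection strength when only one timepoint is sampled.
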
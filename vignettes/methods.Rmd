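---
title: "Models and methods: TF contributions and conserved RNA structure motifs in regional brain expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

brainRegulome implements a two-armed analysis of regional gene
regulation in the brain.  The first arm asks which transcription
factors (TFs) drive gene expression in which brain regions: it derives
candidate TF–gene interactions from scored binding-site clusters,
models each gene's expression as a sparse linear combination of its
candidate TFs' expression, gates each model against random models, and
converts the surviving coefficients into per-region TF contributions
with an entropy-based localization call.  The second arm asks which
conserved RNA secondary structure elements in UTRs could contribute to
post-transcriptional regulation: it tests regulatory elements (REs) of
differentially expressed genes for enrichment, and characterizes the
overlapping conserved RNA structures (CRSs) by base-pair fingerprints,
phylogenetic subtree conservation, Fitch parsimony, recurrence and
instance-overlap clustering.

Because the original data sources (a six-donor brain microarray atlas,
ChIP-seq cluster tracks, a UTR element database, a genome-wide
structure screen) are large external resources, the package ships a
synthetic-data generator that reproduces the statistical structure of
every input at desk scale.  Everything the generator plants is recorded
as ground truth, so the whole pipeline is validated end to end.

# The regression model and its gate

For each gene $g$ with candidate regulators, expression across the
$n_d$ samples of a region is modeled as
$y_g = X_{tf}\beta + \varepsilon$, where $X_{tf}$ holds the expression
of the candidate TFs.  Candidates come from two filters on binding-site
clusters: per-TF Z-standardized cluster scores must reach $z \ge 1.96$,
and a peak must lie within ±10,000 nt of the gene's transcription start
site (any overlapping nucleotide counts; 0-based half-open coordinates
throughout, conversion only at I/O boundaries).

The LASSO stage solves
$\min_\beta \frac{1}{2n_d}\lVert y_g - X_{tf}\beta\rVert_2^2 +
\lambda\lVert\beta\rVert_1$ with internal predictor standardization and
an unpenalized intercept, selecting $\lambda$ by 10-fold
cross-validation with the one-standard-error rule.  The solver is a
covariance-update coordinate-descent path written in C++: the pipeline
fits on the order of $10^5$ small problems ($n \le 200$, $p \le 10$),
so per-call overhead, not arithmetic, is the binding constraint.  The
test suite verifies the solver against glmnet along a shared
$\lambda$ grid and checks the KKT conditions of returned solutions.

Genes keep at most $n_d - 1$ non-zero coefficients (truncating by
$|\beta|$, ties by TF id); genes with fewer than two candidates skip
the LASSO and go straight to OLS.  The selected design is re-fit by
10-fold cross-validated OLS, giving 10 held-out SSEs.  Ten random
models per gene — $n_{tf}$ predictors redrawn from all other genes on
the array, including TF genes, run through the identical procedure —
give 100 reference SSEs.  A one-sided Welch t-test (real SSEs smaller)
with Benjamini–Hochberg correction over genes at 0.05 is the gate.
The Welch (unequal-variance) form is our choice; the equal-variance
form is available via an argument.

Because fold assignment and random-model draws are stochastic, the
whole analysis is repeated five times with seeds drawn from a pool of
500 unique numbers, and only (TF, gene) pairs present with non-zero
coefficients in gate-passing models of all five runs are reported
(robust interactions).

# Contributions, entropy, localization

Per sample, a TF's contribution to a target is $c = x\,\beta / y$ (a
guard zeroes the ratio when $|y| < 10^{-8}$; log-scale expression makes
this rare).  Contributions are averaged over a region's samples, and a
TF's regional total is $s_{tf} = \sum_g |c_{tf,g}|$ over gate-passing
genes.  Across the regions of one ontology depth the normalized totals
$p_{tf,k} = s_{tf,k} / \sum_j s_{tf,j}$ yield a Shannon entropy
$e_{tf} = -\sum_k p_{tf,k}\log p_{tf,k}$ (natural log; the base only
rescales and cannot change any quantile-based call).  A TF is called
localized when its regional total is in the top third of some region's
totals and its entropy is in the bottom third at that depth; ranking
within regions is dense (ties share a rank), and TFs ranked at or above
20 in every region are reported as brain-wide active.

The default pipeline fits the regression once at the ontology root (all
left-hemisphere samples) and evaluates contributions per depth-2 region
by restricting the samples in the contribution average.  Fitting
per region is fully supported (`fitRegionModels` takes any region;
`pipelineConfig(regressionRegions=)`), and region eligibility (at least
20 collapsed samples) is enforced either way; the root-fit default
keeps the five-run protocol at a problem size a single CPU handles in a
few minutes, and the planted-recovery checks show both the interaction
network and the localization calls are recovered under it.

# Differential expression with a fold-change threshold

Sibling sub-regions are compared with a moderated t-test against a
fold-change threshold $\tau = \log_2 1.5$ rather than zero: with group
means fit jointly over all of a region's sub-regions (replicates
retained), per-gene residual variances $s^2$ on $df$ degrees of freedom
are shrunk toward a scaled-inverse-chi-square prior fit by method of
moments on $\log s^2$ (prior df $d_0$ via a trigamma inverse, prior
variance $s_0^2$), and the p-value sums the two shifted tails
$P(T_{d_0+df} > (|\hat\Delta|-\tau)/se) +
P(T_{d_0+df} > (|\hat\Delta|+\tau)/se)$, capped at 1.  With $\tau = 0$
and no moderation this is the ordinary pooled t-test (verified in the
tests); the implementation is validated against the reference
moderated-statistics package on fixtures and by boundary-null and power
simulation.  BH correction is applied per contrast; a region's DE set
is the union of significant genes over all pairwise contrasts, and a
gene significantly up (down) versus every sibling is called localized
in that sub-region.  Donor identity is not in the design matrix — the
fixed-effect group-means design is the documented choice.

# RE enrichment

Association between DE membership and RE membership is tested on 2×2
tables over a protein-coding background (gene-level counting: a gene
either carries the RE or not).  Tests run for RE types and specific
elements, for all and structured-only REs (structured = at least one
nucleotide of genomic overlap with a CRS interval, half-open
arithmetic), stratified by UTR, and require at least ten DE and ten
non-DE carrier genes.  The Monte-Carlo p-value resamples tables as
multinomial draws with fixed grand total under independence estimated
from the observed margins, scoring each simulated table against its own
margins' expected counts, with the $(1 + \#\{\chi^2_* \ge
\chi^2_{obs}\})/(1 + n_{mc})$ estimator.  We implement this scheme
directly because conditioning on both margins (as the base-R simulation
does) produces an exact-conditional null that deviates from the
asymptotic $\chi^2$ reference by far more than the Monte-Carlo standard
error; the multinomial scheme converges to the asymptotic p on
large-count tables, which is what the oracle checks assert.  The
default is $n_{mc} = 10^4$ in the pipeline and $10^5$ in the oracle
tests; stable third-decimal p-values would need $10^8$, which is not a
desk-scale setting and changes nothing about the method.

# CRS conservation analysis

Every CRS carries a consensus base-pair set and gapped per-species
sequences.  A species' fingerprint marks, per consensus pair, whether
the projected pair is canonical (AU, UA, GC, CG, GU, UG — wobble
included) and gap-free.  Fingerprint dissimilarity is Hamming distance
over the pair count, $d_h = h/n_{bp}$.  Walking the ancestors of the
human leaf, the largest subtree in which at least 80% of the species
with sequences satisfy $d_h < 0.2$ is the conserved subtree; the
fraction's denominator is the species with sequences (missing species
neither help nor hurt), and an exhaustive scan over all
human-containing clades is the test oracle.  Over that subtree the
pooled GC content must lie strictly inside (0.2, 0.8) and the mean
pairwise identity (identities over non-gap columns divided by the
gap-free length of the shorter sequence, averaged over pairs) strictly
below 0.95.

Fitch small parsimony is computed per fingerprint bit over fixed
species subtrees (nested lists supplied as input, T11 and T26 by
default), bottom-up with set intersection/union in C++; species without
sequences are pruned without penalty, but a subtree's score is only
defined when fingerprints cover at least 80% of its species.  The raw
change count is normalized by $n_{bp} \times n_{species}$ (the
"sequence length" in the weighting is read as the number of consensus
pairs, since fingerprints are per-pair; alignment-length normalization
is a switch).  Selection keeps CRSs strictly below the candidate-set
median in both named subtrees.

Search hits (the package consumes a hit table; running a covariance
model search is out of scope) are validated by requiring at least 80%
of consensus pairs to project onto the matched sequence — the source
texts state both 80% and 90% in different places; 0.8 is the default
and the cutoff is a config knob — and by rejecting hits overlapping
non-simple repeats (a flag carried by the input table).  A CRS recurs
when validated instances fall in at least three distinct genes within
one (region, RE-category) stratum.  Selected motifs are compared by
instance overlap $|A \cap B| / \max(|A|, |B|)$ (instances keyed by
chrom:start-end:strand) and clustered single-linkage on $1 -$ overlap.

# The synthetic generator: what it emulates, and what it does not

The default study conditions are 5 depth-2 regions of 40 collapsed
samples each (2 sub-regions per region, 6 donors), 30 TFs and 300
genes, 3 planted regulators per modeled gene with $|\beta| \in
[0.3, 1]$ and residual sd 0.3, and 20% null genes.  TF expression is
Gaussian on the log scale (baseline mean ≈ 6); planted gene expression
is an intercept plus the planted TFs' centered expression times their
coefficients plus noise, which keeps expression positive, as log-scale
microarray values are.  Regulators are assigned from a balanced,
shuffled pool so every TF has a comparable regulon — a deliberate
choice so that the localization call tests the entropy machinery rather
than regulon-size lottery.  Three localized TFs get a +4.5 expression
offset inside one region each, the strength of a strongly regionally
induced master regulator; DE genes are drawn from the null genes (half
of them) and shifted ±1.2 log2 units — about twice the test threshold —
in one sub-region of every region, so the differential shifts cannot
masquerade as TF effects in the regression.  Peaks for planted
interactions ride at +3.5–5 sd above a 2000-peak score background per
TF, with in-window low-score and out-of-window high-score decoys so
both candidate filters do real work, plus per-gene high-scoring decoy
TFs the LASSO must prune.  The phylogeny arm evolves a stem–loop
alignment over a random 26-species tree: conserved CRSs substitute
stems compensatorily 95% of the time, degraded ones 15%, and 8% of
species are dropped entirely.

What the generator does not emulate: probe-level microarray artifacts,
background correction, real branch lengths, genomic interval complexity
(one chromosome per gene, fixed TSS), or correlated TF programs.
Passing tests therefore demonstrate that the statistical machinery
recovers what it is designed to recover under its stated model — not
that the thresholds are optimal for any particular real data set.

# Numerical choices and degenerate inputs

Medians of even-sized sets are means of the central pair; replicate
collapse groups by (donor, anatomical structure) and keeps a present
call by majority; both choices are configurable where the interface
allows.  Zero-variance peak-score sets and single-peak TFs are skipped
with warnings; all-zero contribution profiles are excluded from entropy
ranking; a gate test with zero spread on both sides returns p = 0 or 1
by mean comparison; an all-gap sequence is skipped in identity with a
warning; an unbalanced structure string is an error.  The coordinate
descent converges at $10^{-8}$ absolute change on standardized
coefficients; KKT checks in the suite use $10^{-6}$.  All randomness
descends from one base seed via labeled stage seeds (kept below
$2^{31}$), so any stage can be re-run alone and two runs of the whole
pipeline are byte-identical; the run manifest records seeds, config and
input digests but deliberately no timestamps.

# Problem sizes in the validation suite

The acceptance checks run the five-run protocol on the default
300-gene study (once, shared across checks), a 200-gene all-null gate
calibration, 1000 Fitch-vs-enumeration cases on trees of up to 8
leaves, 200 subtree-vs-scan cases up to 12 leaves, a 2000-gene
boundary-null and power simulation at 20 samples per group, $10^5$
Monte-Carlo replicates per chi-square oracle table, the 26-species
motif pipeline with 10 conserved and 10 degraded structures, and two
full pipeline runs compared byte for byte.  These sizes were chosen so
the whole suite runs on one CPU in well under half an hour while every
stage still faces a non-trivial instance.

# Known limitations

The regression gate compares CV errors, not held-out replication across
donors; donor structure enters only through sample collapse.  The
enrichment background is the array's gene set, not a curated
protein-coding list.  The TREAT-style test is a native implementation
validated by simulation and fixture comparison, not a bit-identical
port.  Contribution ratios $x\beta/y$ are scale-dependent summaries;
comparisons are only meaningful within a run's conventions.  The
conserved-subtree walk follows ancestors of human only, by design — a
conserved clade not containing human is invisible to it.
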
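# brainRegulome

Associating transcription factors and conserved RNA secondary
structures with regional gene expression in the brain.

Anatomical brain regions differ in function, and those differences are
written into gene expression.  brainRegulome asks two questions about
that regulatory landscape.  **Which transcription factors (TFs) drive
expression where?**  Candidate TF–gene interactions are read off scored
binding-site clusters near transcription start sites (per-TF Z ≥ 1.96,
±10 kb window); each gene's expression is then modeled as a sparse
linear combination of its candidate TFs,

  y_g = X_tf β + ε,   with  min_β { 1/(2n_d) ‖y_g − X_tf β‖² + λ‖β‖₁ },

λ chosen by 10-fold CV with the one-standard-error rule.  Models must
beat ten random-predictor models (one-sided Welch t-test on
cross-validated SSEs, BH-corrected at 0.05), and only (TF, gene) pairs
surviving five independently seeded repetitions are reported.
Coefficients convert to per-region contributions c = xβ/y, regional
totals s_tf = Σ_g |c_tf,g|, and a Shannon entropy over regions
e_tf = −Σ_k p_tf,k log p_tf,k that flags *localized* TFs (top-tercile
contribution, bottom-tercile entropy).  **Which structured UTR elements
ride along?**  Genes differentially expressed between sibling
sub-regions (moderated t against a fold-change threshold of log₂ 1.5)
are tested for regulatory-element enrichment (Monte-Carlo χ²), and the
conserved RNA structures overlapping those elements are graded by
base-pair fingerprints, largest conserved phylogenetic subtree
(d_h < 0.2 for ≥ 80% of species), GC/identity filters, Fitch parsimony
below the candidate median in nested species subtrees, ≥ 3-gene
recurrence, and instance-overlap clustering.

The package is aimed at computational biologists who want this pipeline
as tested, composable functions.  Because the original inputs are large
external resources, a synthetic-data generator reproduces every input's
statistical structure at desk scale with recorded ground truth, so the
full pipeline runs and validates itself anywhere.

## Worked example

Recover a planted regulatory network under the default study
conditions (5 regions × 40 samples, 30 TFs, 300 genes, 3 regulators
per gene):

```r
library(brainRegulome)
cf    <- simulationConfig()
sim   <- simulateExpression(cf, seed = 42)
peaks <- simulatePeaks(sim$truth, cf, seed = 42)
cand  <- candidateInteractions(peaks$peaks, peaks$tss)
study <- collapseReplicates(sim$study)
runs  <- lapply(runSeeds(42), function(s)
  fitRegionModels(study, "GM", cand, seed = s))
ri <- robustInteractions(runs)
head(ri, 3)
#>    tf  gene   beta_mean runs_observed
#>  TF01 G0026 -0.02549371             5
#>  TF01 G0036 -0.79282505             5
#>  TF01 G0071  0.79388772             5
```

1620 candidate pairs survive the peak filters; 734 interactions are
robust across the five runs, recovering the planted network with
recall 1.00 and precision 0.98.  `beta_mean` is the fitted coefficient
averaged over runs; `runs_observed` must equal 5 by construction.

Localization from the first run's fit:

```r
ct <- contributionTable(study, runs[[1]], regions = paste0("R", 1:5))
localizedTfs(ct$totals)
#>    tf region        e
#>  TF17     R4 1.504311
#>  TF22     R5 1.509171
#>  TF06     R1 1.561267
#>  ...
sim$truth$localized
#>    tf region
#>  TF22     R5
#>  TF17     R4
#>  TF06     R1
```

The three planted region-shifted TFs head the list with the lowest
entropies (uniform over 5 regions would be ln 5 ≈ 1.609) and the
correct regions.  `runAll(outDir)` composes every stage — simulation,
candidates, five-run regression, contributions and entropy,
differential expression, RE enrichment, motif conservation — and
writes TSV reports plus a seed/digest manifest; identical seeds give
byte-identical reports.

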
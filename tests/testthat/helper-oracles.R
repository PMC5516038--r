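# Independent oracles used across the suite.

# Minimum-change count of one binary character on a rooted tree by
# exhaustive enumeration of all internal-node labelings.
bruteForceFitch <- function(tree, states) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  internal <- (nt + 1):nn
  lab <- integer(nn)
  lab[seq_len(nt)] <- states[tree$tip.label]
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(internal)))
  for (r in seq_len(nrow(grid))) {
    lab[internal] <- as.integer(grid[r, ])
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Largest human-containing qualifying subtree by scanning every
# internal node (independent route: extract.clade instead of the
# ancestor walk).
bruteForceSubtree <- function(tree, fps, theta = 0.2, coverage = 0.8,
                              human = "human") {
  nt <- length(tree$tip.label)
  d <- apply(fps, 1, function(f) mean(f != fps[human, ]))
  best <- list(species = human, size = 1L)
  for (node in (nt + 1):(nt + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    if (!human %in% tips) next
    withFp <- intersect(tips, rownames(fps))
    if (length(withFp) == 0) next
    if (mean(d[withFp] < theta) >= coverage && length(tips) > best$size)
      best <- list(species = sort(tips), size = length(tips))
  }
  best
}

# Random binary fingerprints over a tree's tips.
randomFingerprints <- function(tree, nbp) {
  m <- matrix(sample(0:1, length(tree$tip.label) * nbp, replace = TRUE),
              length(tree$tip.label), nbp,
              dimnames = list(tree$tip.label, NULL))
  m
}

# A stem of n canonical pairs: left side and its reversed complement.
.canonicalPairsFixture <- function(n) {
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  left <- sample(bases, n, replace = TRUE)
  list(left = paste(left, collapse = ""),
       right = paste(rev(unname(comp[left])), collapse = ""))
}

# Tiny hand-built study: 2 regions x 2 sub-regions, known values.
tinyStudy <- function(nGenes = 4, nPerSub = 3) {
  ont <- RegionOntology(id = c("GM", "A", "B", "Aa", "Ab", "Ba", "Bb"),
                        parent = c(NA, "GM", "GM", "A", "A", "B", "B"))
  regions <- rep(c("Aa", "Ab", "Ba", "Bb"), each = nPerSub)
  n <- length(regions)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    donor_id = rep(c("d1", "d2"), length.out = n),
    region_id = regions, hemisphere = "L",
    structure_id = sprintf("st%02d", seq_len(n)),
    stringsAsFactors = FALSE)
  genes <- paste0("g", seq_len(nGenes))
  set.seed(99)
  em <- matrix(rnorm(nGenes * n, 8, 1), nGenes, n,
               dimnames = list(genes, samples$sample_id))
  pm <- matrix(TRUE, nGenes, n, dimnames = dimnames(em))
  BrainExpressionStudy(em, pm, samples, ont)
}
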
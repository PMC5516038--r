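#' Parse a dot-bracket consensus structure
#'
#' @param ss Dot-bracket string; \code{()} and \code{<>} are pair
#'   symbols, anything else is unpaired.
#' @return Integer matrix with columns \code{i}, \code{j} (1-based,
#'   i < j), ordered by \code{i}.
#' @export
dotBracketPairs <- function(ss) {
  ch <- strsplit(ss, "")[[1]]
  open <- ch %in% c("(", "<")
  close <- ch %in% c(")", ">")
  stack <- integer(0)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(ch)) {
    if (open[k]) stack <- c(stack, k)
    else if (close[k]) {
      if (length(stack) == 0) stop("unbalanced structure string")
      out <- rbind(out, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced structure string")
  out[order(out[, 1]), , drop = FALSE]
}

.pairsToDotBracket <- function(pairs, width) {
  ss <- rep(".", width)
  ss[pairs[, 1]] <- "("
  ss[pairs[, 2]] <- ")"
  paste(ss, collapse = "")
}

#' Read a CRS alignment from a Stockholm file
#'
#' Minimal Stockholm reader: per-species aligned sequences plus the
#' \code{#=GC SS_cons} consensus structure line (dot-bracket).  The
#' human entry is recognized by the \code{humanId} name.
#'
#' @param path File path.
#' @param crsId Identifier (default: file name without extension).
#' @param humanId Name of the human sequence (default "human").
#' @return A \linkS4class{CRSAlignment}.
#' @export
readStockholm <- function(path, crsId = NULL,
                          humanId = "human") {
  if (is.null(crsId)) crsId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  seqs <- character(0)
  ss <- ""
  for (ln in lines) {
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (!startsWith(ln, "#") && !startsWith(ln, "//") &&
               nzchar(trimws(ln))) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 2) {
        cur <- if (f[1] %in% names(seqs)) seqs[[f[1]]] else ""
        seqs[f[1]] <- paste0(cur, f[2])
      }
    }
  }
  if (!nzchar(ss)) stop("no SS_cons line in ", path)
  methods::new("CRSAlignment", crsId = crsId,
               pairs = dotBracketPairs(ss),
               sequences = chartr("T.", "U-", toupper(seqs)),
               human = humanId)
}

#' Write a CRS alignment to a Stockholm file
#'
#' @param aln A \linkS4class{CRSAlignment}.
#' @param path Output path.
#' @export
writeStockholm <- function(aln, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  w <- max(nchar(names(aln@sequences)), nchar("#=GC SS_cons")) + 2
  lines <- c("# STOCKHOLM 1.0",
             paste0("#=GF ID ", aln@crsId),
             sprintf("%-*s%s", w, names(aln@sequences), aln@sequences),
             sprintf("%-*s%s", w, "#=GC SS_cons",
                     .pairsToDotBracket(aln@pairs,
                                        nchar(aln@sequences[[1]]))),
             "//")
  writeLines(lines, path)
  invisible(path)
}

# canonical base pairs, wobble included
.isCanonical <- function(a, b) {
  paste0(a, b) %in% .canonicalPairs
}

#' Project the consensus structure onto one species
#'
#' The fingerprint marks, per consensus base pair, whether the pair
#' survives in the species' aligned sequence: a bit is 1 iff both
#' paired columns are non-gap and form a canonical pair (AU, UA, GC,
#' CG, GU, UG); gaps and non-canonical pairs give 0.
#'
#' @param aln A \linkS4class{CRSAlignment}.
#' @param species Species name.
#' @return Integer vector of length \code{nrow(aln@pairs)}.
#' @export
projectFingerprint <- function(aln, species) {
  if (!species %in% names(aln@sequences))
    stop("species ", species, " absent from alignment")
  s <- strsplit(unname(aln@sequences[species]), "")[[1]]
  a <- s[aln@pairs[, 1]]
  b <- s[aln@pairs[, 2]]
  as.integer(a != "-" & b != "-" & .isCanonical(a, b))
}

#' Fingerprints of every aligned species
#'
#' @param aln A \linkS4class{CRSAlignment}.
#' @return Integer matrix, species x base pairs.
#' @export
fingerprintMatrix <- function(aln) {
  sp <- names(aln@sequences)
  t(vapply(sp, function(s) projectFingerprint(aln, s),
           integer(nrow(aln@pairs))))
}

#' Normalized Hamming distance between fingerprints
#'
#' @param a,b Fingerprint bit vectors of equal length.
#' @return \eqn{d_h = h / n_{bp}} in [0, 1].
#' @export
fpDistance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  mean(a != b)
}

# internal tree helpers on ape phylo objects
.ancestorsOfTip <- function(tree, tip) {
  node <- match(tip, tree$tip.label)
  if (is.na(node)) stop("tip ", tip, " not in tree")
  anc <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    node <- tree$edge[e, 1]
    anc <- c(anc, node)
  }
  anc
}

.tipsUnder <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) {
      if (k <= nt) out <- c(out, tree$tip.label[k])
      else stack <- c(stack, k)
    }
  }
  out
}

#' Largest conserved phylogenetic subtree around human
#'
#' Scans the ancestors of the human leaf from the leaf towards the
#' root; for each ancestor subtree it computes the fraction of leaf
#' species (with sequences) whose fingerprint distance to the human
#' fingerprint is below \code{theta}, and returns the largest ancestor
#' subtree in which that fraction reaches \code{coverage}.  When no
#' ancestor qualifies the human leaf alone is returned.
#'
#' @param tree Rooted ape \code{phylo} with the human tip.
#' @param fps Fingerprint matrix (species x base pairs); rows are the
#'   species with sequences.
#' @param theta Distance threshold (default 0.2, strict).
#' @param coverage Required conserved fraction (default 0.8).
#' @param human Human tip label.
#' @return List with \code{species} (subtree tips), \code{size},
#'   \code{fraction} (conserved fraction among species with
#'   fingerprints) and \code{node} (internal node id, NA for the leaf).
#' @export
largestConservedSubtree <- function(tree, fps, theta = 0.2,
                                    coverage = 0.8, human = "human") {
  if (!human %in% tree$tip.label) stop("human tip missing from tree")
  if (!human %in% rownames(fps)) stop("human fingerprint missing")
  d <- apply(fps, 1, fpDistance, b = fps[human, ])
  best <- list(species = human, size = 1L, fraction = 1,
               node = NA_integer_)
  for (node in .ancestorsOfTip(tree, human)) {
    tips <- .tipsUnder(tree, node)
    withFp <- intersect(tips, rownames(fps))
    frac <- mean(d[withFp] < theta)
    if (length(withFp) > 0 && frac >= coverage &&
        length(tips) > best$size)
      best <- list(species = sort(tips), size = length(tips),
                   fraction = frac, node = node)
  }
  best
}

#' Mean pairwise sequence identity
#'
#' For each unordered pair of aligned sequences, identities are counted
#' over columns where both are non-gap and divided by the gap-free
#' length of the shorter sequence; the mean over all pairs is returned.
#' Pairs involving an all-gap sequence are skipped with a warning.
#'
#' @param seqs Character vector of aligned sequences.
#' @return Mean pairwise identity in [0, 1].
#' @export
pairwiseIdentity <- function(seqs) {
  if (length(seqs) < 2) stop("need at least two sequences")
  m <- do.call(rbind, strsplit(seqs, ""))
  gapfree <- rowSums(m != "-")
  vals <- numeric(0)
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      den <- min(gapfree[i], gapfree[j])
      if (den == 0) {
        warning("all-gap sequence skipped in identity", call. = FALSE)
        next
      }
      id <- sum(m[i, ] != "-" & m[j, ] != "-" & m[i, ] == m[j, ])
      vals <- c(vals, id / den)
    }
  }
  mean(vals)
}

#' Pooled GC content
#'
#' @param seqs Character vector of (gapped) RNA sequences.
#' @return (G + C) / (A + C + G + U) pooled over all sequences, gaps
#'   excluded.
#' @export
gcContent <- function(seqs) {
  ch <- unlist(strsplit(seqs, ""))
  ch <- ch[ch %in% c("A", "C", "G", "U")]
  if (length(ch) == 0) return(NA_real_)
  sum(ch %in% c("G", "C")) / length(ch)
}

# CSR-style child arrays in postorder for the compiled Fitch kernel
.fitchTreeData <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  reord <- ape::reorder.phylo(tree, "postorder")
  kids <- vector("list", nn)
  for (e in seq_len(nrow(reord$edge)))
    kids[[reord$edge[e, 1]]] <- c(kids[[reord$edge[e, 1]]],
                                  reord$edge[e, 2])
  post <- unique(reord$edge[, 1])
  ptr <- integer(nn + 1)
  idx <- integer(0)
  for (v in seq_len(nn)) {
    ptr[v + 1] <- ptr[v] + length(kids[[v]])
    idx <- c(idx, kids[[v]])
  }
  list(post = post, ptr = ptr, idx = idx, ntip = nt,
       tips = reord$tip.label, nn = nn)
}

#' Fitch parsimony score of a fingerprint set on a subtree
#'
#' Classic Fitch small parsimony (set intersection/union, bottom-up)
#' per base-pair bit, summed over bits.  Species without a fingerprint
#' (missing sequences) are pruned without penalty, but the score is
#' only defined when fingerprints cover at least \code{minCoverage} of
#' the subtree's species.  The normalized score divides by the number
#' of base pairs times the number of species with fingerprints
#' (switchable to alignment length).
#'
#' @param tree Rooted ape \code{phylo} for the subtree of interest.
#' @param fps Fingerprint matrix (species x base pairs).
#' @param minCoverage Required fingerprint coverage (default 0.8).
#' @param normalizeBy \code{"bp"} (base-pair count, default) or
#'   \code{"length"} (alignment length).
#' @param alignmentLength Required when \code{normalizeBy = "length"}.
#' @return List with \code{raw}, \code{normalized}, \code{coverage},
#'   \code{n_species}; \code{raw} is NA when coverage is insufficient.
#' @export
fitchParsimony <- function(tree, fps, minCoverage = 0.8,
                           normalizeBy = c("bp", "length"),
                           alignmentLength = NULL) {
  normalizeBy <- match.arg(normalizeBy)
  have <- intersect(tree$tip.label, rownames(fps))
  cov <- length(have) / length(tree$tip.label)
  if (cov < minCoverage)
    return(list(raw = NA_real_, normalized = NA_real_, coverage = cov,
                n_species = length(have)))
  if (length(have) < 2)
    return(list(raw = 0, normalized = 0, coverage = cov,
                n_species = length(have)))
  sub <- ape::keep.tip(tree, have)
  td <- .fitchTreeData(sub)
  states <- fps[td$tips, , drop = FALSE] + 1L  # 1 = absent, 2 = present
  raw <- sum(vapply(seq_len(ncol(states)), function(b)
    .fitch_count(td$post, td$ptr, td$idx, states[, b], td$nn),
    integer(1)))
  den <- if (normalizeBy == "bp") ncol(fps) * length(have) else {
    if (is.null(alignmentLength))
      stop("alignmentLength required for length normalization")
    alignmentLength * length(have)
  }
  list(raw = raw, normalized = raw / den, coverage = cov,
       n_species = length(have))
}

#' Conservation report for one CRS
#'
#' Computes fingerprints, the largest conserved subtree, subtree GC
#' content and mean pairwise identity, and Fitch parsimony scores
#' inside each named species subtree.
#'
#' @param aln A \linkS4class{CRSAlignment}.
#' @param tree Species tree (ape \code{phylo}).
#' @param subtrees Named list of species vectors (e.g. T11, T26).
#' @param theta,coverage Conserved-subtree parameters.
#' @param minCoverage Fingerprint coverage required for parsimony.
#' @return One-row data frame: \code{crs_id}, \code{n_bp},
#'   \code{subtree_size}, \code{subtree_fraction}, \code{gc},
#'   \code{identity}, and \code{parsimony_<name>} (normalized) per
#'   subtree.
#' @export
subtreeReport <- function(aln, tree, subtrees, theta = 0.2,
                          coverage = 0.8, minCoverage = 0.8) {
  fps <- fingerprintMatrix(aln)
  lcs <- largestConservedSubtree(tree, fps, theta, coverage,
                                 human = aln@human)
  spSeq <- intersect(lcs$species, names(aln@sequences))
  gc <- gcContent(aln@sequences[spSeq])
  ident <- if (length(spSeq) >= 2) pairwiseIdentity(aln@sequences[spSeq])
  else 1
  out <- data.frame(crs_id = aln@crsId, n_bp = nrow(aln@pairs),
                    subtree_size = lcs$size,
                    subtree_fraction = lcs$fraction, gc = gc,
                    identity = ident, stringsAsFactors = FALSE)
  for (nm in names(subtrees)) {
    sp <- intersect(subtrees[[nm]], tree$tip.label)
    sub <- ape::keep.tip(tree, sp)
    ps <- fitchParsimony(sub, fps, minCoverage)
    out[[paste0("parsimony_", nm)]] <- ps$normalized
    out[[paste0("parsimony_raw_", nm)]] <- ps$raw
  }
  out
}

#' Median parsimony filter
#'
#' Keeps CRSs whose normalized parsimony score is strictly below the
#' candidate-set median in every listed subtree; undefined scores fail.
#'
#' @param reports Data frame of \code{\link{subtreeReport}} rows.
#' @param subtreeNames Subtrees that must both pass (default T11, T26).
#' @return Character vector of passing \code{crs_id}s.
#' @export
parsimonyFilter <- function(reports, subtreeNames = c("T11", "T26")) {
  keep <- rep(TRUE, nrow(reports))
  for (nm in subtreeNames) {
    col <- reports[[paste0("parsimony_", nm)]]
    med <- stats::median(col, na.rm = TRUE)
    keep <- keep & !is.na(col) & col < med
  }
  reports$crs_id[keep]
}

#' Sequence-level filters on conservation reports
#'
#' @param reports Data frame of \code{\link{subtreeReport}} rows.
#' @param gcBounds Admissible GC range, exclusive (default 0.2-0.8).
#' @param maxIdentity Identity must be strictly below this (default
#'   0.95).
#' @return Logical vector per report row.
#' @export
sequenceFilters <- function(reports, gcBounds = c(0.2, 0.8),
                            maxIdentity = 0.95) {
  reports$gc > gcBounds[1] & reports$gc < gcBounds[2] &
    reports$identity < maxIdentity
}

#' Fraction of consensus pairs projectable onto a matched sequence
#'
#' @param aln A \linkS4class{CRSAlignment}.
#' @param matchedSeq Sequence aligned to the consensus columns (gapped,
#'   same length as the alignment).
#' @return Fraction in [0, 1].
#' @export
projectionFraction <- function(aln, matchedSeq) {
  s <- strsplit(chartr("T.", "U-", toupper(matchedSeq)), "")[[1]]
  if (length(s) != nchar(aln@sequences[[1]]))
    stop("matched sequence length differs from alignment")
  a <- s[aln@pairs[, 1]]
  b <- s[aln@pairs[, 2]]
  mean(a != "-" & b != "-" & .isCanonical(a, b))
}

#' Validate a structure-motif search hit
#'
#' A hit instance is retained when at least \code{minFraction} of the
#' consensus base pairs project onto the matched sequence and the hit
#' does not overlap a (non-simple) repeat.
#'
#' @param aln The hit's \linkS4class{CRSAlignment}.
#' @param matchedSeq Matched sequence aligned to consensus columns.
#' @param repeatOverlap Whether the hit overlaps a non-simple repeat.
#' @param minFraction Projection cutoff (default 0.8, inclusive).
#' @return List \code{kept}, \code{fraction}.
#' @export
validateHit <- function(aln, matchedSeq, repeatOverlap = FALSE,
                        minFraction = 0.8) {
  fr <- projectionFraction(aln, matchedSeq)
  list(kept = fr >= minFraction && !isTRUE(repeatOverlap),
       fraction = fr)
}

#' Recurrence filter over validated motif instances
#'
#' A CRS recurs when, within some annotation stratum (RE category,
#' optionally per region), its instances fall in at least
#' \code{minGenes} distinct genes.
#'
#' @param instances Data frame with columns \code{crs_id}, \code{gene},
#'   \code{category} and optionally \code{region}.
#' @param minGenes Distinct-gene threshold (default 3).
#' @return Character vector of recurring \code{crs_id}s.
#' @export
recurrenceFilter <- function(instances, minGenes = 3L) {
  if (is.null(instances) || nrow(instances) == 0) return(character(0))
  keyCols <- intersect(c("crs_id", "region", "category"),
                       names(instances))
  key <- do.call(paste, c(instances[keyCols], sep = "\r"))
  counts <- tapply(instances$gene, key, function(g)
    length(unique(g)))
  hit <- names(counts)[counts >= minGenes]
  sort(unique(vapply(strsplit(hit, "\r"), `[[`, "", 1)))
}

#' Overlap score between two motifs' instance sets
#'
#' \eqn{|A \cap B| / \max(|A|, |B|)}; 0 when both sets are empty.
#'
#' @param a,b Character vectors of instance keys (e.g.
#'   chrom:start-end:strand).
#' @return Overlap in [0, 1].
#' @export
motifOverlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(0)
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Pairwise overlap matrix of motif instance sets
#'
#' @param instanceSets Named list of instance-key vectors.
#' @return Symmetric numeric matrix of overlap scores.
#' @export
overlapMatrix <- function(instanceSets) {
  n <- length(instanceSets)
  m <- matrix(0, n, n, dimnames = list(names(instanceSets),
                                       names(instanceSets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- motifOverlap(instanceSets[[i]],
                                         instanceSets[[j]])
    }
  }
  m
}

#' Single-linkage clustering of motifs by instance overlap
#'
#' Hierarchical clustering on distance 1 - overlap with single linkage;
#' flat clusters are cut at the given height.
#'
#' @param overlap Symmetric overlap matrix.
#' @param cut Cut height on the distance scale (default 0.5).
#' @return List with \code{hclust} and \code{clusters} (named integer
#'   vector); NULL \code{hclust} for fewer than two motifs.
#' @export
clusterMotifs <- function(overlap, cut = 0.5) {
  if (nrow(overlap) < 2) {
    cl <- rep(1L, nrow(overlap))
    names(cl) <- rownames(overlap)
    return(list(hclust = NULL, clusters = cl))
  }
  hc <- stats::hclust(stats::as.dist(1 - overlap), method = "single")
  list(hclust = hc, clusters = stats::cutree(hc, h = cut))
}
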
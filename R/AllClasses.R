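#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' Brain-region ontology
#'
#' A rooted tree of brain-region identifiers.  Depth 1 is the root
#' (entire gray matter); every child is one level deeper than its
#' parent.  The ontology defines which samples belong to a region: a
#' sample annotated to any descendant of a region belongs to that
#' region.
#'
#' @slot nodes A \code{data.frame} with columns \code{id}, \code{name},
#'   \code{parent} (\code{NA} for the root) and \code{depth}.
#' @export
setClass("RegionOntology", slots = c(nodes = "data.frame"))

setValidity("RegionOntology", function(object) {
  nd <- object@nodes
  need <- c("id", "name", "parent", "depth")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id))
    return("region identifiers must be unique")
  root <- is.na(nd$parent)
  if (sum(root) != 1)
    return("ontology must have exactly one root")
  if (nd$depth[root] != 1L)
    return("root must have depth 1")
  known <- nd$parent %in% nd$id | root
  if (!all(known))
    return(paste("unknown parent for region:",
                 paste(nd$id[!known], collapse = ", ")))
  pd <- nd$depth[match(nd$parent, nd$id)]
  bad <- !root & nd$depth != pd + 1L
  if (any(bad))
    return(paste("depth must equal parent depth + 1 for:",
                 paste(nd$id[bad], collapse = ", ")))
  TRUE
})

#' Regional brain expression study
#'
#' A \linkS4class{SummarizedExperiment} of log-scale expression with a
#' matched present-call assay (microarray detection flags), sample
#' annotation (\code{sample_id}, \code{donor_id}, \code{region_id},
#' \code{structure_id}, \code{hemisphere}) and the region ontology the
#' sample annotation resolves against.  Rows are genes (or probes),
#' columns are samples.
#'
#' @slot ontology A \linkS4class{RegionOntology}.
#' @export
setClass("BrainExpressionStudy",
         contains = "SummarizedExperiment",
         slots = c(ontology = "RegionOntology"))

setValidity("BrainExpressionStudy", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "present") %in% an))
    return("assays 'exprs' and 'present' are required")
  if (!identical(dim(SummarizedExperiment::assay(object, "exprs")),
                 dim(SummarizedExperiment::assay(object, "present"))))
    return("exprs and present assays must have identical dimensions")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "donor_id", "region_id", "hemisphere")
  if (!all(need %in% names(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  ids <- object@ontology@nodes$id
  bad <- setdiff(unique(cd$region_id), ids)
  if (length(bad))
    return(paste("sample region not in ontology:", paste(bad, collapse = ", ")))
  TRUE
})

#' Conserved RNA secondary structure alignment
#'
#' One conserved RNA structure (CRS) prediction: the consensus base-pair
#' set and the gapped, aligned sequences of the species it was predicted
#' for.  The designated human sequence anchors all fingerprint
#' comparisons.
#'
#' @slot crsId Identifier of the structure prediction.
#' @slot pairs Integer matrix with columns \code{i}, \code{j}: 1-based
#'   alignment columns of each consensus base pair, \code{i < j}.
#' @slot sequences Named character vector of aligned (gapped) RNA
#'   sequences, one per species.
#' @slot human Name of the human entry in \code{sequences}.
#' @export
setClass("CRSAlignment",
         slots = c(crsId = "character", pairs = "matrix",
                   sequences = "character", human = "character"))

setValidity("CRSAlignment", function(object) {
  if (length(object@sequences) == 0) return("no sequences")
  if (is.null(names(object@sequences))) return("sequences must be named")
  if (!object@human %in% names(object@sequences))
    return("human sequence missing from alignment")
  len <- unique(nchar(object@sequences))
  if (length(len) != 1) return("sequences must share one alignment length")
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (nrow(p) > 0) {
    if (any(p[, 1] >= p[, 2])) return("pair columns must satisfy i < j")
    if (any(p < 1) || any(p > len)) return("pair columns outside alignment")
  }
  TRUE
})

setMethod("show", "RegionOntology", function(object) {
  nd <- object@nodes
  cat("RegionOntology with", nrow(nd), "regions,",
      max(nd$depth), "depth levels\n")
  cat("root:", nd$id[is.na(nd$parent)], "\n")
})

setMethod("show", "BrainExpressionStudy", function(object) {
  cat("BrainExpressionStudy:", nrow(object), "genes x", ncol(object),
      "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  donors:", length(unique(cd$donor_id)),
      " regions:", length(unique(cd$region_id)), "\n")
  cat("  ontology:", nrow(object@ontology@nodes), "regions\n")
})

setMethod("show", "CRSAlignment", function(object) {
  cat("CRSAlignment", object@crsId, "-", length(object@sequences),
      "species,", nrow(object@pairs), "consensus base pairs, length",
      nchar(object@sequences[[1]]), "\n")
})
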
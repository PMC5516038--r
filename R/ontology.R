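#' Construct a region ontology
#'
#' @param id Character vector of region identifiers.
#' @param name Human-readable names (defaults to \code{id}).
#' @param parent Parent identifier per region; \code{NA} for the root.
#' @return A \linkS4class{RegionOntology}.
#' @examples
#' ont <- RegionOntology(id = c("GM", "Tel", "DiE"),
#'                       parent = c(NA, "GM", "GM"))
#' regionDepth(ont, "Tel")
#' @export
RegionOntology <- function(id, name = id, parent) {
  depth <- rep(NA_integer_, length(id))
  depth[is.na(parent)] <- 1L
  while (anyNA(depth)) {
    pd <- depth[match(parent, id)]
    todo <- is.na(depth) & !is.na(pd)
    if (!any(todo)) stop("ontology contains unreachable regions: ",
                         paste(id[is.na(depth)], collapse = ", "))
    depth[todo] <- pd[todo] + 1L
  }
  methods::new("RegionOntology",
               nodes = data.frame(id = id, name = name, parent = parent,
                                  depth = depth, stringsAsFactors = FALSE))
}

#' Read a region ontology from JSON
#'
#' The file holds an array of objects with fields \code{id}, \code{name}
#' and \code{parent} (\code{null} for the root); depths are derived.
#'
#' @param path Path to the JSON file.
#' @return A \linkS4class{RegionOntology}.
#' @export
readOntology <- function(path) {
  x <- jsonlite::fromJSON(path)
  parent <- x$parent
  if (is.null(parent)) parent <- rep(NA_character_, length(x$id))
  parent[parent == ""] <- NA_character_
  RegionOntology(id = x$id,
                 name = if (is.null(x$name)) x$id else x$name,
                 parent = parent)
}

#' Write a region ontology to JSON
#'
#' @param ontology A \linkS4class{RegionOntology}.
#' @param path Output path.
#' @export
writeOntology <- function(ontology, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  nd <- ontology@nodes[, c("id", "name", "parent")]
  jsonlite::write_json(nd, path, na = "null", pretty = TRUE)
  invisible(path)
}

#' @describeIn RegionOntology-utils All region ids at a given depth.
#' @export
regionsAtDepth <- function(ontology, depth) {
  nd <- ontology@nodes
  nd$id[nd$depth == depth]
}

#' Region ontology queries
#'
#' Small query helpers over a \linkS4class{RegionOntology}: depth of a
#' region, its direct children, and the region itself plus all its
#' descendants.
#'
#' @param ontology A \linkS4class{RegionOntology}.
#' @param region A region identifier.
#' @param depth An integer depth (root = 1).
#' @name RegionOntology-utils
NULL

#' @describeIn RegionOntology-utils Depth of one region.
#' @export
regionDepth <- function(ontology, region) {
  nd <- ontology@nodes
  i <- match(region, nd$id)
  if (is.na(i)) stop("unknown region: ", region)
  nd$depth[i]
}

#' @describeIn RegionOntology-utils Direct children of a region.
#' @export
regionChildren <- function(ontology, region) {
  nd <- ontology@nodes
  if (!region %in% nd$id) stop("unknown region: ", region)
  nd$id[!is.na(nd$parent) & nd$parent == region]
}

#' @describeIn RegionOntology-utils The region and all descendants.
#' @export
regionDescendants <- function(ontology, region) {
  nd <- ontology@nodes
  if (!region %in% nd$id) stop("unknown region: ", region)
  out <- region
  frontier <- region
  while (length(frontier)) {
    kids <- nd$id[!is.na(nd$parent) & nd$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' @describeIn RegionOntology-utils The root region id.
#' @export
rootRegion <- function(ontology) {
  nd <- ontology@nodes
  nd$id[is.na(nd$parent)]
}
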
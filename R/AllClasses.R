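#' @import methods
NULL

#' In-memory structure reference database
#'
#' Holds one row per reference compound with its structure, Hill formula,
#' neutral monoisotopic mass and (optional) source-organism taxonomy, plus a
#' mass-sorted index for adduct window queries.
#'
#' @slot records data.frame with columns `compound_id`, `name`, `smiles`,
#'   `formula`, `exact_mass`, followed by one column per taxonomy rank.
#' @slot taxonomyRanks Character vector naming which record columns are
#'   taxonomy ranks (possibly empty).
#' @slot sourceDb One of `"npatlas"`, `"coconut"`, `"fixture"`.
#' @slot massOrder Integer permutation of the record rows, nondecreasing in
#'   `exact_mass`.
#' @slot skipped Number of dump entries dropped at load (unparseable
#'   structures).
#' @exportClass CompoundDb
setClass("CompoundDb",
  representation(
    records = "data.frame",
    taxonomyRanks = "character",
    sourceDb = "character",
    massOrder = "integer",
    skipped = "integer"
  )
)

setValidity("CompoundDb", function(object) {
  rec <- object@records
  need <- c("compound_id", "name", "smiles", "formula", "exact_mass")
  if (!all(need %in% colnames(rec))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(rec$compound_id)) {
    return("compound_id values must be unique")
  }
  if (nrow(rec) > 0L && any(rec$exact_mass <= 0)) {
    return("exact_mass must be positive")
  }
  if (length(object@massOrder) != nrow(rec) ||
      (nrow(rec) > 0L && !identical(sort(object@massOrder), seq_len(nrow(rec))))) {
    return("massOrder must be a permutation of the record rows")
  }
  if (nrow(rec) > 1L && is.unsorted(rec$exact_mass[object@massOrder])) {
    return("massOrder must sort records by nondecreasing exact_mass")
  }
  if (!all(object@taxonomyRanks %in% colnames(rec))) {
    return("taxonomyRanks must name record columns")
  }
  if (!object@sourceDb %in% c("npatlas", "coconut", "fixture")) {
    return("sourceDb must be npatlas, coconut or fixture")
  }
  TRUE
})

#' Chemical-fingerprint similarity network
#'
#' Undirected network over compound ids; an edge is kept iff the pairwise
#' fingerprint similarity is at or above the recorded cutoff. Isolated nodes
#' are retained so connected components partition the input compounds.
#'
#' @slot nodes Character vector of compound ids.
#' @slot edges data.frame with columns `from`, `to`, `score`; `from < to`,
#'   no self loops, no duplicates.
#' @slot method Fingerprint method (`morgan`, `maccs`, `atom_pair`).
#' @slot radius Morgan radius (ignored for other methods).
#' @slot metric Similarity metric (`dice`, `tanimoto`).
#' @slot cutoff Score threshold in (0, 1].
#' @exportClass SimilarityNetwork
setClass("SimilarityNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    method = "character",
    radius = "numeric",
    metric = "character",
    cutoff = "numeric"
  )
)

setValidity("SimilarityNetwork", function(object) {
  ed <- object@edges
  if (!all(c("from", "to", "score") %in% colnames(ed))) {
    return("edges must have columns from, to, score")
  }
  if (nrow(ed)) {
    if (!all(ed$from %in% object@nodes) || !all(ed$to %in% object@nodes)) {
      return("edge endpoints must be network nodes")
    }
    if (any(ed$from == ed$to)) return("self loops are not allowed")
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    if (anyDuplicated(key)) return("duplicate edges are not allowed")
    if (any(ed$score < object@cutoff - 1e-12) ||
        any(ed$score > 1 + 1e-12) || any(ed$score < 0)) {
      return("edge scores must lie in [cutoff, 1]")
    }
  }
  if (anyDuplicated(object@nodes)) return("nodes must be unique")
  TRUE
})

#' Pipeline parameters for subnetwork annotation
#'
#' @slot ppmWindow Mass tolerance in ppm for binning and database queries.
#' @slot adducts data.frame adduct panel (name, mass_shift, charge).
#' @slot minFamilySize Candidate families smaller than this are dropped.
#' @slot minGnpsClusterSize,maxGnpsClusterSize Subnetwork size filters applied
#'   when splitting a molecular network into mass lists.
#' @slot maxNodeCount,maxEdgeCount Results-graph size limits; larger graphs
#'   are flagged `graph_too_large` rather than returned.
#' @slot fpMethod,fpRadius,metric,cutoff Clustering configuration for the
#'   candidate similarity network.
#' @exportClass SnapmsParams
setClass("SnapmsParams",
  representation(
    ppmWindow = "numeric",
    adducts = "data.frame",
    minFamilySize = "integer",
    minGnpsClusterSize = "integer",
    maxGnpsClusterSize = "integer",
    maxNodeCount = "integer",
    maxEdgeCount = "integer",
    fpMethod = "character",
    fpRadius = "integer",
    metric = "character",
    cutoff = "numeric"
  )
)

setValidity("SnapmsParams", function(object) {
  if (object@ppmWindow <= 0) return("ppmWindow must be positive")
  counts <- c(object@minFamilySize, object@minGnpsClusterSize,
              object@maxGnpsClusterSize, object@maxNodeCount,
              object@maxEdgeCount)
  if (any(counts <= 0L)) return("all count parameters must be positive")
  if (object@cutoff <= 0 || object@cutoff > 1) {
    return("cutoff must lie in (0, 1]")
  }
  if (!object@fpMethod %in% c("morgan", "maccs", "atom_pair")) {
    return("fpMethod must be morgan, maccs or atom_pair")
  }
  if (!object@metric %in% c("dice", "tanimoto")) {
    return("metric must be dice or tanimoto")
  }
  if (nrow(object@adducts) == 0L) return("adduct panel must be non-empty")
  TRUE
})

#' Annotation result for one subnetwork
#'
#' @slot subnetworkId Label of the annotated subnetwork.
#' @slot compoundGroups data.frame of binned mass groups (`group_id`,
#'   `representative_mz`, `n_members`, list columns `member_mz`,
#'   `member_nodes`).
#' @slot candidateCount Number of distinct candidate compounds retrieved.
#' @slot matches data.frame of (group, compound, adduct) candidate matches
#'   with signed ppm errors.
#' @slot families data.frame of surviving candidate compound families, ranked;
#'   list columns `members` and `covered_groups`.
#' @slot resultsGraph [SimilarityNetwork] restricted to surviving families.
#' @slot status One of `annotated`, `no_candidates`, `all_families_filtered`,
#'   `graph_too_large`.
#' @slot params The [SnapmsParams] used.
#' @exportClass AnnotationResult
setClass("AnnotationResult",
  representation(
    subnetworkId = "character",
    compoundGroups = "data.frame",
    candidateCount = "integer",
    matches = "data.frame",
    families = "data.frame",
    resultsGraph = "SimilarityNetwork",
    status = "character",
    params = "SnapmsParams"
  )
)

setValidity("AnnotationResult", function(object) {
  ok <- c("annotated", "no_candidates", "all_families_filtered",
          "graph_too_large")
  if (!object@status %in% ok) {
    return(paste("status must be one of", paste(ok, collapse = ", ")))
  }
  fam <- object@families
  if (nrow(fam) > 1L && is.unsorted(fam$rank)) {
    return("families must be sorted by rank")
  }
  if (nrow(fam) > 0L && any(fam$coverage > nrow(object@compoundGroups))) {
    return("family coverage cannot exceed the number of compound groups")
  }
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @rdname CompoundDb-class
#' @param x A `CompoundDb`.
#' @export
dbRecords <- function(x) {
  stopifnot(is(x, "CompoundDb"))
  x@records
}

#' @rdname CompoundDb-class
#' @export
nRecords <- function(x) {
  stopifnot(is(x, "CompoundDb"))
  nrow(x@records)
}

#' @rdname CompoundDb-class
#' @export
taxonomyRanks <- function(x) {
  stopifnot(is(x, "CompoundDb"))
  x@taxonomyRanks
}

#' @rdname CompoundDb-class
#' @export
dbSource <- function(x) {
  stopifnot(is(x, "CompoundDb"))
  x@sourceDb
}

#' @rdname CompoundDb-class
#' @export
nSkipped <- function(x) {
  stopifnot(is(x, "CompoundDb"))
  x@skipped
}

#' @rdname SimilarityNetwork-class
#' @param x A `SimilarityNetwork`.
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "SimilarityNetwork"))
  x@nodes
}

#' @rdname SimilarityNetwork-class
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "SimilarityNetwork"))
  x@edges
}

#' @rdname AnnotationResult-class
#' @param x An `AnnotationResult`.
#' @export
annotationStatus <- function(x) {
  stopifnot(is(x, "AnnotationResult"))
  x@status
}

#' @rdname AnnotationResult-class
#' @export
resultFamilies <- function(x) {
  stopifnot(is(x, "AnnotationResult"))
  x@families
}

#' @rdname AnnotationResult-class
#' @export
compoundGroups <- function(x) {
  stopifnot(is(x, "AnnotationResult"))
  x@compoundGroups
}

#' @rdname AnnotationResult-class
#' @export
candidateMatches <- function(x) {
  stopifnot(is(x, "AnnotationResult"))
  x@matches
}

#' @rdname AnnotationResult-class
#' @export
resultsGraph <- function(x) {
  stopifnot(is(x, "AnnotationResult"))
  x@resultsGraph
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "CompoundDb", function(object) {
  cat("CompoundDb (", object@sourceDb, ") with ", nrow(object@records),
      " records\n", sep = "")
  if (length(object@taxonomyRanks)) {
    cat("  taxonomy ranks:", paste(object@taxonomyRanks, collapse = ", "), "\n")
  }
  if (object@skipped > 0L) {
    cat("  entries skipped at load:", object@skipped, "\n")
  }
  if (nrow(object@records)) {
    rng <- range(object@records$exact_mass)
    cat(sprintf("  mass range: %.4f - %.4f Da\n", rng[1], rng[2]))
  }
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat("SimilarityNetwork: ", length(object@nodes), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
  cat("  ", object@method,
      if (object@method == "morgan") paste0(" (radius ", object@radius, ")"),
      " / ", object@metric, " >= ", object@cutoff, "\n", sep = "")
})

setMethod("show", "SnapmsParams", function(object) {
  cat("SnapmsParams\n")
  cat("  ppm window:", object@ppmWindow, "\n")
  cat("  adducts:", paste(object@adducts$name, collapse = ", "), "\n")
  cat("  clustering:", object@fpMethod, "r =", object@fpRadius, "/",
      object@metric, ">=", object@cutoff, "\n")
  cat("  min family size:", object@minFamilySize,
      "| GNPS cluster size:", object@minGnpsClusterSize, "-",
      object@maxGnpsClusterSize, "\n")
  cat("  results graph limits:", object@maxNodeCount, "nodes /",
      object@maxEdgeCount, "edges\n")
})

setMethod("show", "AnnotationResult", function(object) {
  cat("AnnotationResult for subnetwork '", object@subnetworkId, "': ",
      object@status, "\n", sep = "")
  cat("  compound groups:", nrow(object@compoundGroups),
      "| candidates:", object@candidateCount,
      "| families kept:", nrow(object@families), "\n")
  if (nrow(object@families)) {
    top <- object@families[1L, ]
    cat("  rank-1 family: ", top$family_id, " (", top$size, " members, ",
        "coverage ", top$coverage, ")\n", sep = "")
  }
})
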
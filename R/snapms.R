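# End-to-end subnetwork annotation: mass-list input, binning, candidate
# retrieval, clustering, family ranking, graph-size filtering and GraphML
# output.

#' Construct pipeline parameters
#'
#' Defaults follow the platform's published configuration: 10 ppm tolerance,
#' the three-species positive adduct panel, Morgan radius-2 / Dice >= 0.71
#' clustering, candidate families of fewer than 3 members dropped, GNPS
#' subnetworks of 3..5000 nodes considered, and results graphs larger than
#' 2000 nodes or 10,000 edges flagged instead of returned.
#'
#' @param ppmWindow Mass tolerance (ppm) for binning and database queries.
#' @param adducts Adduct panel data.frame or adduct names.
#' @param minFamilySize Minimum members for a candidate family to survive.
#' @param minGnpsClusterSize,maxGnpsClusterSize Subnetwork size filter.
#' @param maxNodeCount,maxEdgeCount Results-graph size limits.
#' @param fpMethod,fpRadius Fingerprint configuration.
#' @param metric Similarity metric.
#' @param cutoff Similarity cutoff for candidate clustering.
#' @return A [SnapmsParams-class].
#' @export
snapmsParams <- function(ppmWindow = 10, adducts = adductPanel(),
                         minFamilySize = 3L, minGnpsClusterSize = 3L,
                         maxGnpsClusterSize = 5000L, maxNodeCount = 2000L,
                         maxEdgeCount = 10000L, fpMethod = "morgan",
                         fpRadius = 2L, metric = "dice", cutoff = 0.71) {
  new("SnapmsParams",
      ppmWindow = ppmWindow,
      adducts = resolveAdducts(adducts),
      minFamilySize = as.integer(minFamilySize),
      minGnpsClusterSize = as.integer(minGnpsClusterSize),
      maxGnpsClusterSize = as.integer(maxGnpsClusterSize),
      maxNodeCount = as.integer(maxNodeCount),
      maxEdgeCount = as.integer(maxEdgeCount),
      fpMethod = fpMethod,
      fpRadius = as.integer(fpRadius),
      metric = metric,
      cutoff = cutoff)
}

#' Read a parent-mass list from CSV
#'
#' One m/z per row (first field of each line); an optional header row is
#' skipped. Non-numeric rows are dropped with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of mass features: `mz`, `node_id` (row index),
#'   `subnetwork_id` (a single subnetwork, `"S1"`).
#' @export
parseMassListCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(vapply(strsplit(lines, ","), function(x) {
    if (length(x)) x[[1L]] else ""
  }, character(1)))
  nonEmpty <- which(nzchar(lines))
  vals <- suppressWarnings(as.numeric(lines[nonEmpty]))
  bad <- which(is.na(vals))
  # a leading non-numeric row is a header, not a malformed row
  if (length(bad) && bad[1L] == 1L) bad <- bad[-1L]
  if (length(bad)) {
    warning(length(bad), " non-numeric row(s) skipped in ", path,
            call. = FALSE)
  }
  keep <- which(!is.na(vals) & vals > 0)
  if (!length(keep)) {
    stop("no numeric m/z values found in ", path, call. = FALSE)
  }
  data.frame(mz = vals[keep], node_id = as.character(nonEmpty[keep]),
             subnetwork_id = "S1", stringsAsFactors = FALSE)
}

# Resolve the precursor-mass node attribute of a GNPS GraphML export.
# Dialects vary; names are compared case-insensitively after stripping
# non-alphanumerics.
.MASS_ATTR_CANDIDATES <- c("precursormass", "parentmass", "mz")

.resolveMassAttribute <- function(g, massAttribute = NULL) {
  attrs <- igraph::vertex_attr_names(g)
  if (!is.null(massAttribute)) {
    if (!massAttribute %in% attrs) {
      stop("node attribute '", massAttribute, "' not present; found: ",
           paste(attrs, collapse = ", "), call. = FALSE)
    }
    return(massAttribute)
  }
  norm <- gsub("[^a-z0-9]", "", tolower(attrs))
  for (cand in .MASS_ATTR_CANDIDATES) {
    hit <- which(norm == cand)
    if (length(hit)) return(attrs[hit[1L]])
  }
  stop("no recognised precursor-mass node attribute; found: ",
       paste(attrs, collapse = ", "),
       " (use 'massAttribute' to pick one)", call. = FALSE)
}

#' Split a molecular network into per-subnetwork mass lists
#'
#' Reads a GNPS-exported GraphML molecular network, computes its connected
#' components, drops components outside the configured size range, and
#' returns one mass-feature table per surviving component.
#'
#' @param path GraphML file path.
#' @param params A [SnapmsParams-class] (cluster-size filter).
#' @param massAttribute Optional name of the node attribute holding the
#'   precursor mass; by default `precursor mass`, `parent mass` or `mz` is
#'   matched case-insensitively.
#' @return Named list of mass-feature data.frames (`mz`, `node_id`,
#'   `subnetwork_id`), one per surviving subnetwork.
#' @export
extractSubnetworksFromGraphml <- function(path, params = snapmsParams(),
                                          massAttribute = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) stop("malformed GraphML in '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  attrName <- .resolveMassAttribute(g, massAttribute)
  mz <- suppressWarnings(as.numeric(igraph::vertex_attr(g, attrName)))
  ids <- if ("name" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name
  } else if ("id" %in% igraph::vertex_attr_names(g)) {
    as.character(igraph::V(g)$id)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    n <- length(nodes)
    if (n > params@maxGnpsClusterSize) {
      warning("subnetwork of ", n, " nodes exceeds maxGnpsClusterSize (",
              params@maxGnpsClusterSize, "); dropped", call. = FALSE)
      next
    }
    if (n < params@minGnpsClusterSize) next
    snid <- sprintf("S%d", ci)
    feats <- data.frame(mz = mz[nodes], node_id = ids[nodes],
                        subnetwork_id = snid, stringsAsFactors = FALSE)
    feats <- feats[!is.na(feats$mz) & feats$mz > 0, , drop = FALSE]
    if (nrow(feats) == 0L) next
    out[[snid]] <- feats
  }
  out
}

#' Bin mass features into compound groups
#'
#' Features are sorted ascending by m/z; a single greedy pass opens a new
#' group whenever the next mass deviates from the current group's
#' representative (its first, lowest member) by more than `ppmWindow`. The
#' representative mass of a group is therefore its minimum.
#'
#' @param features data.frame of mass features (`mz`, `node_id`).
#' @param ppmWindow Tolerance in ppm.
#' @return data.frame of compound groups: `group_id`, `representative_mz`,
#'   `n_members`, list columns `member_mz` and `member_nodes`.
#' @export
binMasses <- function(features, ppmWindow = 10) {
  stopifnot(is.data.frame(features), "mz" %in% colnames(features))
  if (nrow(features) == 0L) stop("no mass features to bin", call. = FALSE)
  if (!"node_id" %in% colnames(features)) {
    features$node_id <- as.character(seq_len(nrow(features)))
  }
  ord <- order(features$mz)
  mz <- features$mz[ord]
  nodes <- features$node_id[ord]
  groupOf <- integer(length(mz))
  rep <- mz[1L]
  gi <- 1L
  groupOf[1L] <- 1L
  for (i in seq_along(mz)[-1L]) {
    if (.ppmError(mz[i], rep) > ppmWindow) {
      gi <- gi + 1L
      rep <- mz[i]
    }
    groupOf[i] <- gi
  }
  data.frame(
    group_id = sprintf("G%03d", seq_len(gi)),
    representative_mz = vapply(split(mz, groupOf), min, numeric(1),
                               USE.NAMES = FALSE),
    n_members = as.integer(tabulate(groupOf, gi)),
    member_mz = I(unname(split(mz, groupOf))),
    member_nodes = I(unname(split(nodes, groupOf))),
    stringsAsFactors = FALSE
  )
}

#' Rank candidate compound families by subnetwork coverage
#'
#' Sort key: number of covered compound groups (descending), then family
#' size (descending), then mean pairwise member similarity (descending),
#' then smallest member id (ascending). Ranks 1..k are assigned in that
#' order. Coverage, not size, is the primary key because large families of
#' isobaric regio-/stereoisomers would otherwise dominate.
#'
#' @param families data.frame with columns `coverage`, `size`,
#'   `mean_similarity` and list column `members`.
#' @return The same data.frame, sorted, with a `rank` column.
#' @export
rankFamilies <- function(families) {
  stopifnot(is.data.frame(families))
  if (nrow(families) == 0L) {
    families$rank <- integer(0)
    return(families)
  }
  if (!"mean_similarity" %in% colnames(families)) {
    families$mean_similarity <- 0
  }
  firstMember <- vapply(families$members, function(m) sort(m)[1L],
                        character(1))
  ord <- order(-families$coverage, -families$size,
               -families$mean_similarity, firstMember)
  families <- families[ord, , drop = FALSE]
  families$rank <- seq_len(nrow(families))
  rownames(families) <- NULL
  families
}

# Mean pairwise similarity among a family's members (1 for singletons).
.meanPairSim <- function(members, simMatrix) {
  if (length(members) < 2L) return(1)
  s <- simMatrix[members, members, drop = FALSE]
  mean(s[upper.tri(s)])
}

#' Annotate one subnetwork with candidate compound families
#'
#' The core pipeline: bin the subnetwork masses into compound groups, query
#' every representative mass against the reference database through the
#' adduct panel, pool all candidate compounds (deduplicated across groups),
#' cluster them into compound families by fingerprint similarity, drop
#' families below the minimum size, rank the rest by how many compound
#' groups their members explain, and size-filter the resulting graph.
#'
#' @param features data.frame of mass features (`mz`, `node_id`, optionally
#'   `subnetwork_id`).
#' @param db A [CompoundDb-class].
#' @param params A [SnapmsParams-class].
#' @return An [AnnotationResult-class]; its status is `annotated`,
#'   `no_candidates`, `all_families_filtered` or `graph_too_large`.
#' @export
annotateSubnetwork <- function(features, db, params = snapmsParams()) {
  stopifnot(is(db, "CompoundDb"), is(params, "SnapmsParams"))
  if (nRecords(db) == 0L) stop("reference database is empty", call. = FALSE)
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop("no mass features supplied", call. = FALSE)
  }
  snid <- if ("subnetwork_id" %in% colnames(features)) {
    as.character(features$subnetwork_id[1L])
  } else "S1"

  groups <- binMasses(features, params@ppmWindow)

  matches <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    hit <- queryMass(db, groups$representative_mz[i], params@adducts,
                     params@ppmWindow)
    if (nrow(hit)) {
      matches[[i]] <- cbind(
        data.frame(group_id = groups$group_id[i],
                   representative_mz = groups$representative_mz[i],
                   stringsAsFactors = FALSE),
        hit[, c("compound_id", "name", "formula", "adduct",
                "theoretical_mz", "ppm_error")]
      )
    }
  }
  matches <- do.call(rbind, matches[!vapply(matches, is.null, logical(1))])
  if (is.null(matches)) matches <- .emptyMatches()
  rownames(matches) <- NULL

  emptyNet <- new("SimilarityNetwork", nodes = character(0),
                  edges = data.frame(from = character(0), to = character(0),
                                     score = numeric(0)),
                  method = params@fpMethod, radius = as.numeric(params@fpRadius),
                  metric = params@metric, cutoff = params@cutoff)
  emptyFam <- data.frame(family_id = character(0), size = integer(0),
                         members = I(list()), covered_groups = I(list()),
                         coverage = integer(0), mean_similarity = numeric(0),
                         rank = integer(0), stringsAsFactors = FALSE)

  result <- function(status, families = emptyFam, net = emptyNet,
                     candidateCount = 0L) {
    new("AnnotationResult", subnetworkId = snid, compoundGroups = groups,
        candidateCount = as.integer(candidateCount), matches = matches,
        families = families, resultsGraph = net, status = status,
        params = params)
  }

  if (nrow(matches) == 0L) return(result("no_candidates"))

  candIds <- unique(matches$compound_id)
  rec <- dbRecords(db)
  cand <- rec[match(candIds, rec$compound_id), , drop = FALSE]

  net <- suppressWarnings(
    buildSimilarityNetwork(cand, params@fpMethod, params@fpRadius,
                           params@metric, params@cutoff))
  fams <- extractFamilies(net)

  # coverage: distinct compound groups matched by any member, any adduct
  groupsOf <- split(matches$group_id, matches$compound_id)
  fams$covered_groups <- I(lapply(fams$members, function(m) {
    sort(unique(unlist(groupsOf[m], use.names = FALSE)))
  }))
  fams$coverage <- vapply(fams$covered_groups, length, integer(1))

  fp <- computeFingerprints(stats::setNames(cand$smiles, cand$compound_id),
                            params@fpMethod, params@fpRadius)
  simM <- if (nrow(fp) >= 2L) .similarityMatrix(fp, params@metric) else NULL
  fams$mean_similarity <- vapply(fams$members, function(m) {
    if (is.null(simM)) 1 else .meanPairSim(intersect(m, rownames(fp)), simM)
  }, numeric(1))

  fams <- fams[fams$size >= params@minFamilySize, , drop = FALSE]
  if (nrow(fams) == 0L) {
    return(result("all_families_filtered", candidateCount = length(candIds)))
  }
  fams <- rankFamilies(fams)

  keepNodes <- sort(unique(unlist(fams$members, use.names = FALSE)))
  keepEdges <- net@edges[net@edges$from %in% keepNodes &
                           net@edges$to %in% keepNodes, , drop = FALSE]
  rownames(keepEdges) <- NULL
  resNet <- new("SimilarityNetwork", nodes = keepNodes, edges = keepEdges,
                method = net@method, radius = net@radius, metric = net@metric,
                cutoff = net@cutoff)

  out <- result("annotated", families = fams, net = resNet,
                candidateCount = length(candIds))
  filterResultGraph(out, params)
}

#' Apply the results-graph size filter
#'
#' Results graphs larger than the configured node or edge limits are not
#' useful for family identification; such results are flagged
#' `graph_too_large` and their family list cleared, rather than silently
#' dropped, so database-driven false negatives stay auditable.
#'
#' @param result An [AnnotationResult-class].
#' @param params A [SnapmsParams-class].
#' @return The (possibly re-flagged) [AnnotationResult-class].
#' @export
filterResultGraph <- function(result, params = result@params) {
  stopifnot(is(result, "AnnotationResult"))
  net <- result@resultsGraph
  if (length(net@nodes) > params@maxNodeCount ||
      nrow(net@edges) > params@maxEdgeCount) {
    result@status <- "graph_too_large"
    result@families <- result@families[0L, , drop = FALSE]
    result@resultsGraph <- new("SimilarityNetwork", nodes = character(0),
                               edges = net@edges[0L, , drop = FALSE],
                               method = net@method, radius = net@radius,
                               metric = net@metric, cutoff = net@cutoff)
  }
  result
}

#' Annotate every subnetwork of a molecular network or mass list
#'
#' Convenience driver: reads a GraphML molecular network (or a CSV mass
#' list), splits it into subnetworks, and runs [annotateSubnetwork()] on
#' each.
#'
#' @param input Path to a `.graphml` network or `.csv` mass list.
#' @param db A [CompoundDb-class].
#' @param params A [SnapmsParams-class].
#' @param massAttribute Passed to [extractSubnetworksFromGraphml()].
#' @return Named list of [AnnotationResult-class] objects.
#' @export
annotateNetwork <- function(input, db, params = snapmsParams(),
                            massAttribute = NULL) {
  isGraphml <- grepl("\\.graphml$", input, ignore.case = TRUE)
  featureSets <- if (isGraphml) {
    extractSubnetworksFromGraphml(input, params, massAttribute)
  } else {
    list(S1 = parseMassListCsv(input))
  }
  lapply(featureSets, annotateSubnetwork, db = db, params = params)
}

#' Write annotation results as GraphML plus a summary table
#'
#' One GraphML file per `annotated` subnetwork (node attributes:
#' compound id, name, formula, matched adducts, matched group m/z, family
#' rank; edge attribute: similarity score) and a `snapms_summary.tsv` with
#' one row per input subnetwork regardless of status.
#'
#' @param results List of [AnnotationResult-class] objects.
#' @param outDir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
writeAnnotationGraphml <- function(results, outDir) {
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", outDir, "'",
                  call. = FALSE)
  }
  if (file.access(outDir, 2L) != 0L) {
    stop("output directory '", outDir, "' is not writable", call. = FALSE)
  }
  paths <- character(0)
  summary <- data.frame(subnetwork_id = character(0), status = character(0),
                        n_groups = integer(0), n_candidates = integer(0),
                        rank1_family = character(0), rank1_members = character(0),
                        rank1_coverage = integer(0), stringsAsFactors = FALSE)
  for (res in results) {
    stopifnot(is(res, "AnnotationResult"))
    fam <- res@families
    row <- data.frame(
      subnetwork_id = res@subnetworkId, status = res@status,
      n_groups = nrow(res@compoundGroups), n_candidates = res@candidateCount,
      rank1_family = if (nrow(fam)) fam$family_id[1L] else "",
      rank1_members = if (nrow(fam)) {
        paste(fam$members[[1L]], collapse = ";")
      } else "",
      rank1_coverage = if (nrow(fam)) fam$coverage[1L] else 0L,
      stringsAsFactors = FALSE)
    summary <- rbind(summary, row)
    if (res@status != "annotated") next

    memberRank <- rep(NA_integer_, length(res@resultsGraph@nodes))
    names(memberRank) <- res@resultsGraph@nodes
    matchedAdducts <- matchedMz <- stats::setNames(
      character(length(memberRank)), names(memberRank))
    for (i in seq_len(nrow(fam))) {
      memberRank[fam$members[[i]]] <- fam$rank[i]
    }
    m <- res@matches
    for (id in names(memberRank)) {
      mi <- m[m$compound_id == id, , drop = FALSE]
      matchedAdducts[id] <- paste(unique(mi$adduct), collapse = ";")
      matchedMz[id] <- paste(unique(signif(mi$representative_mz, 10)),
                             collapse = ";")
    }
    lookup <- m[!duplicated(m$compound_id), , drop = FALSE]
    li <- match(names(memberRank), lookup$compound_id)
    nd <- data.frame(compound_id = names(memberRank),
                     name = lookup$name[li],
                     formula = lookup$formula[li],
                     family_rank = unname(memberRank),
                     matched_adducts = unname(matchedAdducts),
                     matched_group_mz = unname(matchedMz),
                     stringsAsFactors = FALSE)
    path <- file.path(outDir, paste0("subnetwork_", res@subnetworkId,
                                     ".graphml"))
    exportGraphML(res@resultsGraph, path, nodeData = nd)
    paths <- c(paths, path)
  }
  sumPath <- file.path(outDir, "snapms_summary.tsv")
  utils::write.table(summary, sumPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sumPath))
}
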
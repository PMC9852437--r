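# Fingerprint-method / cutoff selection against a reference MS2 molecular
# network: edge confusion over node pairs, a cutoff sweep, and selection of
# the method with the most true edges at a fixed false-edge ceiling.

# Accept a SimilarityNetwork or an igraph as a reference network; return
# list(nodes, edgeKeys).
.asEdgeSet <- function(net) {
  if (is(net, "SimilarityNetwork")) {
    list(nodes = net@nodes,
         keys = unique(.pairKey(net@edges$from, net@edges$to)))
  } else if (inherits(net, "igraph")) {
    el <- igraph::as_edgelist(net, names = TRUE)
    keys <- if (nrow(el)) unique(.pairKey(el[, 1L], el[, 2L])) else character(0)
    list(nodes = igraph::V(net)$name, keys = keys)
  } else {
    stop("expected a SimilarityNetwork or igraph object", call. = FALSE)
  }
}

#' Edge confusion between a structural and an MS network
#'
#' Over all unordered node pairs of the shared node set:
#' `tp_pct` = percentage of MS-network edges also present in the structural
#' network; `tn_pct` = percentage of MS-network *non*-edges also absent from
#' the structural network. The non-edge denominator (rather than all pairs)
#' keeps a 0.5% false-positive ceiling meaningful on sparse networks.
#'
#' @param structNet Structural [SimilarityNetwork-class].
#' @param msNet Reference MS network ([SimilarityNetwork-class] or igraph
#'   with named vertices) on the same node set.
#' @return Named numeric `c(tp_pct=, tn_pct=)`.
#' @export
edgeConfusion <- function(structNet, msNet) {
  s <- .asEdgeSet(structNet)
  m <- .asEdgeSet(msNet)
  onlyS <- setdiff(s$nodes, m$nodes)
  onlyM <- setdiff(m$nodes, s$nodes)
  if (length(onlyS) || length(onlyM)) {
    stop("node sets differ; only in structural network: {",
         paste(onlyS, collapse = ", "), "}; only in MS network: {",
         paste(onlyM, collapse = ", "), "}", call. = FALSE)
  }
  if (!length(m$keys)) {
    stop("MS network has no edges; tp_pct is undefined", call. = FALSE)
  }
  nPairs <- choose(length(s$nodes), 2)
  tp <- length(intersect(s$keys, m$keys))
  union <- length(s$keys) + length(m$keys) - tp
  absentBoth <- nPairs - union
  negPairs <- nPairs - length(m$keys)
  c(tp_pct = 100 * tp / length(m$keys),
    tn_pct = if (negPairs > 0) 100 * absentBoth / negPairs else 100)
}

#' Default benchmark method panel
#'
#' @return data.frame of (method, radius, metric) configurations compared by
#'   default: Morgan r=2 and r=4 with Dice and Tanimoto, MACCS/Dice and
#'   atom-pair/Dice.
#' @export
benchmarkMethods <- function() {
  data.frame(
    method = c("morgan", "morgan", "morgan", "morgan", "maccs", "atom_pair"),
    radius = c(2L, 2L, 4L, 4L, 2L, 2L),
    metric = c("dice", "tanimoto", "dice", "tanimoto", "dice", "dice"),
    stringsAsFactors = FALSE
  )
}

#' Sweep fingerprint methods over a cutoff grid
#'
#' For each (method, radius, metric) configuration, similarities are
#' computed once and thresholded at every cutoff; each row reports the edge
#' confusion against the reference MS network. MS nodes sharing one
#' structure should be collapsed to a single node keyed by compound id
#' before calling; nodes missing from either side are dropped pairwise with
#' a message, and unparseable structures are dropped from both networks with
#' a warning.
#'
#' @param compounds Named SMILES vector, data.frame with
#'   `compound_id`/`smiles`, or a [CompoundDb-class].
#' @param msNet Reference MS network (igraph with vertex names = compound
#'   ids, or [SimilarityNetwork-class]).
#' @param methods data.frame of configurations (default
#'   [benchmarkMethods()]).
#' @param cutoffs Numeric cutoff grid, default `seq(0.01, 1, 0.01)`.
#' @return data.frame of benchmark rows: `method`, `radius`, `metric`,
#'   `cutoff`, `tp_pct`, `tn_pct`.
#' @export
sweepMethods <- function(compounds, msNet, methods = benchmarkMethods(),
                         cutoffs = seq(0.01, 1, by = 0.01)) {
  stopifnot(is.data.frame(methods),
            all(c("method", "radius", "metric") %in% colnames(methods)),
            nrow(methods) > 0L, length(cutoffs) > 0L)
  smi <- .asSmilesVector(compounds)
  ms <- .asEdgeSet(msNet)

  shared <- intersect(names(smi), ms$nodes)
  dropped <- length(smi) + length(ms$nodes) - 2L * length(shared)
  if (dropped > 0L) {
    message(dropped, " node(s) present on only one side dropped pairwise")
  }
  if (length(shared) < 2L) {
    stop("fewer than two shared nodes between compound list and MS network",
         call. = FALSE)
  }
  smi <- smi[shared]

  rows <- list()
  for (mi in seq_len(nrow(methods))) {
    cfg <- methods[mi, ]
    fp <- computeFingerprints(smi, cfg$method, cfg$radius)
    skipped <- attr(fp, "skipped")
    if (length(skipped)) {
      warning("dropping unparseable structure(s) from both networks: ",
              paste(skipped, collapse = ", "), call. = FALSE)
    }
    nodes <- rownames(fp)
    msKeys <- ms$keys
    if (length(skipped)) {
      bothIn <- function(keys) {
        parts <- strsplit(keys, "\r", fixed = TRUE)
        keep <- vapply(parts, function(p) all(p %in% nodes), logical(1))
        keys[keep]
      }
      msKeys <- bothIn(msKeys)
    } else {
      parts <- strsplit(msKeys, "\r", fixed = TRUE)
      keep <- vapply(parts, function(p) all(p %in% nodes), logical(1))
      msKeys <- msKeys[keep]
    }
    if (!length(msKeys)) {
      stop("no MS edges remain among fingerprintable shared nodes",
           call. = FALSE)
    }
    s <- .similarityMatrix(fp, cfg$metric)
    ut <- upper.tri(s)
    pairScore <- s[ut]
    idx <- which(ut, arr.ind = TRUE)
    pairKeys <- .pairKey(nodes[idx[, 1L]], nodes[idx[, 2L]])
    isMs <- pairKeys %in% msKeys
    nMs <- sum(isMs)
    nNeg <- length(pairKeys) - nMs
    for (co in cutoffs) {
      above <- pairScore >= co - 1e-12
      tp <- sum(above & isMs)
      fp_ <- sum(above & !isMs)
      rows[[length(rows) + 1L]] <- data.frame(
        method = cfg$method, radius = cfg$radius, metric = cfg$metric,
        cutoff = co,
        tp_pct = 100 * tp / nMs,
        tn_pct = if (nNeg > 0) 100 * (nNeg - fp_) / nNeg else 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the clustering method at a false-edge ceiling
#'
#' For each configuration, takes the smallest cutoff whose true-negative
#' percentage reaches `minTnPct`, then picks the configuration with the
#' highest true-positive percentage at that cutoff. Ties break to the lower
#' cutoff, then to the alphabetically first method label.
#'
#' @param rows Benchmark rows from [sweepMethods()].
#' @param minTnPct True-negative floor in percent (default 99.5, i.e. a
#'   0.5% false-edge ceiling).
#' @return One-row data.frame (`method`, `radius`, `metric`, `cutoff`,
#'   `tp_pct`, `tn_pct`), or a zero-row data.frame (with a warning) when no
#'   configuration reaches the ceiling.
#' @export
selectClusteringMethod <- function(rows, minTnPct = 99.5) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0L)
  key <- paste(rows$method, rows$radius, rows$metric)
  picks <- lapply(split(rows, key), function(r) {
    ok <- r[r$tn_pct >= minTnPct, , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
    ok[which.min(ok$cutoff), , drop = FALSE]
  })
  picks <- do.call(rbind, picks[!vapply(picks, is.null, logical(1))])
  if (is.null(picks) || nrow(picks) == 0L) {
    warning("no configuration reaches tn_pct >= ", minTnPct, call. = FALSE)
    return(rows[0L, , drop = FALSE])
  }
  ord <- order(-picks$tp_pct, picks$cutoff,
               paste(picks$method, picks$radius, picks$metric))
  out <- picks[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}
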
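# Structure fingerprinting, pairwise similarity, similarity networks and
# compound-family extraction.

.FP_METHODS <- c("morgan", "maccs", "atom_pair")
.FP_NBITS <- 2048L    # hashed length for morgan / atom_pair
.MACCS_NBITS <- 166L  # defined MACCS keys

# On-bit indices for a batch of structures under one method; returns a
# named list covering the structures that could be fingerprinted.
.rawBits <- function(smiles, method, radius, nbits) {
  if (method %in% c("morgan", "maccs")) {
    fpName <- if (method == "maccs") "MACCS" else paste0("ECFP", 2L * radius)
    bits <- .obFingerprints(smiles, fpName)
    if (method == "morgan") {
      # fold OpenBabel's native 4096-bit ECFP down to nbits
      bits <- lapply(bits, function(b) sort(unique((b - 1L) %% nbits + 1L)))
    }
    bits
  } else {
    parsed <- .smilesToSdf(smiles)
    if (!length(parsed$ok)) return(list())
    ap <- ChemmineR::sdf2ap(parsed$sdf)
    ids <- ChemmineR::sdfid(parsed$sdf)
    out <- lapply(seq_along(ids), function(i) {
      sort(unique(as.integer(ap@AP[[i]] %% nbits) + 1L))
    })
    stats::setNames(out, ids)[parsed$ok]
  }
}

# Fingerprint a named SMILES vector with memoisation. Returns a logical
# matrix (rows = structures that parsed, in input order) with attribute
# "skipped" listing the names that failed.
.fingerprintMatrix <- function(smiles, method, radius, nbits) {
  keys <- paste(method, radius, smiles, sep = "|")
  cached <- vapply(keys, exists, logical(1), envir = .snapfamCache,
                   USE.NAMES = FALSE)
  if (any(!cached)) {
    todoIdx <- which(!cached)[!duplicated(keys[!cached])]
    todo <- smiles[todoIdx]
    names(todo) <- paste0("q", seq_along(todo))
    bits <- .rawBits(todo, method, radius, nbits)
    for (j in seq_along(todo)) {
      assign(keys[todoIdx[j]], bits[[names(todo)[j]]],
             envir = .snapfamCache)
    }
  }
  width <- if (method == "maccs") .MACCS_NBITS else nbits
  rows <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    b <- get(keys[i], envir = .snapfamCache)
    if (is.null(b)) next
    ok[i] <- TRUE
    rows[[i]] <- b
  }
  m <- matrix(FALSE, sum(ok), width,
              dimnames = list(names(smiles)[ok], NULL))
  for (i in seq_len(sum(ok))) m[i, rows[which(ok)[i]][[1L]]] <- TRUE
  attr(m, "skipped") <- names(smiles)[!ok]
  attr(m, "method") <- method
  attr(m, "radius") <- radius
  m
}

.checkFpArgs <- function(method, radius) {
  if (!method %in% .FP_METHODS) {
    stop("method must be one of ", paste(.FP_METHODS, collapse = ", "),
         call. = FALSE)
  }
  if (method == "morgan" && (!radius %in% 1:5)) {
    stop("morgan radius must be an integer in 1..5 (the circular-environment ",
         "diameters available from the fingerprinter)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute a chemical fingerprint for one structure
#'
#' Deterministic hashed binary fingerprints: Morgan (circular, radius-
#' parameterised, 2048 bits), MACCS (166 structural keys), or atom-pair
#' (hashed to 2048 bits). Equivalent SMILES spellings of the same molecule
#' give identical bit sets.
#'
#' @param smiles A single SMILES string.
#' @param method `"morgan"`, `"maccs"` or `"atom_pair"`.
#' @param radius Morgan radius (1..5; ignored for other methods).
#' @return Logical bit vector with attributes `method` and `radius`.
#' @examples
#' \donttest{
#' fp <- computeFingerprint("c1ccccc1O", "morgan", 2)
#' sum(fp)
#' }
#' @export
computeFingerprint <- function(smiles, method = "morgan", radius = 2L) {
  .checkFpArgs(method, radius)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  names(smiles) <- "x"
  m <- .fingerprintMatrix(smiles, method, as.integer(radius), .FP_NBITS)
  if (nrow(m) == 0L) {
    stop("unparseable structure: '", smiles, "'", call. = FALSE)
  }
  out <- m[1L, ]
  attr(out, "method") <- method
  attr(out, "radius") <- as.integer(radius)
  out
}

#' Fingerprint a set of structures
#'
#' Vectorised form of [computeFingerprint()]: unparseable structures are
#' dropped (their ids are returned in the `"skipped"` attribute) rather than
#' raising an error.
#'
#' @param smiles Named character vector of SMILES (names are compound ids).
#' @inheritParams computeFingerprint
#' @return Logical matrix, one row per successfully parsed structure.
#' @export
computeFingerprints <- function(smiles, method = "morgan", radius = 2L) {
  .checkFpArgs(method, radius)
  stopifnot(is.character(smiles), !is.null(names(smiles)))
  .fingerprintMatrix(smiles, method, as.integer(radius), .FP_NBITS)
}

#' Pairwise fingerprint similarity
#'
#' Sorensen-Dice `2|A&B| / (|A|+|B|)` or Tanimoto `|A&B| / |A or B|` on two
#' bit sets from the same fingerprint method. Two empty bit sets score 0 under
#' both metrics.
#'
#' @param a,b Logical bit vectors from [computeFingerprint()].
#' @param metric `"dice"` or `"tanimoto"`.
#' @return Similarity score in \[0, 1\].
#' @export
pairwiseSimilarity <- function(a, b, metric = c("dice", "tanimoto")) {
  metric <- match.arg(metric)
  ma <- attr(a, "method"); mb <- attr(b, "method")
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb)) {
    stop("fingerprints come from different methods (", ma, " vs ", mb, ")",
         call. = FALSE)
  }
  if (length(a) != length(b)) {
    stop("fingerprints have different lengths; were they computed with the ",
         "same method and parameters?", call. = FALSE)
  }
  nab <- sum(a & b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(0)
  if (metric == "dice") 2 * nab / (na + nb) else nab / (na + nb - nab)
}

# All-pairs similarity matrix from a logical fingerprint matrix.
.similarityMatrix <- function(fp, metric) {
  inter <- tcrossprod(fp * 1L)
  n <- diag(inter)
  if (metric == "dice") {
    denom <- outer(n, n, "+")
    s <- ifelse(denom > 0, 2 * inter / denom, 0)
  } else {
    denom <- outer(n, n, "+") - inter
    s <- ifelse(denom > 0, inter / denom, 0)
  }
  dimnames(s) <- dimnames(inter)
  s
}

# Normalise buildSimilarityNetwork-style inputs to a named SMILES vector.
.asSmilesVector <- function(x) {
  if (is(x, "CompoundDb")) {
    smi <- x@records$smiles
    names(smi) <- x@records$compound_id
  } else if (is.data.frame(x)) {
    stopifnot(all(c("compound_id", "smiles") %in% colnames(x)))
    smi <- x$smiles
    names(smi) <- x$compound_id
  } else {
    smi <- x
    stopifnot(is.character(smi), !is.null(names(smi)))
  }
  smi
}

#' Build a chemical similarity network
#'
#' All-pairs fingerprint similarity over a compound set; an undirected edge
#' is kept iff the score is at or above `cutoff` (closed threshold, so the
#' printed cutoffs are attainable exactly). Isolated nodes are retained.
#' Structures that fail to parse are skipped with a warning.
#'
#' @param x A [CompoundDb-class], a data.frame with `compound_id` and
#'   `smiles`, or a named SMILES vector.
#' @param method,radius Fingerprint configuration (see
#'   [computeFingerprint()]).
#' @param metric `"dice"` or `"tanimoto"`.
#' @param cutoff Score threshold in (0, 1]. Default 0.71, the candidate-
#'   clustering cutoff.
#' @return A [SimilarityNetwork-class].
#' @export
buildSimilarityNetwork <- function(x, method = "morgan", radius = 2L,
                                   metric = c("dice", "tanimoto"),
                                   cutoff = 0.71) {
  metric <- match.arg(metric)
  .checkFpArgs(method, radius)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1) {
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  }
  smi <- .asSmilesVector(x)
  if (!length(smi)) stop("no compounds supplied", call. = FALSE)
  fp <- computeFingerprints(smi, method, radius)
  if (length(attr(fp, "skipped"))) {
    warning("skipping unparseable structure(s): ",
            paste(attr(fp, "skipped"), collapse = ", "), call. = FALSE)
  }
  nodes <- rownames(fp)
  if (nrow(fp) >= 2L) {
    s <- .similarityMatrix(fp, metric)
    idx <- which(upper.tri(s) & s >= cutoff - 1e-12, arr.ind = TRUE)
    edges <- data.frame(
      from = nodes[idx[, 1L]],
      to = nodes[idx[, 2L]],
      score = s[idx],
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  new("SimilarityNetwork", nodes = nodes, edges = edges, method = method,
      radius = as.numeric(radius), metric = metric, cutoff = cutoff)
}

# igraph view of a SimilarityNetwork (keeps isolated nodes).
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

#' Extract compound families from a similarity network
#'
#' One family per connected component (singletons included). Families are
#' ordered, and given ids, by their lexicographically smallest member id, so
#' the labelling is deterministic.
#'
#' @param net A [SimilarityNetwork-class].
#' @return data.frame with columns `family_id`, `size`, and list column
#'   `members` (sorted compound ids).
#' @export
extractFamilies <- function(net) {
  stopifnot(is(net, "SimilarityNetwork"))
  if (!length(net@nodes)) {
    return(data.frame(family_id = character(0), size = integer(0),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  comp <- igraph::components(.asIgraph(net))
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(m) sort(unname(m)))
  first <- vapply(members, `[`, character(1), 1L)
  members <- members[order(first)]
  data.frame(
    family_id = sprintf("CF%04d", seq_along(members)),
    size = vapply(members, length, integer(1)),
    members = I(unname(members)),
    stringsAsFactors = FALSE
  )
}

#' Export a similarity network to GraphML
#'
#' @param net A [SimilarityNetwork-class].
#' @param path Output file path.
#' @param nodeData Optional data.frame of node attributes with a
#'   `compound_id` column (e.g. name, formula, family rank).
#' @return The path, invisibly.
#' @export
exportGraphML <- function(net, path, nodeData = NULL) {
  stopifnot(is(net, "SimilarityNetwork"))
  g <- .asIgraph(net)
  igraph::V(g)$compound_id <- igraph::V(g)$name
  if (!is.null(nodeData)) {
    stopifnot("compound_id" %in% colnames(nodeData))
    idx <- match(igraph::V(g)$name, nodeData$compound_id)
    for (col in setdiff(colnames(nodeData), "compound_id")) {
      val <- nodeData[[col]][idx]
      if (is.list(val)) {
        val <- vapply(val, function(v) paste(v, collapse = ";"), character(1))
      }
      g <- igraph::set_vertex_attr(g, col, value = val)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
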
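# Molecular-formula tuple diagnosticity statistics over database compound
# families: how often a formula (or a pair/triple of distinct formulae)
# co-occurs across families.

#' Molecular-formula census of a reference database
#'
#' Counts how many database molecules carry each (Hill-normalised) formula.
#'
#' @param db A [CompoundDb-class].
#' @return data.frame with columns `formula` and `n`, sorted by decreasing
#'   multiplicity then formula; attribute `n_singletons` gives the number of
#'   formulae appearing exactly once.
#' @export
formulaCounts <- function(db) {
  stopifnot(is(db, "CompoundDb"))
  tab <- table(dbRecords(db)$formula)
  out <- data.frame(formula = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_singletons") <- sum(out$n == 1L)
  out
}

#' Precompute compound families over a whole database
#'
#' Convenience wrapper for the database-wide family grouping used by the
#' formula statistics: fingerprint every record and take connected
#' components at the database cutoff (default Dice >= 0.75, Morgan r = 2).
#'
#' @param db A [CompoundDb-class].
#' @param method,radius,metric,cutoff Clustering configuration.
#' @return Family table as returned by [extractFamilies()].
#' @export
databaseFamilies <- function(db, method = "morgan", radius = 2L,
                             metric = "dice", cutoff = 0.75) {
  net <- buildSimilarityNetwork(db, method, radius, metric, cutoff)
  extractFamilies(net)
}

#' Count formula-tuple occurrence across compound families
#'
#' For every k-subset (k = 1, 2 or 3) of *distinct* formulae that co-occurs
#' within at least one compound family, counts the number of families whose
#' formula set contains the whole tuple. Only tuples observed in some family
#' are enumerated. Formulae appearing exactly once in the whole database can
#' be excluded first, the exclusion used by the published census.
#'
#' @param families Family table from [extractFamilies()] /
#'   [databaseFamilies()] (list column `members`).
#' @param db The [CompoundDb-class] the families were computed on.
#' @param k Tuple size: 1, 2 or 3.
#' @param excludeGlobalSingletons Drop formulae with database-wide molecule
#'   count 1 before enumeration (default TRUE).
#' @param minFamilySize Only census families with at least this many members
#'   (default 1 = all families).
#' @return data.frame with columns `f1`..`fk` (tuple members, sorted),
#'   `n_families`, and list column `n_molecules` (database-wide molecule
#'   count of each tuple member).
#' @export
familyTupleOccurrence <- function(families, db, k = 1L,
                                  excludeGlobalSingletons = TRUE,
                                  minFamilySize = 1L) {
  stopifnot(is(db, "CompoundDb"), is.data.frame(families))
  if (!k %in% 1:3) stop("k must be 1, 2 or 3", call. = FALSE)
  k <- as.integer(k)
  counts <- formulaCounts(db)
  countOf <- stats::setNames(counts$n, counts$formula)
  eligible <- if (excludeGlobalSingletons) {
    counts$formula[counts$n > 1L]
  } else {
    counts$formula
  }
  rec <- dbRecords(db)
  formulaOf <- stats::setNames(rec$formula, rec$compound_id)

  tupleCount <- new.env(parent = emptyenv())
  fams <- families[vapply(families$members, length, integer(1)) >=
                     minFamilySize, , drop = FALSE]
  for (members in fams$members) {
    fs <- sort(unique(formulaOf[members]))
    fs <- fs[!is.na(fs) & fs %in% eligible]
    if (length(fs) < k) next
    combos <- utils::combn(fs, k)
    keys <- apply(combos, 2L, paste, collapse = "\r")
    for (key in keys) {
      prev <- if (exists(key, envir = tupleCount)) {
        get(key, envir = tupleCount)
      } else 0L
      assign(key, prev + 1L, envir = tupleCount)
    }
  }
  keys <- sort(ls(tupleCount))
  if (!length(keys)) {
    out <- as.data.frame(matrix(character(0), 0L, k,
                                dimnames = list(NULL, paste0("f", 1:k))),
                         stringsAsFactors = FALSE)
    out$n_families <- integer(0)
    out$n_molecules <- I(list())
    return(out)
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  colnames(out) <- paste0("f", 1:k)
  out$n_families <- vapply(keys, get, integer(1), envir = tupleCount,
                           USE.NAMES = FALSE)
  out$n_molecules <- I(lapply(seq_len(nrow(parts)), function(i) {
    unname(countOf[parts[i, ]])
  }))
  out <- out[order(-out$n_families, out$f1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a tuple-occurrence census
#'
#' Proportion of tuples found in exactly one, exactly two, or three-or-more
#' compound families, plus a log-occurrence histogram over the number of
#' families.
#'
#' @param counts Output of [familyTupleOccurrence()].
#' @return List with `proportions` (named numeric, sums to 1) and
#'   `histogram` (data.frame `n_families`, `n_tuples`, `log10_n_tuples`).
#' @export
distributionSummary <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) stop("empty tuple census", call. = FALSE)
  nf <- counts$n_families
  props <- c(one = mean(nf == 1L), two = mean(nf == 2L),
             three_plus = mean(nf >= 3L))
  tab <- table(nf)
  hist <- data.frame(n_families = as.integer(names(tab)),
                     n_tuples = as.integer(tab))
  hist$log10_n_tuples <- log10(hist$n_tuples)
  list(proportions = props, histogram = hist)
}
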
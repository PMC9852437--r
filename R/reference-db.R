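# Reference-database loading, taxonomy filtering and mass-window queries.

# Construct a CompoundDb from a validated record table.
.newCompoundDb <- function(records, taxonomyRanks = character(0),
                           sourceDb = "fixture", skipped = 0L) {
  rownames(records) <- NULL
  new("CompoundDb",
      records = records,
      taxonomyRanks = taxonomyRanks,
      sourceDb = sourceDb,
      massOrder = order(records$exact_mass),
      skipped = as.integer(skipped))
}

#' Build a reference database from a record table
#'
#' Constructor used by the dump loaders and the fixture generator. Structures
#' are parsed; entries whose SMILES cannot be converted are dropped and
#' counted. Missing formulae are derived from the parsed structure, and every
#' `exact_mass` is recomputed from the (Hill-normalised) formula so mass
#' queries and formula statistics are internally consistent.
#'
#' @param records data.frame with columns `compound_id`, `name`, `smiles`,
#'   optionally `formula`, plus any taxonomy columns named in `taxonomyRanks`.
#' @param taxonomyRanks Character vector of taxonomy column names.
#' @param sourceDb `"npatlas"`, `"coconut"` or `"fixture"`.
#' @param force Keep going (with a warning) even if more than half of the
#'   entries had to be skipped.
#' @return A [CompoundDb-class].
#' @export
compoundDb <- function(records, taxonomyRanks = character(0),
                       sourceDb = "fixture", force = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("compound_id", "name", "smiles")
  if (!all(need %in% colnames(records))) {
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nIn <- nrow(records)
  records$compound_id <- as.character(records$compound_id)
  if (anyDuplicated(records$compound_id)) {
    stop("compound_id values must be unique", call. = FALSE)
  }
  if (!"formula" %in% colnames(records)) records$formula <- NA_character_

  smi <- records$smiles
  names(smi) <- records$compound_id
  derived <- .obFormula(smi)
  keep <- records$compound_id %in% names(derived)
  records <- records[keep, , drop = FALSE]

  # derive formulae from structures where the dump carries none
  noFormula <- is.na(records$formula) | !nzchar(records$formula)
  records$formula[noFormula] <-
    unname(derived[records$compound_id[noFormula]])

  hill <- vapply(records$formula, function(f) {
    tryCatch(hillFormula(f), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  badFormula <- is.na(hill)
  records <- records[!badFormula, , drop = FALSE]
  records$formula <- hill[!badFormula]
  records$exact_mass <- formulaMonoisotopicMass(records$formula)

  skipped <- nIn - nrow(records)
  if (nIn > 0L && skipped > nIn / 2 && !force) {
    stop(skipped, "/", nIn, " entries skipped; use force = TRUE to accept a ",
         "majority-unparseable dump", call. = FALSE)
  }
  if (skipped > 0L) {
    warning(skipped, " of ", nIn, " entries skipped (unparseable structure ",
            "or formula)", call. = FALSE)
  }
  keepCols <- c("compound_id", "name", "smiles", "formula", "exact_mass",
                taxonomyRanks)
  .newCompoundDb(records[, keepCols, drop = FALSE], taxonomyRanks, sourceDb,
                 skipped)
}

## ---- dump dialects ---------------------------------------------------------

# Column dialects for the supported tabular dumps (matched case-insensitively
# after stripping non-alphanumerics).
.TSV_DIALECTS <- list(
  fixture_tsv = list(
    id = "compound_id", name = "name", smiles = "smiles",
    formula = NULL, ranks = c(genus = "genus", phylum = "phylum"),
    source = "fixture"),
  npatlas_tsv = list(
    id = c("npaid"), name = c("compoundnames", "compoundname"),
    smiles = c("compoundsmiles", "smiles"),
    formula = c("compoundmolecularformula", "molformula"),
    ranks = c(genus = "genus", origin_type = "origintype"),
    source = "npatlas"),
  coconut = list(
    id = c("coconutid", "id"), name = c("name", "compoundname"),
    smiles = c("smiles", "canonicalsmiles", "uniquesmiles"),
    formula = c("molecularformula", "formula"),
    ranks = NULL, source = "coconut")
)

.normHeader <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.pickColumn <- function(tab, aliases, what, required = TRUE) {
  if (is.null(aliases)) return(NULL)
  hit <- match(.normHeader(aliases), .normHeader(colnames(tab)))
  hit <- hit[!is.na(hit)]
  if (!length(hit)) {
    if (required) {
      stop("no column matching ", what, " (tried: ",
           paste(aliases, collapse = ", "), ") among: ",
           paste(colnames(tab), collapse = ", "), call. = FALSE)
    }
    return(NULL)
  }
  tab[[hit[1L]]]
}

.loadTabular <- function(path, dialect, force) {
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "",
                      check.names = FALSE, comment.char = ""),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rec <- data.frame(
    compound_id = as.character(.pickColumn(tab, dialect$id, "compound id")),
    name = as.character(.pickColumn(tab, dialect$name, "compound name")),
    smiles = as.character(.pickColumn(tab, dialect$smiles, "SMILES")),
    stringsAsFactors = FALSE
  )
  f <- .pickColumn(tab, dialect$formula, "formula", required = FALSE)
  if (!is.null(f)) rec$formula <- as.character(f)
  ranks <- character(0)
  for (rank in names(dialect$ranks)) {
    v <- .pickColumn(tab, dialect$ranks[[rank]], rank, required = FALSE)
    if (!is.null(v)) {
      rec[[rank]] <- as.character(v)
      ranks <- c(ranks, rank)
    }
  }
  compoundDb(rec, taxonomyRanks = ranks, sourceDb = dialect$source,
             force = force)
}

# NPAtlas JSON dump: a top-level array of compound objects. Taxonomy is taken
# from origin_organism (genus/species directly; higher ranks from the
# ancestor list when present).
.loadNpatlasJson <- function(path, force) {
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (!length(raw)) stop("empty NPAtlas JSON dump", call. = FALSE)
  pick <- function(entry, keys) {
    for (k in keys) {
      v <- entry[[k]]
      if (!is.null(v) && length(v) == 1L && !is.na(v) && nzchar(as.character(v)))
        return(as.character(v))
    }
    NA_character_
  }
  getRank <- function(entry, rank) {
    org <- entry[["origin_organism"]]
    if (is.null(org)) return(NA_character_)
    direct <- org[[rank]]
    if (!is.null(direct) && length(direct) == 1L) return(as.character(direct))
    anc <- org[["taxon"]][["ancestors"]]
    if (is.null(anc)) return(NA_character_)
    for (a in anc) {
      if (identical(tolower(as.character(a[["rank"]])), rank)) {
        return(as.character(a[["name"]]))
      }
    }
    NA_character_
  }
  rec <- data.frame(
    compound_id = vapply(raw, pick, character(1), keys = c("npaid", "id")),
    name = vapply(raw, pick, character(1),
                  keys = c("original_name", "name")),
    smiles = vapply(raw, pick, character(1), keys = "smiles"),
    formula = vapply(raw, pick, character(1),
                     keys = c("mol_formula", "molecular_formula")),
    genus = vapply(raw, getRank, character(1), rank = "genus"),
    phylum = vapply(raw, getRank, character(1), rank = "phylum"),
    kingdom = vapply(raw, getRank, character(1), rank = "kingdom"),
    stringsAsFactors = FALSE
  )
  compoundDb(rec, taxonomyRanks = c("genus", "phylum", "kingdom"),
             sourceDb = "npatlas", force = force)
}

#' Load a structure reference database
#'
#' Reads one of the supported dump dialects into a [CompoundDb-class]:
#' `npatlas_json` / `npatlas_tsv` (Natural Products Atlas dumps, with
#' organism taxonomy), `coconut` (TSV, no taxonomy), or `fixture_tsv`
#' (tab-separated `compound_id name smiles genus phylum`; formula and mass
#' derived from the structure).
#'
#' Entries with unparseable structures are skipped and counted (see
#' [nSkipped()]); if more than half of the entries are skipped the load
#' aborts unless `force = TRUE`.
#'
#' @param path Path to the dump file.
#' @param format One of `"npatlas_json"`, `"npatlas_tsv"`, `"coconut"`,
#'   `"fixture_tsv"`.
#' @param force Accept majority-unparseable dumps with a warning.
#' @return A [CompoundDb-class].
#' @export
loadReferenceDb <- function(path,
                            format = c("fixture_tsv", "npatlas_json",
                                       "npatlas_tsv", "coconut"),
                            force = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "npatlas_json") {
    .loadNpatlasJson(path, force)
  } else {
    .loadTabular(path, .TSV_DIALECTS[[format]], force)
  }
}

#' Filter a reference database by taxonomy
#'
#' Keeps exactly the records whose taxonomy at `rank` matches one of `names`
#' (case-insensitive); indices are rebuilt. COCONUT dumps carry no usable
#' taxonomy, so filtering a COCONUT database is an error.
#'
#' @param db A [CompoundDb-class].
#' @param rank A taxonomy rank present in the database (see [taxonomyRanks()]).
#' @param names Character vector of taxon names to keep.
#' @return The filtered [CompoundDb-class] (possibly empty, with a warning).
#' @export
filterByTaxonomy <- function(db, rank, names) {
  stopifnot(is(db, "CompoundDb"))
  if (db@sourceDb == "coconut") {
    stop("COCONUT dumps carry no usable taxonomy; taxonomy filtering is ",
         "only available for NPAtlas or fixture databases", call. = FALSE)
  }
  if (!is.character(rank) || length(rank) != 1L ||
      !rank %in% db@taxonomyRanks) {
    stop("unknown taxonomy rank '", rank, "'; valid ranks: ",
         paste(db@taxonomyRanks, collapse = ", "), call. = FALSE)
  }
  keep <- tolower(db@records[[rank]]) %in% tolower(names)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("no records match ", rank, " in {",
            paste(names, collapse = ", "), "}", call. = FALSE)
  }
  .newCompoundDb(db@records[keep, , drop = FALSE], db@taxonomyRanks,
                 db@sourceDb, 0L)
}

#' Query a reference database by observed m/z
#'
#' Returns every (record, adduct) pair whose theoretical adduct m/z lies
#' within `ppmWindow` ppm of the observed `mz`. The same record may match
#' under more than one adduct. The ppm error is signed and computed relative
#' to the theoretical adduct m/z.
#'
#' @param db A [CompoundDb-class].
#' @param mz Observed m/z (positive scalar).
#' @param adducts Adduct panel (data.frame) or character vector of adduct
#'   names; defaults to the three-species panel of [adductPanel()].
#' @param ppmWindow Mass tolerance in ppm (positive).
#' @return data.frame of candidate matches sorted by `abs(ppm_error)`:
#'   columns `compound_id`, `name`, `formula`, `exact_mass`, `adduct`,
#'   `theoretical_mz`, `ppm_error`.
#' @export
queryMass <- function(db, mz, adducts = adductPanel(), ppmWindow = 10) {
  stopifnot(is(db, "CompoundDb"))
  if (!is.numeric(mz) || length(mz) != 1L || mz <= 0) {
    stop("'mz' must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(ppmWindow) || ppmWindow <= 0) {
    stop("'ppmWindow' must be positive", call. = FALSE)
  }
  adducts <- resolveAdducts(adducts)
  rec <- db@records
  sortedMass <- rec$exact_mass[db@massOrder]
  out <- vector("list", nrow(adducts))
  for (i in seq_len(nrow(adducts))) {
    shift <- adducts$mass_shift[i]
    # theoretical m/z window -> neutral-mass window on the sorted index
    lo <- mz / (1 + ppmWindow * 1e-6) - shift
    hi <- mz / (1 - ppmWindow * 1e-6) - shift
    iLo <- findInterval(lo, sortedMass, left.open = TRUE) + 1L
    iHi <- findInterval(hi, sortedMass)
    if (iHi < iLo) next
    idx <- db@massOrder[iLo:iHi]
    theo <- rec$exact_mass[idx] + shift
    err <- .ppmError(mz, theo)
    ok <- abs(err) <= ppmWindow + 1e-12
    if (!any(ok)) next
    out[[i]] <- data.frame(
      compound_id = rec$compound_id[idx][ok],
      name = rec$name[idx][ok],
      formula = rec$formula[idx][ok],
      exact_mass = rec$exact_mass[idx][ok],
      adduct = adducts$name[i],
      theoretical_mz = theo[ok],
      ppm_error = err[ok],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(compound_id = character(0), name = character(0),
                      formula = character(0), exact_mass = numeric(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(abs(out$ppm_error), out$compound_id, out$adduct), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
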
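# Integration checks that require the externally distributed reference
# inputs (the pinned NPAtlas v2020_06 dump, the actinobacterial molecular
# network, the NIH Round-1 standards network). These are not shipped with
# the package; each helper runs the full computation when pointed at the
# downloaded files and returns the headline quantities.

#' Database census on a full reference dump
#'
#' Loads the dump and computes the formula census: number of records,
#' unique formulae, formulae occurring once, and the most common formula
#' with its multiplicity. On the NPAtlas v2020_06 dump this reproduces
#' 29,006 records, 12,666 unique formulae, 8349 singletons and C15H22O3
#' with 151 instances.
#'
#' @param dbPath Path to the downloaded dump.
#' @param format Dump format (see [loadReferenceDb()]).
#' @return Named list of census quantities (includes the loaded `db` for
#'   follow-up analyses).
#' @export
referenceDbCensus <- function(dbPath, format = "npatlas_json") {
  db <- loadReferenceDb(dbPath, format, force = TRUE)
  fc <- formulaCounts(db)
  list(db = db,
       n_records = nRecords(db),
       n_unique_formulae = nrow(fc),
       n_singleton_formulae = attr(fc, "n_singletons"),
       top_formula = fc$formula[1L],
       top_formula_n = fc$n[1L])
}

#' Family and formula-tuple census on a full reference database
#'
#' Precomputes database-wide compound families (Morgan r=2, Dice >= 0.75)
#' and the single/pair/triple formula-tuple statistics. On NPAtlas v2020_06
#' this reproduces 8381 families (1901 with >= 3 members), 4317 eligible
#' single formulae with 36% confined to one family, pair/triple
#' single-family proportions above 95%/97%, and the
#' (C10H10O4, C11H12O4, C11H12O5) triple occurring in 5 families whose
#' formulae carry 33/39/39 molecules.
#'
#' @param db A loaded [CompoundDb-class] (e.g. from [referenceDbCensus()]).
#' @param cutoff Database clustering cutoff (default 0.75).
#' @return Named list: family counts, per-k tuple censuses and their
#'   [distributionSummary()] proportions, and the diagnostic triple's row.
#' @export
referenceFamilyCensus <- function(db, cutoff = 0.75) {
  fams <- databaseFamilies(db, cutoff = cutoff)
  singles <- familyTupleOccurrence(fams, db, k = 1L)
  pairs <- familyTupleOccurrence(fams, db, k = 2L)
  triples <- familyTupleOccurrence(fams, db, k = 3L)
  triple <- triples[triples$f1 == "C10H10O4" & triples$f2 == "C11H12O4" &
                      triples$f3 == "C11H12O5", , drop = FALSE]
  list(n_families = nrow(fams),
       n_families_ge3 = sum(fams$size >= 3L),
       n_eligible_formulae = nrow(singles),
       singles_one_family_pct = 100 * distributionSummary(singles)$proportions[["one"]],
       pairs_one_family_pct = 100 * distributionSummary(pairs)$proportions[["one"]],
       triples_one_family_pct = 100 * distributionSummary(triples)$proportions[["one"]],
       diagnostic_triple = triple)
}

#' Worked-example annotation chain on a real subnetwork
#'
#' Runs the full pipeline on one subnetwork's masses against a loaded
#' reference database and reports each stage of the chain: input masses,
#' distinct candidates, compound families before size filtering, surviving
#' families, and the top family's size and coverage. On the trichostatin
#' subnetwork of the marine-actinobacteria network (5 masses) against
#' NPAtlas v2020_06 this reproduces 17 candidates, 11 families, and one
#' surviving family of 6 members covering 3 masses.
#'
#' @param masses Numeric vector of subnetwork parent masses.
#' @param db A loaded [CompoundDb-class].
#' @param params A [SnapmsParams-class].
#' @return Named list of per-stage counts plus the [AnnotationResult-class].
#' @export
annotationChainCheck <- function(masses, db, params = snapmsParams()) {
  features <- data.frame(mz = masses,
                         node_id = as.character(seq_along(masses)),
                         subnetwork_id = "worked_example",
                         stringsAsFactors = FALSE)
  groups <- binMasses(features, params@ppmWindow)
  hits <- lapply(groups$representative_mz, queryMass, db = db,
                 adducts = params@adducts, ppmWindow = params@ppmWindow)
  candIds <- unique(unlist(lapply(hits, `[[`, "compound_id")))
  rec <- dbRecords(db)
  cand <- rec[match(candIds, rec$compound_id), , drop = FALSE]
  net <- suppressWarnings(
    buildSimilarityNetwork(cand, params@fpMethod, params@fpRadius,
                           params@metric, params@cutoff))
  famsAll <- extractFamilies(net)
  res <- annotateSubnetwork(features, db, params)
  fam <- resultFamilies(res)
  list(n_masses = length(masses),
       n_groups = nrow(groups),
       n_candidates = length(candIds),
       n_families = nrow(famsAll),
       n_surviving_families = nrow(fam),
       top_family_size = if (nrow(fam)) fam$size[1L] else 0L,
       top_family_coverage = if (nrow(fam)) fam$coverage[1L] else 0L,
       result = res)
}

#' Benchmark-selection check against a reference MS network
#'
#' Sweeps the default method panel against a reference molecular network of
#' known structures and reports the selected configuration at the 99.5%
#' true-negative floor, together with the MACCS/Dice qualifying cutoff and
#' its true-positive percentage. On the GNPS NIH Round-1 standards network
#' the selected configuration is Morgan/Dice (cutoff near 0.71) while
#' MACCS/Dice needs a cutoff near 0.94 and keeps only about 58% of true
#' edges.
#'
#' @param compounds Named SMILES vector (names matching MS-network node
#'   ids), data.frame, or [CompoundDb-class].
#' @param msNet Reference network (igraph or [SimilarityNetwork-class]).
#' @param minTnPct True-negative floor (default 99.5).
#' @return Named list: `selected` (one-row data.frame), `maccs` (MACCS/Dice
#'   row at its qualifying cutoff), and the full sweep `rows`.
#' @export
benchmarkSelectionCheck <- function(compounds, msNet, minTnPct = 99.5) {
  rows <- sweepMethods(compounds, msNet)
  sel <- selectClusteringMethod(rows, minTnPct)
  maccs <- rows[rows$method == "maccs" & rows$tn_pct >= minTnPct, ,
                drop = FALSE]
  maccs <- if (nrow(maccs)) maccs[which.min(maccs$cutoff), , drop = FALSE] else maccs
  list(selected = sel, maccs = maccs, rows = rows)
}
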
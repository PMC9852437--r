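# Seeded synthetic fixtures: ground-truthed reference databases built from
# decorated natural-product-like scaffolds, plus subnetwork mass lists whose
# correct annotation is known by construction.

# Scaffold templates with three substitution sites ({R1}-{R3}). Each core
# mimics a common NP structural class; decorating sites with small
# substituents keeps within-family Morgan/Dice similarity high while the
# distinct cores keep cross-family similarity low.
.SCAFFOLD_TEMPLATES <- c(
  flavanone      = "CC(C)=CCc1c(O)cc2OC(c3cc{R1}c(O)c{R2}c3)CC(=O)c2c1O{R3}",
  flavone        = "COc1cc(-c2oc3cc(O)c{R1}c(O)c3c(=O)c2{R2})cc{R3}c1O",
  coumarin       = "CC(C)=CCc1c(O)c{R1}c2oc(=O)c(Cc3cc{R2}cc{R3}c3)cc2c1O",
  naphthoquinone = "CC(O)CC1OC2CC(=O)c3c(O)c{R1}c(O{R2})c(O)c3C2C(=O)C1{R3}",
  indolediketo   = "O=C1NC(Cc2c{R1}[nH]c3cc{R2}cc{R3}c23)C(=O)N2CCCC12",
  carbazole      = "CC1(C)CCc2c(O1)c{R1}c1c(c2{R2})[nH]c2cc{R3}c(CC=C(C)C)cc12",
  xanthone       = "COc1c(O)c{R1}c2oc3cc(O)c(CC=C(C)C{R2})c(O)c3c(=O)c2c1{R3}",
  anthraquinone  = "CC1Cc2cc3cc(O{R1})c4c(O)c5c(c(O)c4c3c(O)c2C(=O)O1)C(=O)C{R2}C(O)C5{R3}",
  stilbene       = "COc1cc(/C=C/c2cc{R1}c(O)c(CC=C(C)C)c2{R2})cc(O)c1O{R3}",
  chalcone       = "CC(C)=CCc1c(O)ccc(C(=O)/C=C/c2cc{R1}c(O)c{R2}c2O{R3})c1O",
  quinolone      = "CCCCCCCc1cc(=O)c2c(O)c{R1}c(OC{R2})c(O)c2n1C{R3}",
  pterocarpan    = "CC(C)=CCc1c(O)c{R1}c2c(c1O)OCC1c3cc{R2}c(O{R3})cc3OC21",
  pyranone       = "CCC(C)C1OC(=O)C(C)C(O)C(C)C(O{R1})C(CC{R2})CC(C)C1O{R3}",
  diketopiperazine = "O=C1NC(Cc2cc{R1}ccc2)C(=O)NC1Cc1cc{R2}cc{R3}c1",
  macrolactone   = "CC1CCC(O)C(C)C(=O)C{R1}CC(C)C(O{R2})CCC(C)CC(CC{R3})OC1=O",
  steroid        = "CC12CCC3c4cc{R1}c(O{R2})c{R3}c4CCC3C1CCC2O",
  prenylphenol   = "CC(C)=CCc1c(O{R1})c(C(C)=O)c(O)c(CC=C(C)C{R2})c1OC{R3}",
  naphthopyrone  = "CC1=CC(=O)c2c(O)c3c(c(O{R1})c2C1{R2})OC(C)CC3=O{R3}",
  cyclopeptide   = "CC(C)CC1NC(=O)C(CCC{R1})NC(=O)C(COC{R2})NC(=O)C(C{R3})NC1=O",
  aminoglycoside = "NC1C(O{R1})C(CO)OC(OC2C(N)CC(N{R2})C(O)C2OC{R3})C1O"
)

# Small substituents inserted as branches; "" leaves the site unsubstituted.
.SUBSTITUENTS <- c("", "(C)", "(O)", "(OC)", "(F)", "(Cl)", "(Br)",
                   "(CC)", "(C(C)=O)", "(OC(C)=O)")

# Structurally diverse singleton decoys (common metabolites and drugs),
# chosen to sit below the clustering cutoff against every scaffold family
# and against each other.
.DECOY_SMILES <- c(
  caffeine      = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  aspirin       = "CC(=O)Oc1ccccc1C(O)=O",
  ibuprofen     = "CC(C)Cc1ccc(C(C)C(O)=O)cc1",
  cholesterol   = "CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C",
  nicotine      = "CN1CCCC1c1cccnc1",
  glucose       = "OCC1OC(O)C(O)C(O)C1O",
  citrate       = "OC(=O)CC(O)(CC(O)=O)C(O)=O",
  menthol       = "CC(C)C1CCC(C)CC1O",
  camphor       = "CC1(C)C2CCC1(C)C(=O)C2",
  geraniol      = "CC(C)=CCCC(C)=CCO",
  limonene      = "CC(=C)C1CCC(C)=CC1",
  vanillin      = "COc1cc(C=O)ccc1O",
  cinnamate     = "OC(=O)/C=C/c1ccccc1",
  indoleacetate = "OC(=O)Cc1c[nH]c2ccccc12",
  adenine       = "Nc1ncnc2[nH]cnc12",
  uracil        = "O=c1cc[nH]c(=O)[nH]1",
  proline       = "OC(=O)C1CCCN1",
  leucine       = "CC(C)CC(N)C(O)=O",
  tyrosine      = "NC(Cc1ccc(O)cc1)C(O)=O",
  arachidate    = "CCCCCCCCCCCCCCCCCCCC(O)=O",
  biotin        = "OC(=O)CCCCC1SCC2NC(=O)NC12",
  riboflavinoid = "Cc1cc2nc3c(=O)[nH]c(=O)nc3n(CC(O)C(O)C(O)CO)c2cc1C",
  pantothenate  = "CC(C)(CO)C(O)C(=O)NCCC(O)=O",
  anthranilate  = "Nc1ccccc1C(O)=O",
  shikimate     = "OC1CC(=CC(O)C1O)C(O)=O",
  mevalonate    = "CC(O)(CCO)CC(O)=O",
  putrescine    = "NCCCCN",
  spermidine    = "NCCCCNCCCN",
  glutathione   = "NC(CCC(=O)NC(CS)C(=O)NCC(O)=O)C(O)=O",
  pyridoxine    = "Cc1ncc(CO)c(CO)c1O",
  thiamineless  = "Cc1ncc(CN)c(N)n1",
  gallate       = "OC(=O)c1cc(O)c(O)c(O)c1",
  quinate       = "OC1CC(O)(CC(O)C1O)C(O)=O",
  taurine       = "NCCS(O)(=O)=O",
  carnitine     = "C[N+](C)(C)CC(O)CC([O-])=O",
  sorbate       = "C/C=C/C=C/C(O)=O",
  furfural      = "O=Cc1ccco1"
)

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.fillTemplate <- function(template, subs) {
  out <- template
  for (i in seq_along(subs)) {
    out <- sub(paste0("{R", i, "}"), subs[i], out, fixed = TRUE)
  }
  out
}

#' Specify a synthetic fixture
#'
#' The defaults define the standard test conditions: 3 seeded scaffold
#' families of 6 members each, 30 structurally unrelated decoys, subnetwork
#' masses emitted mostly as protonated species with 5 ppm uniform mass
#' jitter (half a typical 10 ppm matching window).
#'
#' @param nFamilies Number of seeded scaffold families.
#' @param familySize Members per family (2..24).
#' @param nDecoys Number of unrelated singleton compounds.
#' @param adductMix Named probability vector over the adduct panel used when
#'   emitting subnetwork masses.
#' @param massNoisePpm Half-width of the uniform ppm jitter on emitted m/z.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @return A `fixture_spec` list.
#' @export
fixtureSpec <- function(nFamilies = 3L, familySize = 6L, nDecoys = 30L,
                        adductMix = c("[M+H]+" = 0.6, "[M+Na]+" = 0.2,
                                      "[M-H2O+H]+" = 0.2),
                        massNoisePpm = 5, seed = 1L) {
  stopifnot(nFamilies >= 0L, nFamilies <= length(.SCAFFOLD_TEMPLATES),
            familySize >= 2L, nDecoys >= 0L, massNoisePpm >= 0,
            abs(sum(adductMix) - 1) < 1e-9,
            all(names(adductMix) %in% adductPanel()$name))
  structure(list(nFamilies = as.integer(nFamilies),
                 familySize = as.integer(familySize),
                 nDecoys = as.integer(nDecoys),
                 adductMix = adductMix,
                 massNoisePpm = massNoisePpm,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# All distinct decorated variants of one scaffold template, in random order.
.scaffoldVariants <- function(template) {
  grid <- expand.grid(.SUBSTITUENTS, .SUBSTITUENTS, .SUBSTITUENTS,
                      stringsAsFactors = FALSE)
  smi <- vapply(seq_len(nrow(grid)), function(i) {
    .fillTemplate(template, unlist(grid[i, ], use.names = FALSE))
  }, character(1))
  unique(smi)[sample.int(length(unique(smi)))]
}

# Dice similarity between two fingerprint row-matrices (cross-block).
.crossDice <- function(a, b) {
  inter <- tcrossprod(a * 1L, b * 1L)
  denom <- outer(rowSums(a), rowSums(b), "+")
  ifelse(denom > 0, 2 * inter / denom, 0)
}

#' Generate a ground-truthed reference database fixture
#'
#' Each seeded family is one scaffold decorated with small substituents
#' (methyl, hydroxyl, methoxy, halogen, acetyl, ...). The family structure
#' is verified at generation time under the clustering configuration:
#' members are accepted greedily, in seeded random order, only if every
#' within-family Morgan r=2 / Dice similarity reaches `cutoff` while every
#' cross-family similarity stays below it; decorations violating either
#' constraint are discarded and the next candidate is tried, up to a
#' bounded number of draws. Decoys are structurally diverse singletons.
#' Formulae and masses are computed from the structures.
#'
#' @param spec A [fixtureSpec()].
#' @param cutoff Clustering cutoff the fixture is verified against
#'   (default 0.71).
#' @param maxDraws Candidate decorations examined per family before giving
#'   up.
#' @return List with `db` (a [CompoundDb-class], source `"fixture"`) and
#'   `truth` (per-family member ids, scaffold names and SMILES, plus the
#'   spec).
#' @export
generateReferenceFixture <- function(spec = fixtureSpec(), cutoff = 0.71,
                                     maxDraws = 1000L) {
  stopifnot(inherits(spec, "fixture_spec"))
  .withSeed(spec$seed, {
    scaffolds <- sample(names(.SCAFFOLD_TEMPLATES), spec$nFamilies)
    famSmiles <- list()
    famFp <- list()
    for (fi in seq_len(spec$nFamilies)) {
      variants <- .scaffoldVariants(.SCAFFOLD_TEMPLATES[[scaffolds[fi]]])
      variants <- variants[seq_len(min(length(variants), maxDraws))]
      accepted <- character(0)
      accFp <- NULL
      # candidates are fingerprinted in batches but accepted greedily
      chunks <- split(variants, ceiling(seq_along(variants) / 25))
      for (chunk in chunks) {
        if (length(accepted) == spec$familySize) break
        names(chunk) <- paste0("v", seq_along(chunk))
        fpAll <- computeFingerprints(chunk, "morgan", 2L)
        for (vi in rownames(fpAll)) {
          if (length(accepted) == spec$familySize) break
          fp <- fpAll[vi, , drop = FALSE]
          # clique constraint within the family being built
          if (!is.null(accFp) && min(.crossDice(fp, accFp)) < cutoff) next
          # separation from the families fixed so far
          clash <- FALSE
          for (prev in famFp) {
            if (max(.crossDice(fp, prev)) >= cutoff) { clash <- TRUE; break }
          }
          if (clash) next
          accepted <- c(accepted, chunk[[vi]])
          accFp <- rbind(accFp, fp)
        }
      }
      if (length(accepted) < spec$familySize) {
        stop("could not build a well-separated family of ", spec$familySize,
             " members from scaffold '", scaffolds[fi], "' within ",
             maxDraws, " candidate decorations", call. = FALSE)
      }
      smi <- stats::setNames(accepted,
                             sprintf("F%02dM%02d", fi, seq_along(accepted)))
      famSmiles[[fi]] <- smi
      famFp[[fi]] <- accFp
    }
    nd <- spec$nDecoys
    decoys <- character(0)
    if (nd > 0L) {
      decoys <- rep(sample(.DECOY_SMILES), length.out = nd)
      names(decoys) <- sprintf("D%03d", seq_len(nd))
    }

    allSmiles <- c(unlist(famSmiles), decoys)
    genera <- c("Streptomyces", "Aspergillus", "Penicillium", "Nostoc",
                "Bacillus", "Micromonospora")
    phyla <- c("Actinobacteria", "Ascomycota", "Cyanobacteria", "Firmicutes")
    rec <- data.frame(
      compound_id = names(allSmiles),
      name = names(allSmiles),
      smiles = unname(allSmiles),
      genus = sample(genera, length(allSmiles), replace = TRUE),
      phylum = sample(phyla, length(allSmiles), replace = TRUE),
      stringsAsFactors = FALSE
    )
    db <- compoundDb(rec, taxonomyRanks = c("genus", "phylum"),
                     sourceDb = "fixture")
    truth <- list(
      families = stats::setNames(lapply(famSmiles, names),
                                 sprintf("F%02d", seq_len(spec$nFamilies))),
      scaffolds = stats::setNames(as.list(scaffolds),
                                  sprintf("F%02d", seq_len(spec$nFamilies))),
      smiles = allSmiles,
      spec = spec
    )
    list(db = db, truth = truth)
  })
}

#' Generate a subnetwork mass list for one seeded family
#'
#' Emits the adduct m/z of `nMasses` distinct members of the chosen seeded
#' family, with the adduct drawn per-member from the spec's adduct mix and
#' uniform jitter of up to `massNoisePpm` ppm applied. The expected
#' annotation is known by construction: the seeded family ranks first with
#' coverage `nMasses` whenever the jitter stays inside the matching window
#' and binning does not merge members.
#'
#' @param fixture Output of [generateReferenceFixture()] (or its `truth`).
#' @param familyId Seeded family id (e.g. `"F01"`).
#' @param nMasses Number of member masses to emit (at most the family size).
#' @param db The fixture [CompoundDb-class] (used for member masses);
#'   defaults to `fixture$db`.
#' @return List with `features` (mass-feature data.frame) and `expected`
#'   (family id, emitted member ids, adduct and true m/z per mass, expected
#'   coverage).
#' @export
generateSubnetworkFixture <- function(fixture, familyId, nMasses = 3L,
                                      db = fixture$db) {
  truth <- if (!is.null(fixture$truth)) fixture$truth else fixture
  if (!familyId %in% names(truth$families)) {
    stop("unknown family id '", familyId, "'; available: ",
         paste(names(truth$families), collapse = ", "), call. = FALSE)
  }
  members <- truth$families[[familyId]]
  spec <- truth$spec
  if (nMasses > length(members)) {
    stop("nMasses exceeds the family size (", length(members), ")",
         call. = FALSE)
  }
  seed <- spec$seed + 7919L * match(familyId, names(truth$families)) + nMasses
  .withSeed(seed, {
    chosen <- sort(sample(members, nMasses))
    rec <- dbRecords(db)
    mass <- rec$exact_mass[match(chosen, rec$compound_id)]
    adducts <- sample(names(spec$adductMix), nMasses, replace = TRUE,
                      prob = spec$adductMix)
    theo <- vapply(seq_len(nMasses),
                   function(i) adductMz(mass[i], adducts[i]), numeric(1))
    jitter <- stats::runif(nMasses, -spec$massNoisePpm, spec$massNoisePpm)
    mz <- theo * (1 + jitter * 1e-6)
    features <- data.frame(mz = mz,
                           node_id = sprintf("n%02d", seq_len(nMasses)),
                           subnetwork_id = familyId,
                           stringsAsFactors = FALSE)
    expected <- list(family_id = familyId, members = chosen,
                     adducts = adducts, true_mz = theo,
                     coverage = as.integer(nMasses))
    list(features = features, expected = expected)
  })
}

#' Write a fixture to disk
#'
#' Emits the reference database as `fixture_tsv`, one `masses_<family>.csv`
#' per seeded family, and a `truth.json` describing the ground truth.
#'
#' @param fixture Output of [generateReferenceFixture()].
#' @param dir Output directory (created if needed).
#' @param nMasses Masses per subnetwork file.
#' @return Character vector of written paths, invisibly.
#' @export
writeFixture <- function(fixture, dir, nMasses = 3L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- dbRecords(fixture$db)
  dbPath <- file.path(dir, "fixture_db.tsv")
  utils::write.table(
    rec[, c("compound_id", "name", "smiles", "genus", "phylum")],
    dbPath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- dbPath
  truthOut <- list(spec = unclass(fixture$truth$spec),
                   families = fixture$truth$families,
                   scaffolds = fixture$truth$scaffolds,
                   subnetworks = list())
  for (fid in names(fixture$truth$families)) {
    sn <- generateSubnetworkFixture(fixture, fid, nMasses)
    p <- file.path(dir, paste0("masses_", fid, ".csv"))
    utils::write.table(data.frame(mz = sn$features$mz), p, sep = ",",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    truthOut$subnetworks[[fid]] <- sn$expected
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truthOut, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, tp))
}
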
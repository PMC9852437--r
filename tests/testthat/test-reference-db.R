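test_that("fixture_tsv loads preserve records and skip unparseable rows", {
  db <- tinyDb()
  expect_s4_class(db, "CompoundDb")
  expect_identical(nRecords(db), 3L)
  expect_identical(nSkipped(db), 0L)
  # masses recomputed from formula, consistent within 5 mDa of structure
  rec <- dbRecords(db)
  expect_equal(rec$exact_mass,
               formulaMonoisotopicMass(rec$formula), tolerance = 1e-12)

  rows <- tinyDbRows()
  rows$smiles[2] <- "not_a_smiles(((("
  db2 <- suppressWarnings(loadReferenceDb(writeFixtureTsv(rows),
                                          "fixture_tsv"))
  expect_identical(nRecords(db2), 2L)
  expect_identical(nSkipped(db2), 1L)
})

test_that("majority-unparseable dumps abort unless forced", {
  rows <- tinyDbRows()
  rows$smiles[1:2] <- "xxx((("
  path <- writeFixtureTsv(rows)
  expect_error(loadReferenceDb(path, "fixture_tsv"), "force")
  db <- suppressWarnings(loadReferenceDb(path, "fixture_tsv", force = TRUE))
  expect_identical(nRecords(db), 1L)
})

test_that("npatlas tabular and json dialects map their field names", {
  tsv <- data.frame(
    NPAID = c("NPA000001", "NPA000002"),
    Compound_Names = c("thing one", "thing two"),
    Compound_Molecular_Formula = c("C9H8O4", "C8H10N4O2"),
    Compound_SMILES = c("CC(=O)Oc1ccccc1C(O)=O",
                        "Cn1cnc2c1c(=O)n(C)c(=O)n2C"),
    Genus = c("Streptomyces", "Nostoc"),
    Origin_Type = c("Bacterium", "Bacterium"),
    check.names = FALSE, stringsAsFactors = FALSE)
  db <- loadReferenceDb(writeFixtureTsv(tsv), "npatlas_tsv")
  expect_identical(nRecords(db), 2L)
  expect_identical(dbSource(db), "npatlas")
  expect_true("genus" %in% taxonomyRanks(db))
  expect_equal(dbRecords(db)$formula, c("C9H8O4", "C8H10N4O2"))

  js <- list(
    list(npaid = "NPA000003", original_name = "jsonthing",
         smiles = "OC(=O)Cc1c[nH]c2ccccc12", mol_formula = "C10H9NO2",
         origin_organism = list(
           genus = "Aspergillus",
           taxon = list(ancestors = list(
             list(rank = "Phylum", name = "Ascomycota"))))))
  jp <- tempfile(fileext = ".json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE)
  dbj <- loadReferenceDb(jp, "npatlas_json")
  expect_identical(nRecords(dbj), 1L)
  expect_identical(dbRecords(dbj)$genus, "Aspergillus")
  expect_identical(dbRecords(dbj)$phylum, "Ascomycota")
})

test_that("taxonomy filtering selects case-insensitively and rebuilds indices", {
  db <- tinyDb()
  f <- filterByTaxonomy(db, "genus", "streptomyces")
  expect_identical(nRecords(f), 2L)
  expect_true(all(dbRecords(f)$genus == "Streptomyces"))
  # idempotence
  f2 <- filterByTaxonomy(f, "genus", "streptomyces")
  expect_identical(dbRecords(f2), dbRecords(f))
  # empty result warns but stays valid
  expect_warning(e <- filterByTaxonomy(db, "genus", "Nocardia"),
                 "no records")
  expect_identical(nRecords(e), 0L)
  # union property
  u <- filterByTaxonomy(db, "genus", c("Streptomyces", "Aspergillus"))
  a <- filterByTaxonomy(db, "genus", "Streptomyces")
  b <- filterByTaxonomy(db, "genus", "Aspergillus")
  expect_setequal(dbRecords(u)$compound_id,
                  c(dbRecords(a)$compound_id, dbRecords(b)$compound_id))
  # unknown rank names the valid ones
  expect_error(filterByTaxonomy(db, "kingdom", "x"), "genus")
})

test_that("coconut databases refuse taxonomy filtering", {
  tab <- data.frame(coconut_id = "CNP1", name = "x",
                    SMILES = "CC(=O)Oc1ccccc1C(O)=O",
                    molecular_formula = "C9H8O4",
                    stringsAsFactors = FALSE)
  db <- loadReferenceDb(writeFixtureTsv(tab), "coconut")
  expect_identical(dbSource(db), "coconut")
  expect_error(filterByTaxonomy(db, "genus", "x"), "COCONUT")
})

test_that("mass queries hit exact adduct masses and respect the ppm window", {
  rows <- data.frame(compound_id = "m1", name = "m1", smiles = "CCO",
                     genus = "g", phylum = "p", stringsAsFactors = FALSE)
  db <- loadReferenceDb(writeFixtureTsv(rows), "fixture_tsv")
  m <- dbRecords(db)$exact_mass
  hit <- queryMass(db, m + 1.007276, "[M+H]+", ppmWindow = 10)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$ppm_error, 0, tolerance = 1e-2)
  # ~300 ppm away finds nothing
  expect_identical(nrow(queryMass(db, m + 1.1, "[M+H]+", 10)), 0L)
  expect_error(queryMass(db, -5, "[M+H]+", 10), "positive")
  expect_error(queryMass(db, 100, character(0), 10), "empty")
})

test_that("two near-isobaric records both fall inside a 10 ppm window", {
  # neutral masses 3.0 mDa apart at ~300 Da: 10 ppm spans both
  rows <- data.frame(
    compound_id = c("a", "b"), name = c("a", "b"),
    smiles = c("CCO", "CCN"), genus = "g", phylum = "p",
    stringsAsFactors = FALSE)
  db <- loadReferenceDb(writeFixtureTsv(rows), "fixture_tsv")
  # override with explicit masses via a records-level constructor
  rec <- dbRecords(db)
  rec$exact_mass <- c(300.0000, 300.0030)
  db2 <- methods::new("CompoundDb", records = rec,
                      taxonomyRanks = c("genus", "phylum"),
                      sourceDb = "fixture",
                      massOrder = order(rec$exact_mass), skipped = 0L)
  hits <- queryMass(db2, 301.007276, "[M+H]+", 10)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$compound_id, c("a", "b"))
})

test_that("mass queries agree with a brute-force scan and are window-monotone", {
  fix <- sharedFixture()
  db <- fix$db
  rec <- dbRecords(db)
  set.seed(7)
  probes <- c(
    # true adduct masses of random records under random adducts
    vapply(sample(nrow(rec), 10), function(i) {
      adductMz(rec$exact_mass[i], sample(adductPanel()$name, 1))
    }, numeric(1)),
    # jittered and random masses
    runif(10, 150, 700))
  for (mz in probes) {
    got <- queryMass(db, mz, adductPanel(), 10)
    expect_identical(sort(paste(got$compound_id, got$adduct)),
                     bruteQueryMass(db, mz, adductPanel(), 10))
    # enlarging the window never removes a match
    wide <- queryMass(db, mz, adductPanel(), 50)
    expect_true(all(paste(got$compound_id, got$adduct) %in%
                      paste(wide$compound_id, wide$adduct)))
    # |ppm_error| bounded by the window, results sorted by |ppm_error|
    expect_true(all(abs(got$ppm_error) <= 10 + 1e-9))
    expect_false(is.unsorted(abs(got$ppm_error)))
  }
})

test_that("a compound is always found at its exact adduct m/z", {
  fix <- sharedFixture()
  rec <- dbRecords(fix$db)
  set.seed(11)
  for (i in sample(nrow(rec), 8)) {
    for (ad in adductPanel()$name) {
      got <- queryMass(fix$db, adductMz(rec$exact_mass[i], ad),
                       adductPanel(), 0.5)
      expect_true(rec$compound_id[i] %in% got$compound_id)
    }
  }
})
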
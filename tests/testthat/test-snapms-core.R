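test_that("mass-list CSV parsing skips headers and malformed rows", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("400.1", "500.2"), p)
  expect_identical(nrow(parseMassListCsv(p)), 2L)

  writeLines(c("mz", "400.1", "500.2", "600.3"), p)
  f <- parseMassListCsv(p)
  expect_identical(nrow(f), 3L)
  expect_equal(f$mz, c(400.1, 500.2, 600.3))

  writeLines(c("400.1", "oops", "500.2", "600.3"), p)
  expect_warning(f2 <- parseMassListCsv(p), "skipped")
  expect_identical(nrow(f2), 3L)

  writeLines(c("mz", "oops"), p)
  expect_error(suppressWarnings(parseMassListCsv(p)), "no numeric")
})

test_that("GraphML subnetwork extraction filters components by size", {
  # components of size 2, 3 and 7
  g <- igraph::make_graph(~ a - b,
                          c - d, d - e,
                          f - g, g - h, h - i, i - j, j - k, k - l, f - l)
  igraph::V(g)$`precursor mass` <- 100 + seq_len(igraph::vcount(g))
  p <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, p, format = "graphml")
  subs <- extractSubnetworksFromGraphml(p, snapmsParams())
  expect_length(subs, 2L)
  expect_setequal(vapply(subs, nrow, integer(1)), c(3L, 7L))

  # a single component passes through whole
  g2 <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  igraph::V(g2)$parent.mass <- 200 + 1:5
  igraph::write_graph(g2, p, format = "graphml")
  subs2 <- extractSubnetworksFromGraphml(p, snapmsParams())
  expect_length(subs2, 1L)
  expect_identical(nrow(subs2[[1]]), 5L)

  # oversized component dropped with warning
  expect_warning(
    subs3 <- extractSubnetworksFromGraphml(
      p, snapmsParams(maxGnpsClusterSize = 4L)),
    "exceeds")
  expect_length(subs3, 0L)

  # missing mass attribute is fatal and lists what was found
  g3 <- igraph::make_graph(~ a - b, b - c)
  igraph::V(g3)$intensity <- 1:3
  igraph::write_graph(g3, p, format = "graphml")
  expect_error(extractSubnetworksFromGraphml(p, snapmsParams()),
               "intensity")
})

test_that("mass binning groups within the ppm window from the group minimum", {
  f <- data.frame(mz = c(500.000, 500.002, 600.0))
  g <- binMasses(f, 10)   # 4 ppm apart -> same group
  expect_identical(nrow(g), 2L)
  expect_equal(g$representative_mz, c(500.000, 600.0))
  expect_identical(g$n_members, c(2L, 1L))

  g2 <- binMasses(data.frame(mz = c(500.000, 500.010)), 10)  # 20 ppm apart
  expect_identical(nrow(g2), 2L)

  # partition property on random inputs; representative is the group minimum
  set.seed(5)
  for (i in 1:20) {
    mz <- sort(runif(sample(2:40, 1), 100, 1200)) *
      (1 + rnorm(1, 0, 1e-6))
    g3 <- binMasses(data.frame(mz = sample(mz)), 10)
    expect_identical(sum(g3$n_members), length(mz))
    expect_identical(sort(unlist(g3$member_mz)), sort(mz))
    expect_equal(g3$representative_mz,
                 vapply(g3$member_mz, min, numeric(1)))
    expect_lte(nrow(g3), length(mz))
    # every member within the window of its representative
    for (j in seq_len(nrow(g3))) {
      expect_true(all((g3$member_mz[[j]] - g3$representative_mz[j]) /
                        g3$representative_mz[j] * 1e6 <= 10 + 1e-9))
    }
  }
})

test_that("family ranking follows coverage, size, similarity, then id", {
  fam <- data.frame(
    family_id = c("CF1", "CF2", "CF3", "CF4"),
    size = c(3L, 8L, 3L, 5L),
    coverage = c(3L, 2L, 2L, 1L),
    mean_similarity = c(0.8, 0.9, 0.9, 0.99),
    stringsAsFactors = FALSE)
  fam$members <- list(c("x1", "x2", "x3"), paste0("y", 1:8),
                      c("z1", "z2", "z3"), paste0("w", 1:5))
  r <- rankFamilies(fam)
  expect_identical(r$family_id, c("CF1", "CF2", "CF3", "CF4"))
  expect_identical(r$rank, 1:4)
  # size breaks the coverage tie
  expect_gt(r$size[r$family_id == "CF2"], r$size[r$family_id == "CF3"])
  # single family gets rank 1
  expect_identical(rankFamilies(fam[2, , drop = FALSE])$rank, 1L)
})

test_that("results-graph size limits flag oversized annotations", {
  fam <- data.frame(family_id = "CF0001", size = 3L, coverage = 1L,
                    mean_similarity = 1, rank = 1L,
                    stringsAsFactors = FALSE)
  fam$members <- list(c("a", "b", "c"))
  mk <- function(nNodes, nEdges) {
    nodes <- sprintf("n%05d", seq_len(nNodes))
    edges <- if (nEdges > 0) {
      pairs <- t(combn(nodes[seq_len(min(nNodes, 200))], 2))
      data.frame(from = pairs[seq_len(nEdges), 1],
                 to = pairs[seq_len(nEdges), 2],
                 score = 1, stringsAsFactors = FALSE)
    } else {
      data.frame(from = character(0), to = character(0),
                 score = numeric(0))
    }
    methods::new("AnnotationResult", subnetworkId = "S1",
                 compoundGroups = data.frame(group_id = "G001"),
                 candidateCount = as.integer(nNodes), matches = data.frame(),
                 families = fam,
                 resultsGraph = mkNet(nodes, edges, cutoff = 0.5),
                 status = "annotated", params = snapmsParams())
  }
  expect_identical(annotationStatus(filterResultGraph(mk(2001, 0))),
                   "graph_too_large")
  expect_identical(nrow(resultFamilies(filterResultGraph(mk(2001, 0)))), 0L)
  expect_identical(annotationStatus(filterResultGraph(mk(2000, 10000))),
                   "annotated")
  expect_identical(annotationStatus(filterResultGraph(mk(2000, 10001))),
                   "graph_too_large")
  small <- mk(10, 9)
  expect_identical(annotationStatus(filterResultGraph(small)), "annotated")
  expect_identical(resultFamilies(filterResultGraph(small)), fam)
})

test_that("a seeded subnetwork annotates to its true family", {
  fix <- sharedFixture()
  sn <- generateSubnetworkFixture(fix, "F01", 3)
  res <- annotateSubnetwork(sn$features, fix$db)
  expect_identical(annotationStatus(res), "annotated")
  fam <- resultFamilies(res)
  expect_true(all(sn$expected$members %in% fam$members[[1]]))
  expect_identical(fam$coverage[1], 3L)
  expect_identical(fam$rank[1], 1L)
  # coverage never exceeds the number of compound groups; rank 1 is maximal
  expect_true(all(fam$coverage <= nrow(compoundGroups(res))))
  expect_true(all(fam$coverage <= fam$coverage[1]))
  # matches stay inside the ppm window
  expect_true(all(abs(candidateMatches(res)$ppm_error) <= 10 + 1e-9))
})

test_that("subnetworks matching nothing report no_candidates", {
  db <- tinyDb()
  res <- annotateSubnetwork(data.frame(mz = c(1500.5, 1600.7)), db)
  expect_identical(annotationStatus(res), "no_candidates")
  expect_identical(nrow(resultFamilies(res)), 0L)
  expect_identical(res@candidateCount, 0L)
})

test_that("irrelevant decoy records never change the ranking", {
  fix <- sharedFixture()
  sn <- generateSubnetworkFixture(fix, "F02", 3)
  res <- annotateSubnetwork(sn$features, fix$db)

  # graft 60 extra decoys whose masses match no subnetwork mass
  rec <- dbRecords(fix$db)
  extra <- rec[grepl("^D", rec$compound_id), ][rep(1:10, 6), ]
  extra$compound_id <- sprintf("X%03d", seq_len(nrow(extra)))
  extra$name <- extra$compound_id
  extra$exact_mass <- extra$exact_mass + 250  # far from every query window
  all <- rbind(rec, extra)
  db2 <- methods::new("CompoundDb", records = all,
                      taxonomyRanks = taxonomyRanks(fix$db),
                      sourceDb = "fixture",
                      massOrder = order(all$exact_mass), skipped = 0L)
  res2 <- annotateSubnetwork(sn$features, db2)
  expect_identical(resultFamilies(res2)$members,
                   resultFamilies(res)$members)
  expect_identical(resultFamilies(res2)$coverage,
                   resultFamilies(res)$coverage)
})

test_that("annotation output writes GraphML plus a deterministic summary", {
  fix <- sharedFixture()
  sn <- generateSubnetworkFixture(fix, "F01", 3)
  res <- annotateSubnetwork(sn$features, fix$db)
  resEmpty <- annotateSubnetwork(data.frame(mz = 1900.1,
                                            subnetwork_id = "SX"),
                                 fix$db)
  d1 <- file.path(tempdir(), "out1"); d2 <- file.path(tempdir(), "out2")
  p1 <- writeAnnotationGraphml(list(res, resEmpty), d1)
  p2 <- writeAnnotationGraphml(list(res, resEmpty), d2)
  # one graphml for the annotated result + the summary
  expect_length(p1, 2L)
  sum1 <- read.delim(file.path(d1, "snapms_summary.tsv"))
  expect_identical(nrow(sum1), 2L)
  expect_setequal(sum1$status, c("annotated", "no_candidates"))
  # byte-identical summaries across runs
  expect_identical(readLines(file.path(d1, "snapms_summary.tsv")),
                   readLines(file.path(d2, "snapms_summary.tsv")))
  # written graph re-parses to an isomorphic graph
  g <- igraph::read_graph(p1[1], format = "graphml")
  expect_equal(igraph::vcount(g),
               length(networkNodes(resultsGraph(res))))
  expect_equal(igraph::ecount(g),
               nrow(networkEdges(resultsGraph(res))))
  expect_true(all(c("name", "formula", "family_rank", "matched_adducts") %in%
                    igraph::vertex_attr_names(g)))
})
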
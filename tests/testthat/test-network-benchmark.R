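test_that("edge confusion matches exhaustive pair enumeration", {
  nodes <- c("a", "b", "c", "d")
  ms <- mkNet(nodes, mkEdges(c("a", "c"), c("b", "d"), 0.9))
  st <- mkNet(nodes, mkEdges(c("a", "a"), c("b", "c"), 0.9))
  got <- edgeConfusion(st, ms)
  expect_equal(got[["tp_pct"]], 50)
  expect_equal(got[["tn_pct"]], 75)  # non-edges ac,ad,bc,bd; excluded ad,bc,bd
  expect_equal(got, bruteConfusion(nodes,
                                   list(c("a", "b"), c("c", "d")),
                                   list(c("a", "b"), c("a", "c"))))
  # identity and edgeless extremes
  expect_equal(unname(edgeConfusion(ms, ms)), c(100, 100))
  expect_equal(unname(edgeConfusion(mkNet(nodes), ms)), c(0, 100))
  # random fixture networks against the oracle
  set.seed(13)
  vs <- sprintf("v%02d", 1:9)
  for (i in 1:10) {
    allPairs <- t(combn(vs, 2))
    pick <- function(p) {
      sel <- allPairs[runif(nrow(allPairs)) < p, , drop = FALSE]
      mkNet(vs, mkEdges(sel[, 1], sel[, 2], 0.9))
    }
    ms2 <- pick(0.3)
    if (nrow(networkEdges(ms2)) == 0) next
    st2 <- pick(0.4)
    el <- function(n) {
      ed <- networkEdges(n)
      lapply(seq_len(nrow(ed)), function(r) c(ed$from[r], ed$to[r]))
    }
    expect_equal(edgeConfusion(st2, ms2),
                 bruteConfusion(vs, el(ms2), el(st2)))
  }
})

test_that("edge confusion rejects mismatched node sets and empty references", {
  ms <- mkNet(c("a", "b"), mkEdges("a", "b", 1))
  expect_error(edgeConfusion(mkNet(c("a", "x")), ms), "x")
  expect_error(edgeConfusion(mkNet(c("a", "b")), mkNet(c("a", "b"))),
               "no edges")
})

test_that("method sweeps emit one row per cutoff with monotone rates", {
  smi <- testSmilesPanel()[1:10]
  # reference network: a couple of plausible structure pairs
  ms <- mkNet(names(smi),
              mkEdges(c("t01", "t03", "t06"), c("t02", "t04", "t07"), 1))
  cuts <- seq(0.05, 1, by = 0.05)
  rows <- sweepMethods(smi, ms,
                       methods = data.frame(method = "morgan", radius = 2L,
                                            metric = "dice"),
                       cutoffs = cuts)
  expect_identical(nrow(rows), length(cuts))
  expect_false(is.unsorted(-rows$tp_pct))   # tp nonincreasing in cutoff
  expect_false(is.unsorted(rows$tn_pct))    # tn nondecreasing
  expect_true(all(rows$tp_pct >= 0 & rows$tp_pct <= 100))
  expect_true(all(rows$tn_pct >= 0 & rows$tn_pct <= 100))
  # each row equals a directly thresholded network's confusion
  for (i in sample(seq_len(nrow(rows)), 4)) {
    net <- buildSimilarityNetwork(smi, "morgan", 2, "dice",
                                  rows$cutoff[i])
    expect_equal(unname(edgeConfusion(net, ms)),
                 unname(unlist(rows[i, c("tp_pct", "tn_pct")])))
  }
  # all-distinct structures at cutoff 1: no false edges survive
  expect_equal(rows$tn_pct[rows$cutoff == 1], 100)
})

test_that("nodes on only one side are dropped pairwise", {
  smi <- c(testSmilesPanel()[1:6], extra = "CCCCO")
  ms <- mkNet(c(names(smi)[1:6], "ghost"),
              mkEdges("t01", "t02", 1))
  expect_message(
    rows <- sweepMethods(smi, ms,
                         methods = data.frame(method = "morgan",
                                              radius = 2L, metric = "dice"),
                         cutoffs = c(0.5)),
    "dropped")
  expect_identical(nrow(rows), 1L)
})

test_that("method selection maximises true edges at the ceiling", {
  rows <- rbind(
    data.frame(method = "morgan", radius = 2L, metric = "dice",
               cutoff = c(0.5, 0.7, 0.9),
               tp_pct = c(95, 81, 40), tn_pct = c(98, 99.6, 99.9)),
    data.frame(method = "maccs", radius = 2L, metric = "dice",
               cutoff = c(0.5, 0.94, 0.99),
               tp_pct = c(90, 58, 10), tn_pct = c(97, 99.5, 100)))
  sel <- selectClusteringMethod(rows, 99.5)
  expect_identical(sel$method, "morgan")
  expect_equal(sel$cutoff, 0.7)
  expect_equal(sel$tp_pct, 81)
  # single qualifying method wins by default
  one <- rows[rows$method == "maccs", ]
  expect_identical(selectClusteringMethod(one, 99.5)$cutoff, 0.94)
  # degenerate ceiling compares the lowest cutoffs directly
  sel0 <- selectClusteringMethod(rows, 0)
  expect_identical(sel0$method, "morgan")
  expect_equal(sel0$cutoff, 0.5)
  # tie on tp breaks to the lower cutoff
  tie <- rbind(
    data.frame(method = "a", radius = 2L, metric = "dice", cutoff = 0.8,
               tp_pct = 70, tn_pct = 99.6),
    data.frame(method = "b", radius = 2L, metric = "dice", cutoff = 0.6,
               tp_pct = 70, tn_pct = 99.7))
  expect_identical(selectClusteringMethod(tie, 99.5)$method, "b")
  # nothing qualifies -> explicit empty selection
  expect_warning(none <- selectClusteringMethod(
    data.frame(method = "a", radius = 2L, metric = "dice", cutoff = 0.5,
               tp_pct = 50, tn_pct = 90), 99.5), "no configuration")
  expect_identical(nrow(none), 0L)
})

test_that("a seeded fixture selects a morgan configuration over MACCS", {
  fix <- sharedFixture()
  truth <- fix$truth
  members <- unlist(truth$families, use.names = FALSE)
  smi <- truth$smiles[members]
  # reference network: the true family cliques
  edges <- do.call(rbind, lapply(truth$families, function(m) {
    p <- t(combn(sort(m), 2))
    data.frame(from = p[, 1], to = p[, 2], score = 1,
               stringsAsFactors = FALSE)
  }))
  ms <- mkNet(members, edges, cutoff = 0.5)
  rows <- sweepMethods(smi, ms,
                       methods = data.frame(
                         method = c("morgan", "maccs"),
                         radius = 2L, metric = "dice"),
                       cutoffs = seq(0.05, 1, by = 0.05))
  sel <- selectClusteringMethod(rows, 99.5)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$method, "morgan")
})
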
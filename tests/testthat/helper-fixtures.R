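# Shared test fixtures and independent brute-force oracles.

# A small, chemically varied SMILES panel (phenolics, alkaloid-like,
# aliphatic) used by the similarity tests.
testSmilesPanel <- function() {
  c(t01 = "CC(=O)Oc1ccccc1C(O)=O",
    t02 = "OC(=O)c1ccccc1O",
    t03 = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    t04 = "Nc1ncnc2[nH]cnc12",
    t05 = "CC(C)Cc1ccc(C(C)C(O)=O)cc1",
    t06 = "COc1cc(C=O)ccc1O",
    t07 = "O=Cc1ccc(O)c(OC)c1",
    t08 = "OC(=O)/C=C/c1ccccc1",
    t09 = "OC(=O)/C=C/c1ccc(O)cc1",
    t10 = "CC(C)=CCCC(C)=CCO",
    t11 = "CC(C)=CCCC(C)=CC=O",
    t12 = "CCCCCCCCCC(O)=O",
    t13 = "CCCCCCCCCCCC(O)=O",
    t14 = "OCC1OC(O)C(O)C(O)C1O",
    t15 = "OCC1OC(OC)C(O)C(O)C1O",
    t16 = "c1ccc2c(c1)[nH]c1ccccc12",
    t17 = "OC(=O)Cc1c[nH]c2ccccc12",
    t18 = "CC1(C)C2CCC1(C)C(=O)C2",
    t19 = "CC(C)C1CCC(C)CC1O",
    t20 = "O=c1cc[nH]c(=O)[nH]1")
}

# Write a fixture_tsv reference database to a temp file.
writeFixtureTsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

tinyDbRows <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c3"),
    name = c("alpha", "beta", "gamma"),
    smiles = c("CC(=O)Oc1ccccc1C(O)=O",
               "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
               "OC(=O)Cc1c[nH]c2ccccc12"),
    genus = c("Streptomyces", "Streptomyces", "Aspergillus"),
    phylum = c("Actinobacteria", "Actinobacteria", "Ascomycota"),
    stringsAsFactors = FALSE
  )
}

tinyDb <- function() {
  loadReferenceDb(writeFixtureTsv(tinyDbRows()), "fixture_tsv")
}

# Construct a SimilarityNetwork directly (no chemistry) for graph-level
# tests.
mkNet <- function(nodes, edges = NULL, cutoff = 0.5, method = "morgan",
                  metric = "dice") {
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  }
  methods::new("SimilarityNetwork", nodes = nodes, edges = edges,
               method = method, radius = 2, metric = metric,
               cutoff = cutoff)
}

mkEdges <- function(from, to, score = 1) {
  data.frame(from = from, to = to, score = rep_len(score, length(from)),
             stringsAsFactors = FALSE)
}

# Oracle: exhaustive scan of records x adducts for a mass query.
bruteQueryMass <- function(db, mz, adducts = adductPanel(),
                           ppmWindow = 10) {
  rec <- dbRecords(db)
  hits <- list()
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(adducts))) {
      theo <- rec$exact_mass[i] + adducts$mass_shift[j]
      err <- (mz - theo) / theo * 1e6
      if (abs(err) <= ppmWindow) {
        hits[[length(hits) + 1L]] <- paste(rec$compound_id[i],
                                           adducts$name[j])
      }
    }
  }
  out <- unlist(hits)
  if (is.null(out)) character(0) else sort(out)
}

# Oracle: all-pairs edge list from per-pair pairwiseSimilarity calls.
bruteEdges <- function(smiles, method = "morgan", radius = 2,
                       metric = "dice", cutoff = 0.71) {
  ids <- names(smiles)
  fps <- lapply(smiles, computeFingerprint, method = method,
                radius = radius)
  out <- character(0)
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      s <- pairwiseSimilarity(fps[[a]], fps[[b]], metric)
      if (s >= cutoff) {
        out <- c(out, paste(sort(c(ids[a], ids[b])), collapse = "|"))
      }
    }
  }
  sort(out)
}

netEdgeKeys <- function(net) {
  ed <- networkEdges(net)
  if (!nrow(ed)) return(character(0))
  sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "|"))
}

# Oracle: exhaustive pair enumeration for edge confusion.
bruteConfusion <- function(nodes, msEdges, structEdges) {
  key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  msk <- vapply(msEdges, function(e) key(e[1], e[2]), character(1))
  stk <- vapply(structEdges, function(e) key(e[1], e[2]), character(1))
  tp <- 0; tn <- 0; nMs <- 0; nNeg <- 0
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a >= b) next
      k <- key(nodes[a], nodes[b])
      inMs <- k %in% msk
      inSt <- k %in% stk
      if (inMs) {
        nMs <- nMs + 1
        if (inSt) tp <- tp + 1
      } else {
        nNeg <- nNeg + 1
        if (!inSt) tn <- tn + 1
      }
    }
  }
  c(tp_pct = 100 * tp / nMs, tn_pct = 100 * tn / nNeg)
}

# Oracle: exhaustive tuple census over explicit family formula sets.
bruteTuples <- function(familyFormulaSets, k) {
  counts <- list()
  for (fs in familyFormulaSets) {
    fs <- sort(unique(fs))
    if (length(fs) < k) next
    combos <- utils::combn(fs, k, simplify = FALSE)
    for (cb in combos) {
      key <- paste(cb, collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  unlist(counts[order(names(counts))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared synthetic fixture per test session (generation is the
# expensive step).
.sharedEnv <- new.env()
sharedFixture <- function() {
  if (is.null(.sharedEnv$fix)) {
    .sharedEnv$fix <- generateReferenceFixture(fixtureSpec(seed = 101L))
  }
  .sharedEnv$fix
}
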
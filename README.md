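# snapfam

Compound-family annotation of MS² molecular-networking subnetworks from
MS¹ masses alone.

## The problem

Untargeted LC-MS/MS metabolomics of microbial extracts is routinely
organised by molecular networking: tandem spectra are clustered into a
graph whose connected components (*subnetworks*) contain structurally
related analytes. Putting a name — or at least a compound family — on a
subnetwork normally requires reference MS² spectra, which exist for only a
few percent of known natural products. `snapfam` targets the natural-products
and metabolomics community (dereplication, prioritisation of isolation
targets) and annotates subnetworks using only their **parent masses** and a
structure reference database (Natural Products Atlas, COCONUT, or any
tabular SMILES collection).

## The idea

A single molecular formula is weakly diagnostic: in a large natural-product
database many formulae recur across dozens of unrelated structures. But the
*set* of formulae present in one subnetwork is highly diagnostic for a
single compound family — pairs and triples of co-occurring formulae are
confined to one structure-similarity family in the overwhelming majority of
cases. The pipeline exploits this:

1. **Bin** the subnetwork masses into compound groups within a ppm window
   (representative = group minimum).
2. **Retrieve** candidate structures for each representative mass *m*:
   record with neutral monoisotopic mass *M* matches under adduct *a* iff
   |*m* − (*M* + δ<sub>a</sub>)| / (*M* + δ<sub>a</sub>) × 10⁶ ≤ ppm, with
   the +1 panel [M+H]⁺ (δ = +1.007276), [M+Na]⁺ (+22.989218),
   [M−H₂O+H]⁺ (−17.003289).
3. **Cluster** the pooled candidates into compound families: Morgan
   (ECFP, radius 2, 2048 bits) fingerprints, Sørensen–Dice score
   2|A∩B|/(|A|+|B|), edge iff score ≥ 0.71, families = connected
   components.
4. **Rank** families by *coverage* — the number of compound groups their
   members explain — after dropping families with < 3 members. The top
   family is the annotation.

Two supporting analyses are included: the formula-tuple diagnosticity
census over database-wide families (Dice ≥ 0.75), and a benchmark that
selects the fingerprint/metric/cutoff against a reference MS² network by
maximising true edges at a ≤ 0.5% false-edge ceiling. A seeded
synthetic-fixture generator produces ground-truthed databases and
subnetworks so the whole pipeline is testable offline. See
`vignettes/snapfam-methods.Rmd` for the full model and design rationale.

## Worked example

```r
library(snapfam)

# a ground-truthed fixture: 3 seeded scaffold families x 6 members + 30 decoys
fix <- generateReferenceFixture(fixtureSpec(seed = 11))
writeFixture(fix, "demo")

db <- loadReferenceDb("demo/fixture_db.tsv", "fixture_tsv")
db
#> CompoundDb (fixture) with 48 records
#>   taxonomy ranks: genus, phylum
#>   mass range: 88.1000 - 461.9597 Da

features <- parseMassListCsv("demo/masses_F01.csv")   # 3 subnetwork masses
res <- annotateSubnetwork(features, db, snapmsParams())
res
#> AnnotationResult for subnetwork 'S1': annotated
#>   compound groups: 3 | candidates: 3 | families kept: 1
#>   rank-1 family: CF0001 (3 members, coverage 3)

resultFamilies(res)[, c("family_id", "rank", "size", "coverage")]
#>   family_id rank size coverage
#> 1    CF0001    1    3        3

candidateMatches(res)[, c("group_id", "representative_mz", "compound_id",
                          "adduct", "ppm_error")]
#>   group_id representative_mz compound_id  adduct ppm_error
#> 1     G001          395.0743      F01M03 [M+Na]+  1.295868
#> 2     G002          411.0049      F01M05  [M+H]+  4.031927
#> 3     G003          415.0203      F01M02 [M+Na]+  2.943758
```

The three jittered masses (here sodiated and protonated species, ppm errors
1.3–4.0 within the 10 ppm window) retrieve their true compounds; the
candidates cluster into one family that covers all three compound groups
and ranks first — exactly the planted ground truth (`fix$truth$families$F01`).
`writeAnnotationGraphml(list(res), "out")` exports the annotated results
graph plus a summary TSV; `inst/scripts/snapfam` wraps the same functions
as a command-line tool (`snapfam annotate --input net.graphml --db ...`).

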
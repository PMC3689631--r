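# Spectral-count summaries: abundance index, ranking, keratin fraction.

uninvPath <- system.file("extdata", "tapestrip_uninvolved_counts.tsv",
                         package = "epiTurnover")
psorPath <- system.file("extdata", "tapestrip_psoriatic_counts.tsv",
                        package = "epiTurnover")

test_that("the abundance index reproduces published count/MW values", {
  expect_equal(abundanceIndex(91, 58827)$rounded, 1.55)   # Keratin 10
  expect_equal(abundanceIndex(95, 66039)$rounded, 1.44)   # Keratin 1
  expect_equal(abundanceIndex(191, 60045)$rounded, 3.18)  # Keratin 6A
  expect_equal(abundanceIndex(92, 51622)$rounded, 1.78)   # Keratin 14
  expect_equal(abundanceIndex(1, 1000)$rounded, 1.00)
  expect_error(abundanceIndex(5, 0), "weight")
})

test_that("the abundance index is homogeneous in the count", {
  set.seed(5)
  counts <- sample(1:200, 10); mws <- runif(10, 1e4, 1e5)
  expect_equal(abundanceIndex(2 * counts, mws)$raw,
               2 * abundanceIndex(counts, mws)$raw)
})

test_that("ranking orders the uninvolved table as published", {
  tab <- readSpectralCounts(uninvPath, "uninvolved")
  ranked <- rankByAbundance(tab)
  r <- scRecords(ranked)
  expect_equal(r$proteinName[1], "Keratin 10")
  expect_equal(r$proteinName[2], "Keratin 1")
  expect_true(all(diff(r$abundanceIndex) <= 0))
  # a permutation: nothing gained or lost
  expect_setequal(r$proteinName, scRecords(tab)$proteinName)
  expect_equal(sum(r$totalPeptideCount),
               sum(scRecords(tab)$totalPeptideCount))
})

test_that("ranking handles singletons and breaks ties predictably", {
  single <- spectralCountTable("x", data.frame(
    proteinName = "Keratin 14", uniquePeptides = 5,
    totalPeptideCount = 7, molWt = 51622))
  expect_equal(scRecords(rankByAbundance(single))$proteinName,
               "Keratin 14")
  tied <- spectralCountTable("x", data.frame(
    proteinName = c("Zeta protein", "Alpha protein"),
    uniquePeptides = c(2, 2), totalPeptideCount = c(10, 10),
    molWt = c(5000, 5000)))
  expect_equal(scRecords(rankByAbundance(tied))$proteinName,
               c("Alpha protein", "Zeta protein"))
  empty <- spectralCountTable("x", data.frame(
    proteinName = character(0), uniquePeptides = integer(0),
    totalPeptideCount = integer(0), molWt = numeric(0)))
  expect_error(rankByAbundance(empty), "insufficient")
})

test_that("keratin fraction reproduces the 98% uninvolved figure", {
  tab <- readSpectralCounts(uninvPath, "uninvolved")
  kf <- keratinFraction(tab)
  expect_equal(kf$keratinCounts, 342)
  expect_equal(kf$totalCounts, 349)
  expect_equal(kf$percentRounded, 98)
})

test_that("keratin fraction is bounded, order-invariant and classifiable", {
  tab <- readSpectralCounts(psorPath, "psoriatic")
  kf <- keratinFraction(tab)
  expect_true(kf$percent >= 0 && kf$percent <= 100)
  shuffled <- spectralCountTable("psoriatic",
                                 scRecords(tab)[rev(seq_len(13)), ])
  expect_equal(keratinFraction(shuffled)$percent, kf$percent)
  # the psoriatic table is a prominent-protein subset: warn when asked
  expect_warning(keratinFraction(tab, subset = TRUE), "subset")

  allKer <- spectralCountTable("x", data.frame(
    proteinName = c("Keratin 1", "Keratin 10"),
    uniquePeptides = c(2, 3), totalPeptideCount = c(5, 6),
    molWt = c(1e4, 2e4)))
  expect_equal(keratinFraction(allKer)$percent, 100)
  noKer <- spectralCountTable("x", data.frame(
    proteinName = c("Histone H4", "Plakoglobin"),
    uniquePeptides = c(2, 3), totalPeptideCount = c(5, 6),
    molWt = c(1e4, 2e4)))
  expect_equal(keratinFraction(noKer)$percent, 0)
  # override list admits non-prefixed names
  cls <- keratinClassifier(overrides = "Histone H4")
  expect_equal(keratinFraction(noKer, classifier = cls)$keratinCounts, 5)
})

test_that("malformed spectral-count files are rejected with positions", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("protein_name\tunique_peptides\ttotal_peptide_count\tmol_wt_da",
               "Keratin 1\t5\t10\t66039",
               "Keratin 2\t5\t3\t65433"), tmp)    # count < unique peptides
  expect_error(readSpectralCounts(tmp, "x"), "line\\(s\\) 3")
  writeLines(c("protein_name\tunique_peptides\ttotal_peptide_count\tmol_wt_da",
               "Keratin 1\t5\t10\t66039",
               "Keratin 1\t5\t10\t66039"), tmp)
  expect_error(readSpectralCounts(tmp, "x"), "duplicate")
  writeLines(c("protein\tcount", "a\t1"), tmp)
  expect_error(readSpectralCounts(tmp, "x"), "lacks column")
})

test_that("spectral summaries are written with ranked head and JSON", {
  tab <- readSpectralCounts(uninvPath, "uninvolved")
  out <- tempfile(fileext = ".tsv")
  s <- writeSpectralSummary(tab, out)
  expect_equal(s$keratin_percent, 98)
  ranked <- read.delim(out)
  expect_equal(ranked$protein_name[1], "Keratin 10")
  js <- jsonlite::fromJSON(sub("\\.tsv$", ".json", out))
  expect_equal(js$keratin_percent, 98)
  expect_equal(js$n_proteins, 13)
})
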
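test_that("codon alignments are parsed, validated and round-tripped", {
  a <- codonAlignment(c(s1 = "ATGGCT", s2 = "ATGGCA"))
  expect_equal(nCodons(a), 2L)
  expect_identical(taxa(a), c("s1", "s2"))

  expect_error(codonAlignment(c(x = "ATGGCTA")), "not divisible by 3")
  expect_error(codonAlignment(c(x = "ATGTAAGCT")),
               "internal stop codon at codon 2")
  expect_error(codonAlignment(c(a = "ATG", a = "ATG")), "duplicate taxon")
  expect_error(codonAlignment(character(0)), "empty")

  ## terminal stop stripped, ambiguity -> missing
  a2 <- codonAlignment(c(s1 = "ATGNNNGCTTAA", s2 = "ATGCCAG-ATGA"))
  expect_equal(nCodons(a2), 3L)
  expect_true(is.na(codonStates(a2)["s1", 2L]))
  expect_true(is.na(codonStates(a2)["s2", 3L]))

  ## strict gap handling drops exactly the incomplete columns
  strict <- dropGappedColumns(a2)
  expect_equal(attr(strict, "keptColumns"), 1L)
  expect_equal(nCodons(strict), 1L)
  expect_error(dropGappedColumns(codonAlignment(c(x = "NNN", y = "AAA"))),
               "no fully observed")

  ## FASTA round trip reproduces states exactly
  tmp <- tempfile(fileext = ".fasta")
  writeCodonAlignment(a2, tmp)
  a3 <- readCodonAlignment(tmp)
  expect_identical(codonStates(a3), codonStates(a2))

  ## sequential PHYLIP input
  tmp2 <- tempfile(fileext = ".phy")
  writeLines(c(" 2 6", "s1  ATGGCT", "s2  ATGGCA"), tmp2)
  a4 <- readCodonAlignment(tmp2)
  expect_identical(codonStates(a4), codonStates(a))
})

test_that("codon frequency schemes match hand-tallied expectations", {
  ## single sequence: F61 is a point mass
  a1 <- codonAlignment(c(s = "ATGATG"))
  f61 <- codonFrequencies(a1, "F61")
  expect_equal(f61@pi[match("ATG", codonTable()$codons)], 1)
  expect_equal(sum(f61@pi), 1)

  expect_equal(codonFrequencies(a1, "uniform")@pi, rep(1 / 61, 61))

  ## 3-sequence toy, F3x4 tallied by hand:
  ## codons ATG,CCT,ATG,CCA,GTG,CCT -> pos1 {A:2,C:3,G:1}, pos2 {T:3,C:3},
  ## pos3 {G:3,T:2,A:1}, each /6
  a3 <- codonAlignment(c(x = "ATGCCT", y = "ATGCCA", z = "GTGCCT"))
  f <- codonFrequencies(a3, "F3x4")
  p1 <- c(T = 0, C = 3, A = 2, G = 1) / 6
  p2 <- c(T = 3, C = 3, A = 0, G = 0) / 6
  p3 <- c(T = 2, C = 0, A = 1, G = 3) / 6
  tab <- codonTable()
  nt <- do.call(rbind, strsplit(tab$codons, ""))
  expected <- p1[nt[, 1L]] * p2[nt[, 2L]] * p3[nt[, 3L]]
  expected <- unname(expected / sum(expected))
  expect_equal(f@pi, expected, tolerance = 1e-12)

  expect_error(codonFrequencies(
    codonAlignment(c(s = "NNN", t = "---")), "F61"), "no unambiguous")
})

test_that("coordinate maps skip reference gaps bijectively", {
  a <- codonAlignment(c(ref = "ATG---GCTAAT", oth = "ATGCCCGCTAAT"))
  m <- mapColumnsToReference(a, "ref")
  expect_equal(columnToResidue(m, 3L), 2L)   # gap at column 2 skipped
  expect_equal(columnToResidue(m, 1L), 1L)
  expect_true(is.na(columnToResidue(m, 2L)))
  expect_equal(residueToColumn(m, columnToResidue(m, m@column)), m@column)
  expect_error(mapColumnsToReference(a, "nope"), "unknown reference")

  ## random gapped fixture checked against an independent gap-count scan
  set.seed(42)
  ncod <- 40L
  gaps <- sort(sample(ncod, 12L))
  seq_ <- rep("GCT", ncod); seq_[gaps] <- "---"
  aln <- codonAlignment(c(ref = paste(seq_, collapse = ""),
                          oth = paste(rep("GCA", ncod), collapse = "")))
  m2 <- mapColumnsToReference(aln, "ref")
  for (col in setdiff(seq_len(ncod), gaps))
    expect_equal(columnToResidue(m2, col), col - sum(gaps < col))
})
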
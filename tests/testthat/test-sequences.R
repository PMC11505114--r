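test_that("read_fasta parses the printed zein sequences into valid records", {
  recs <- zein_records()
  expect_length(recs, 6L)
  expect_equal(recs$P06674$length, 230L)
  expect_equal(recs$P06676$length, 240L)
  expect_equal(recs$Q94IM1$length, 266L)
  for (r in recs) {
    expect_true(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", r$sequence))
  }
  expect_equal(recs$P06674$name, "Zein-alpha 19A2")

  # declared lengths from the catalog: the P04705 printed block is shorter
  # than its catalogued 186 residues and must be flagged, never reconciled
  withcat <- read_fasta(zp_file("alpha_zein_printed.fasta"),
                        catalog = zein_catalog())
  expect_false(withcat$P06674$length_mismatch)
  expect_true(withcat$P04705$length_mismatch)
  expect_equal(withcat$P04705$length, 180L)
  expect_equal(withcat$P04705$length_declared, 186L)
})

test_that("read_fasta cleans whitespace, wraps, and rejects bad letters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">X some name", "ACDE"), f)
  recs <- read_fasta(f)
  expect_equal(recs$X$length, 4L)
  expect_equal(recs$X$name, "some name")

  # a line-wrap space inside the sequence is stripped
  writeLines(c(">Y", "ACD EFG", "HIK"), f)
  expect_equal(read_fasta(f)$Y$sequence, "ACDEFGHIK")

  writeLines(c(">X", "AC1E"), f)
  expect_error(read_fasta(f), "X")
  expect_error(read_fasta(f), "1")
})

test_that("percent identity is exact for self, correct for known pairs, symmetric", {
  x <- protein_record("x", "ACDEFGHIKLMNPQRSTVWY")
  expect_identical(percent_identity(x, x), 100)
  expect_equal(percent_identity(protein_record("a", "AAAA"),
                                protein_record("b", "AAAT")), 75)
  # one substitution in nine aligned positions
  expect_equal(percent_identity(protein_record("a", "ACDEFGHIK"),
                                protein_record("b", "ACDQFGHIK")),
               100 * 8 / 9, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:8) {
    a <- protein_record("a", random_peptide(sample(15:40, 1)))
    b <- protein_record("b", random_peptide(sample(15:40, 1)))
    expect_lt(abs(percent_identity(a, b) - percent_identity(b, a)), 1e-9)
  }
})

test_that("identity grouping is a single-linkage partition with longest-sequence representatives", {
  # chain rule: A~B and B~C merge all three even though A!~C
  cat3 <- data.frame(accession = c("A", "B", "C"),
                     length = c(10L, 12L, 11L))
  pairs <- data.frame(accession_a = c("A", "B", "A"),
                      accession_b = c("B", "C", "C"),
                      identity = c(95, 95, 40))
  grp <- group_by_identity(cat3, threshold = 90, pairs = pairs)
  expect_length(grp$groups, 1L)
  expect_setequal(grp$groups[[1]], c("A", "B", "C"))
  expect_equal(unname(grp$representatives), "B")  # longest

  # all below threshold: singletons
  pairs$identity <- c(10, 20, 30)
  grp2 <- group_by_identity(cat3, threshold = 90, pairs = pairs)
  expect_length(grp2$groups, 3L)

  # two identical records merge
  recs <- list(protein_record("r1", "ACDEACDE"),
               protein_record("r2", "ACDEACDE"))
  grp3 <- group_by_identity(recs, threshold = 90)
  expect_length(grp3$groups, 1L)
  # representative tie broken by lexicographic accession
  expect_equal(unname(grp3$representatives), "r1")
})

test_that("grouping the published identity matrix reproduces the reported merges", {
  pairs <- read.delim(zp_file("table1_identity.tsv"))
  grp <- group_by_identity(zein_catalog(), threshold = 90, pairs = pairs)
  find_group <- function(acc) {
    grp$groups[[which(vapply(grp$groups, function(g) acc %in% g,
                             logical(1)))]]
  }
  # the 22-kDa merges
  expect_setequal(find_group("Q94IM1"), c("Q94IM1", "P04698"))
  expect_setequal(find_group("P06679"), c("P06679", "P04700"))
  # the two sequences not >=90% similar to any other stay singletons
  expect_equal(find_group("P06678"), "P06678")
  expect_equal(find_group("P04705"), "P04705")
  # single-linkage chains the remaining 19-kDa entries into one component
  expect_length(grp$groups, 5L)
  expect_true(all(c("P06674", "P06676") %in% find_group("P06674")))

  # refinement monotonicity: raising the threshold never merges groups
  n_groups <- vapply(c(90, 92, 95, 97, 99, 100), function(th)
    length(group_by_identity(zein_catalog(), threshold = th,
                             pairs = pairs)$groups), integer(1))
  expect_true(all(diff(n_groups) >= 0))
})
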
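test_that("find_occurrences reports all overlapping matches", {
  expect_equal(find_occurrences("AAA", "AA"), c(0L, 1L))
  expect_equal(find_occurrences("ACD", "F"), integer(0))
  expect_equal(find_occurrences("AC", "ACDE"), integer(0))  # motif longer
  # exactly one IR in the printed P06674 sequence
  recs <- zein_records()
  expect_length(find_occurrences(recs$P06674$sequence, "IR"), 1L)
})

test_that("find_occurrences equals the brute-force position scan", {
  set.seed(11)
  for (i in 1:300) {
    s <- random_peptide(sample(3:60, 1), alphabet = c("A", "C", "D", "G"))
    m <- random_peptide(sample(1:4, 1), alphabet = c("A", "C", "D", "G"))
    expect_identical(find_occurrences(s, m), brute_positions(s, m),
                     label = paste(s, m))
  }
})

test_that("profile mode counts overlapping occurrences per activity and rounds A half-up", {
  recs <- zein_records()
  db <- zein_db()
  p <- profile_potential(recs$P06674, db)

  campde <- p[p$activity == "CaMPDE inhibitor", ]
  expect_equal(campde$fragments, "IR")
  expect_equal(campde$a, 1L)
  expect_equal(campde$A, 0.0043)

  dpp3 <- p[p$activity == "Dipeptidyl peptidase III inhibitor", ]
  expect_setequal(strsplit(dpp3$fragments, ", ")[[1]],
                  c("YL", "YR", "HL", "LA", "FL", "PF"))
  expect_equal(dpp3$a, 24L)
  expect_equal(dpp3$A, 0.1043)

  # the unrounded a/N times N is integral for every activity
  expect_true(all(abs(p$a - (p$a / p$N) * p$N) < 1e-9))

  # empty database gives an empty profile
  empty <- motif_db(data.frame(motif = character(0),
                               activity = character(0),
                               source = character(0)))
  expect_equal(nrow(profile_potential(recs$P06674, empty)), 0L)
})

test_that("adding a motif to an activity never decreases its count", {
  recs <- zein_records()
  s <- recs$P06674
  base <- tiny_db(c("PL", "GL"))
  more <- tiny_db(c("PL", "GL", "QQ"))
  a1 <- profile_potential(s, base)$a
  a2 <- profile_potential(s, more)$a
  expect_gte(a2, a1)
})

test_that("digest mode counts whole released peptides with multiplicity", {
  # a digest releasing PL, GL, CF, PF, PL (plus non-motif filler) from a
  # 230-residue parent must give a = 5 and A = 0.0217 for an activity
  # holding those motifs
  d <- structure(list(accession = "X", enzymes = "enzyme",
                      cut_sites = integer(0),
                      peptides = c("PL", "GL", "CF", "PF", "PL",
                                   rep("QQQQ", 55)),
                      parent_length = 230L),
                 class = "digest_result")
  db <- tiny_db(c("PL", "GL", "CF", "PF", "IR"))
  prof <- profile_digest(d, db)
  expect_equal(prof$a, 5L)
  expect_equal(prof$A, 0.0217)
  expect_setequal(strsplit(prof$fragments, ", ")[[1]],
                  c("PL", "GL", "CF", "PF"))

  # whole-peptide equality: a longer released peptide containing a motif
  # does not count
  d$peptides <- c("APLA", rep("QQQQ", 10))
  expect_equal(nrow(profile_digest(d, db)), 0L)

  # no matching peptides -> empty profile
  d$peptides <- rep("QQQQ", 10)
  expect_equal(nrow(profile_digest(d, db)), 0L)

  # a is bounded by the number of released peptides, on random digests
  set.seed(5)
  rules <- default_enzymes("gi")
  db2 <- tiny_db(c("PL", "L", "AK", "QF"))
  for (i in 1:50) {
    dd <- digest(random_peptide(sample(10:80, 1)), rules)
    pr <- profile_digest(dd, db2)
    if (nrow(pr) > 0) expect_true(all(pr$a <= length(dd$peptides)))
  }
})

test_that("reports are deterministic TSV with 4-decimal frequencies", {
  recs <- zein_records()
  db <- zein_db()
  p <- profile_potential(recs$P06674, db)
  lines <- render_report(p)
  expect_equal(lines[1], "accession\tmode\tactivity\tfragments\ta\tN\tA")
  expect_true(any(grepl("^P06674\tprofile\tHypouricemic\tLT, PT\t3\t230\t0\\.0130$",
                        lines)))
  q <- profile_potential(recs$Q94IM1, db)
  qlines <- render_report(q)
  expect_true(any(grepl(
    "^Q94IM1\tprofile\tDipeptidyl peptidase III inhibitor\t.*\t0\\.1053$",
    qlines)))
  # empty input: header only
  expect_length(render_report(p[0, ]), 1L)
  # identical input, identical output
  expect_identical(lines, render_report(p))
})
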
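test_that("cleavage sites follow P1 / P1' subrules", {
  trypsin <- cleavage_rule("trypsin",
                           list(list(p1 = c("K", "R"),
                                     p1prime_blocked = "P")))
  chymo <- cleavage_rule("chymo",
                         list(list(p1 = c("F", "Y", "W"),
                                   p1prime_blocked = character(0))))
  expect_equal(cleavage_sites("AAKAA", trypsin), 2L)
  expect_equal(cleavage_sites("AKPA", trypsin), integer(0))  # proline block
  expect_equal(cleavage_sites("AFAYA", chymo), c(1L, 3L))
  # a terminal P1 residue has no bond to cut
  expect_equal(cleavage_sites("AAK", trypsin), integer(0))
  expect_equal(cleavage_sites("K", trypsin), integer(0))
})

test_that("digest splits once at the union of sites and conserves the sequence", {
  d <- digest("AAKAA", "trypsin")
  expect_equal(d$peptides, c("AAK", "AA"))
  expect_equal(d$cut_sites, 2L)

  # no cut site: the whole sequence is released
  d0 <- digest("AAAAA", "trypsin")
  expect_equal(d0$peptides, "AAAAA")

  rep <- digest_report(digest("AAKAA", "trypsin"))
  expect_equal(rep$start, c(0L, 3L))
  expect_equal(rep$end, c(3L, 5L))
})

test_that("digestion is conservative, idempotent and enzyme-monotone on random sequences", {
  rules <- load_rules()
  gi <- rules[c("pepsin", "trypsin", "chymotrypsin")]
  set.seed(42)
  for (i in 1:200) {
    s <- random_peptide(sample(5:120, 1))
    d <- digest(s, gi)
    # conservation
    expect_identical(paste(d$peptides, collapse = ""), s)
    # cut sites strictly increasing within [0, N-2]
    if (length(d$cut_sites) > 0) {
      expect_true(all(diff(d$cut_sites) > 0))
      expect_true(all(d$cut_sites >= 0 & d$cut_sites <= nchar(s) - 2))
    }
    # idempotence: every released peptide is stable under re-digestion
    for (p in d$peptides) {
      expect_identical(digest(p, gi)$peptides, p)
    }
    # monotonicity: adding an enzyme never removes cut sites
    d_more <- digest(s, c(gi, rules["subtilisin"]))
    expect_true(all(d$cut_sites %in% d_more$cut_sites))
  }
})

test_that("the calibration harness ranks rule variants and itemizes mismatches", {
  db <- zein_db()
  gold <- golden_tables(mode = c("gi", "subtilisin"))
  gold <- gold[gold$accession %in% c("P06674", "P06676", "Q94IM1"), ]

  # empty golden set -> empty report
  empty <- calibrate_rules(calibration_candidates(), gold[0, ], db)
  expect_equal(nrow(empty$summary), 0L)

  # a trypsin cutting after K only scores no better than after K and R
  mk <- function(enz, p1) cleavage_rule(enz, list(list(
    p1 = p1, p1prime_blocked = "P")))
  gi_var <- function(name, try_p1) list(
    name = name, mode = "gi",
    rules = list(mk("pepsin", c("F", "L", "E")),
                 mk("trypsin", try_p1),
                 mk("chymotrypsin", c("F", "Y", "W"))))
  cal <- calibrate_rules(list(gi_var("try{KR}", c("K", "R")),
                              gi_var("try{K}", "K")), gold, db)
  hits <- setNames(cal$summary$hits, cal$summary$variant)
  expect_lte(hits[["try{K}"]], hits[["try{KR}"]])

  # the full candidate grid: winners are the shipped defaults
  full <- calibrate_rules(calibration_candidates(), gold, db)
  expect_equal(unname(full$winners["gi"]),
               "pepsin{FLE}+trypsin{KR|!P}+chymotrypsin{FYW|!P}")
  expect_equal(unname(full$winners["subtilisin"]), "subtilisin{FLIMVWYA}")
  shipped <- load_rules()
  expect_setequal(shipped$subtilisin$subrules[[1]]$p1,
                  c("F", "L", "I", "M", "V", "W", "Y", "A"))
  expect_setequal(shipped$pepsin$subrules[[1]]$p1, c("F", "L", "E"))
  expect_equal(shipped$trypsin$subrules[[1]]$p1prime_blocked, "P")

  # residual mismatches are itemized, including the known IR anomaly
  # (IR listed among GI-released fragments though no rule cuts an N-I bond)
  mm <- full$mismatches
  expect_gt(nrow(mm), 0L)
  expect_true(any(mm$accession == "P06674" &
                    grepl("\\bIR\\b", mm$golden_fragments)))
})
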
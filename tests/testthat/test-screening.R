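mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[1], hgvs = r[2], zygosity = r[3],
               stringsAsFactors = FALSE)))
}
no_calls <- data.frame(gene = character(), hgvs = character(),
                       zygosity = character())

test_that("genetic categories follow the carrier/refer rules", {
  expect_equal(categorize_genetics(no_calls), "negative")
  expect_equal(categorize_genetics(
    mk_calls(c("GJB2", "c.235delC", "hom"))), "refer")
  expect_equal(categorize_genetics(
    mk_calls(c("GJB2", "c.235delC", "het"), c("GJB2", "c.176_191del16", "het"))),
    "refer")
  expect_equal(categorize_genetics(
    mk_calls(c("GJB2", "c.235delC", "het"), c("SLC26A4", "c.919-2A>G", "het"))),
    "carrier")
  # mitochondrial calls alone are carriers, never biallelic refers
  expect_equal(categorize_genetics(
    mk_calls(c("MT_RNR1", "m.1555A>G", "heteroplasmic"))), "carrier")
  expect_equal(categorize_genetics(
    mk_calls(c("MT_RNR1", "m.1555A>G", "homoplasmic"))), "carrier")
})

test_that("categories agree with a truth-table oracle over all pairs", {
  pv <- panel_variants(the_panel)
  states <- expand.grid(i = seq_len(nrow(pv)), z = c("het", "hom"),
                        stringsAsFactors = FALSE)
  # normalise: MT variants only occur as heteroplasmic/homoplasmic
  state_call <- function(i, z) {
    mt <- pv$inheritance[i] == "mitochondrial"
    zyg <- if (mt) c(het = "heteroplasmic", hom = "homoplasmic")[[z]] else z
    c(pv$gene[i], pv$hgvs[i], zyg)
  }
  oracle <- function(calls) {
    if (nrow(calls) == 0) return("negative")
    auto <- calls[calls$gene != "MT_RNR1", , drop = FALSE]
    biallelic <- any(auto$zygosity == "hom") ||
      anyDuplicated(auto$gene[auto$zygosity == "het"]) > 0
    if (biallelic) "refer" else "carrier"
  }
  # all singletons and all unordered pairs of distinct variants
  for (a in seq_len(nrow(states))) {
    ca <- mk_calls(state_call(states$i[a], states$z[a]))
    expect_equal(categorize_genetics(ca), oracle(ca))
  }
  set.seed(1)
  pairs <- t(replicate(200, sort(sample(nrow(states), 2))))
  pairs <- pairs[states$i[pairs[, 1]] != states$i[pairs[, 2]], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    ca <- mk_calls(state_call(states$i[pairs[r, 1]], states$z[pairs[r, 1]]),
                   state_call(states$i[pairs[r, 2]], states$z[pairs[r, 2]]))
    expect_equal(categorize_genetics(ca), oracle(ca))
  }
})

test_that("an ambiguous probe forces manual review", {
  gs <- structure(list(
    sample_id = "S", calls = no_calls,
    probe_status = data.frame(reaction = "A", channel = "FAM",
                              status = "ambiguous", flags = "x")),
    class = "genotype_set")
  expect_equal(categorize_genetics(gs), "review_required")
})

test_that("severity bins follow the diagnostic thresholds", {
  expect_equal(classify_severity(26), "mild")
  expect_equal(classify_severity(40), "mild")
  expect_equal(classify_severity(45), "moderate")
  expect_equal(classify_severity(60), "moderate")
  expect_equal(classify_severity(61), "severe")
  expect_equal(classify_severity(80), "severe")
  expect_equal(classify_severity(81), "profound")
  expect_equal(classify_severity(95), "profound")
  expect_error(classify_severity(25), "not hearing loss")
})

test_that("recommendations are deterministic, idempotent and order-independent", {
  hearing_pass <- hearing_trajectory("pass", "pass")
  mt <- mk_calls(c("MT_RNR1", "m.1555A>G", "heteroplasmic"))
  rec <- recommend(mt, "carrier", hearing_pass)
  expect_true(all(c("AVOID_AMINOGLYCOSIDES", "MATERNAL_LINEAGE_COUNSELING") %in% rec))

  expect_equal(recommend(no_calls, "negative", hearing_pass), character())

  hom <- mk_calls(c("SLC26A4", "c.1226G>A", "hom"))
  rec2 <- recommend(hom, "refer", hearing_pass)
  expect_true("DIAGNOSTIC_AUDIOLOGY_REFERRAL" %in% rec2)
  expect_true("FAMILY_GENETIC_DIAGNOSIS" %in% rec2)

  gjb3 <- mk_calls(c("GJB3", "c.538C>T", "het"))
  expect_true("ROUTINE_FOLLOWUP" %in% recommend(gjb3, "carrier", hearing_pass))

  het2 <- mk_calls(c("GJB2", "c.235delC", "het"))
  expect_true("HEARING_FOLLOWUP_DELAYED_ONSET" %in%
              recommend(het2, "carrier", hearing_pass))

  # order independence and idempotence
  two <- mk_calls(c("GJB2", "c.235delC", "het"), c("MT_RNR1", "m.1555A>G", "heteroplasmic"))
  two_rev <- two[2:1, ]
  expect_identical(recommend(two, "carrier", hearing_pass),
                   recommend(two_rev, "carrier", hearing_pass))
  expect_identical(recommend(two, "carrier", hearing_pass),
                   sort(unique(recommend(two, "carrier", hearing_pass))))
})

test_that("the hearing state machine only accepts legal transitions", {
  s <- hearing_trajectory()
  s <- advance_hearing(s, list(stage = "initial", result = "pass"))
  expect_equal(s$initial_oae, "pass")
  # second screen is taken by everyone, also after an initial pass
  s <- advance_hearing(s, list(stage = "second", result = "refer"))
  s <- advance_hearing(s, list(stage = "diagnosis", threshold_db = 55,
                               laterality = "bilateral", age_months = 7))
  expect_equal(s$diagnosis$severity, "moderate")

  # diagnosis before the second screen is a state error
  s2 <- advance_hearing(hearing_trajectory(),
                        list(stage = "initial", result = "refer"))
  expect_error(advance_hearing(s2, list(stage = "diagnosis", threshold_db = 50,
                                        laterality = "unilateral",
                                        age_months = 6)),
               "before second screen")

  # initial refer then second pass terminates without a diagnosis path
  s3 <- advance_hearing(s2, list(stage = "second", result = "pass"))
  expect_error(advance_hearing(s3, list(stage = "diagnosis", threshold_db = 50,
                                        laterality = "unilateral",
                                        age_months = 6)),
               "failed second screen")
  # ... unless flagged as a late diagnosis
  s4 <- advance_hearing(s3, list(stage = "diagnosis", threshold_db = 50,
                                 laterality = "unilateral", age_months = 18,
                                 late = TRUE))
  expect_true(s4$late_diagnosis)

  expect_error(advance_hearing(hearing_trajectory(),
                               list(stage = "second", result = "pass")),
               "before initial")
  expect_error(advance_hearing(s, list(stage = "bogus")), "unknown event")
})
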
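fixture_cohort <- generate_cohort(fixture_cohort_spec())

test_that("allele frequencies reproduce the screening-report convention", {
  af <- allele_frequencies(fixture_cohort)
  row <- function(v) af[af$hgvs == v, ]
  expect_equal(row("c.235delC")$carrier_count, 58L)
  expect_equal(round(row("c.235delC")$allele_frequency_paper_pct, 2), 1.17)
  expect_equal(round(row("c.919-2A>G")$allele_frequency_paper_pct, 2), 0.78)
  expect_equal(round(row("c.167delT")$allele_frequency_paper_pct, 2), 0)
  # mitochondrial variants: no diploid allele count, carrier proportion instead
  expect_true(is.na(row("m.1555A>G")$allele_frequency_strict_pct))
  expect_equal(round(row("m.1555A>G")$allele_frequency_paper_pct, 2), 0.18)
  expect_error(allele_frequencies(
    structure(list(neonates = NULL, calls = fixture_cohort$calls, n_total = 0),
              class = "cohort_table")), "denominator")
})

test_that("strict and paper conventions differ by exactly hom/(2N) per variant", {
  af <- allele_frequencies(fixture_cohort)
  auto <- af[!is.na(af$allele_frequency_strict_pct), ]
  expect_equal(auto$allele_frequency_strict_pct - auto$allele_frequency_paper_pct,
               auto$hom_count / (2 * fixture_cohort$n_total) * 100)
  # the two fixture variants with homozygotes are the only flagged rows
  expect_setequal(af$hgvs[af$conventions_differ], c("c.235delC", "c.1226G>A"))
  expect_equal(round(af$allele_frequency_strict_pct[af$hgvs == "c.1226G>A"], 2),
               0.10)
})

test_that("carrier rate uses an exact binomial interval", {
  cr <- carrier_rate(fixture_cohort)
  expect_equal(cr$carriers, 170L)
  expect_equal(round(cr$rate_pct, 1), 6.8)

  # oracle: Clopper-Pearson bounds from beta quantiles, 1 of 4
  small <- structure(list(
    neonates = data.frame(id = c("a", "b", "c", "d")),
    calls = data.frame(id = "a", gene = "GJB2", hgvs = "c.35delG",
                       zygosity = "het", heteroplasmy_fraction = NA),
    n_total = 4L), class = "cohort_table")
  cr2 <- carrier_rate(small)
  expect_equal(cr2$rate, 0.25)
  expect_equal(cr2$ci_lower, qbeta(0.025, 1, 4), tolerance = 1e-10)
  expect_equal(cr2$ci_upper, qbeta(0.975, 2, 3), tolerance = 1e-10)

  empty <- structure(list(neonates = NULL, calls = small$calls, n_total = 0),
                     class = "cohort_table")
  expect_error(carrier_rate(empty), "denominator")
})

test_that("a balanced table gives chi-squared 0 and Fisher p 1", {
  res <- crosstab_tests(table = matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$chisq_stat, 0)
  expect_equal(res$fisher_p, 1)
})

test_that("chi-squared matches the closed form on random tables", {
  set.seed(42)
  for (r in 1:200) {
    tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2)
    res <- crosstab_tests(table = tab)
    expect_equal(res$chisq_stat, chisq_closed_form(tab), tolerance = 1e-10)
  }
})

test_that("Fisher p matches brute-force hypergeometric enumeration", {
  set.seed(7)
  for (r in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(2:12, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- crosstab_tests(table = tab)
    expect_equal(res$fisher_p, fisher_enum_p(tab), tolerance = 1e-9)
  }
  # the fixture genetic-positive x initial-refer table, and a diagonal table
  tab_fix <- matrix(c(14, 156, 130, 2188), 2, byrow = TRUE)
  expect_equal(crosstab_tests(table = tab_fix)$fisher_p, fisher_enum_p(tab_fix),
               tolerance = 1e-12)
  tab_diag <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(crosstab_tests(table = tab_diag)$fisher_p,
               fisher_enum_p(tab_diag), tolerance = 1e-12)
  # tail-doubling variant stays a valid p and is capped at 1
  expect_lte(crosstab_tests(table = tab_diag)$fisher_doubling_p, 1)
})

test_that("degenerate tables are flagged rather than tested", {
  res <- crosstab_tests(table = matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(is.na(res$chisq_p))
  expect_equal(res$flags, "zero_margin_tests_undefined")
  res2 <- crosstab_tests(table = matrix(c(2, 3, 4, 50), 2))
  expect_true("expected_cell_below_5" %in% res2$flags)
})

test_that("cohort cross-tab grouping extracts the right margins", {
  res <- crosstab_tests(fixture_cohort, "positive", "initial_refer")
  expect_equal(as.vector(res$table), c(14, 130, 156, 2188))
  res2 <- crosstab_tests(fixture_cohort, "positive", "second_refer")
  expect_equal(as.vector(res2$table), c(9, 23, 161, 2295))
})

test_that("diagnostic yield reproduces the case accounting", {
  dy <- diagnostic_yield(fixture_cohort)
  expect_equal(dy$n_diagnosed, 11L)
  expect_equal(round(dy$prevalence_per_1000, 1), 4.4)
  expect_equal(dy$n_failed_nhs, 8L)
  expect_equal(dy$n_missed_found_by_genetics, 2L)
  expect_equal(dy$n_diagnosed_variant_positive, 7L)
  expect_equal(dy$yield_increase_pct, 25.0)

  none <- fixture_cohort
  none$neonates$diagnosed <- FALSE
  dy0 <- diagnostic_yield(none)
  expect_equal(dy0$n_diagnosed, 0L)
  expect_true(is.na(dy0$yield_increase_pct))
  expect_equal(dy0$flags, "yield_undefined_no_nhs_failures")
})

test_that("cohort summary recomputes the remaining headline shares", {
  s <- cohort_summary(fixture_cohort)
  expect_equal(round(s$gjb2_share_pct, 1), 50.0)
  expect_equal(s$n_refer_category, 4L)
  expect_equal(s$initial_refer_total, 144L)
  expect_equal(s$second_fail_total, 32L)
})
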
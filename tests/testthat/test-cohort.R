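test_that("the packaged fixture reproduces the study's headline counts", {
  cohort <- generate_cohort(fixture_cohort_spec())
  expect_equal(cohort$n_total, 2488L)
  expect_equal(length(unique(cohort$calls$id)), 170L)

  per_id <- split(cohort$calls, cohort$calls$id)
  n_double <- sum(vapply(per_id, function(cc) sum(cc$zygosity == "het") >= 2,
                         logical(1)))
  expect_equal(n_double, 5L)
  expect_equal(sum(vapply(per_id, function(cc) any(cc$zygosity == "hom"),
                          logical(1))), 3L)

  nn <- cohort$neonates
  expect_equal(sum(nn$initial_oae == "refer"), 144L)
  expect_equal(sum(nn$second_aabr == "refer"), 32L)
  expect_equal(sum(nn$initial_oae == "pass" & nn$second_aabr == "refer"), 7L)
  expect_equal(sum(nn$diagnosed), 11L)
  # one diagnosed neonate with ototoxic history and negative genetics
  oto <- nn[nn$ototoxic_history, ]
  expect_equal(nrow(oto), 1L)
  expect_true(oto$diagnosed)
  expect_false(oto$id %in% cohort$calls$id)
  expect_equal(oto$severity, "moderate")
})

test_that("fixture refer categories: three homozygotes plus one same-gene double het", {
  cohort <- generate_cohort(fixture_cohort_spec())
  nn <- cohort$neonates
  refer_ids <- nn$id[nn$genetic_category == "refer"]
  expect_length(refer_ids, 4L)
  refer_calls <- cohort$calls[cohort$calls$id %in% refer_ids, ]
  expect_equal(sum(refer_calls$zygosity == "hom"), 3L)
  same_gene <- refer_ids[!refer_ids %in% refer_calls$id[refer_calls$zygosity == "hom"]]
  pair <- sort(cohort$calls$hgvs[cohort$calls$id == same_gene])
  expect_equal(pair, c("c.176_191del16", "c.235delC"))
  # all remaining positives are carriers
  pos <- unique(cohort$calls$id)
  expect_true(all(nn$genetic_category[nn$id %in% setdiff(pos, refer_ids)] == "carrier"))
  expect_true(all(nn$genetic_category[!nn$id %in% pos] == "negative"))
})

test_that("cohort materialisation is a bijection on the spec margins", {
  spec <- fixture_cohort_spec()
  cohort <- generate_cohort(spec)
  got <- cohort_margins(cohort)
  norm_key <- function(v, z) {
    vapply(seq_along(v), function(i) {
      vv <- strsplit(v[i], "/", fixed = TRUE)[[1]]
      zz <- strsplit(z[i], "/", fixed = TRUE)[[1]]
      if (length(zz) == 1) zz <- rep(zz, length(vv))
      ord <- order(vv)
      paste(paste(vv[ord], collapse = "/"), paste(zz[ord], collapse = "/"),
            sep = ":")
    }, "")
  }
  want <- spec$groups
  want_key <- norm_key(want$variants, want$zygosity)
  got_key <- norm_key(got$variants, got$zygosity)
  for (cell in c("n", "ip_sp", "ip_sr", "ir_sp", "ir_sr")) {
    expect_equal(got[[cell]][match(want_key, got_key)], want[[cell]],
                 ignore_attr = TRUE)
  }
  neg <- got[got$variants == "negative", ]
  expect_equal(neg$ip_sp, spec$negatives$ip_sp)
  expect_equal(neg$ir_sr, spec$negatives$ir_sr)
})

test_that("small specs materialise exactly and deterministically", {
  groups <- data.frame(variants = "m.1555A>G", zygosity = "mt", n = 2,
                       ip_sp = 2, ip_sr = 0, ir_sp = 0, ir_sr = 0)
  spec <- cohort_spec(groups, list(ip_sp = 8, ip_sr = 0, ir_sp = 0, ir_sr = 0),
                      seed = 3L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_equal(c1$neonates, c2$neonates)
  expect_equal(c1$calls, c2$calls)
  expect_equal(c1$n_total, 10L)
  expect_true(all(c1$calls$heteroplasmy_fraction > 0.2 &
                  c1$calls$heteroplasmy_fraction < 0.8))
  # all-negative cohort: every record category-negative downstream
  spec0 <- cohort_spec(groups[0, ], list(ip_sp = 10, ip_sr = 0, ir_sp = 0,
                                         ir_sr = 0))
  c0 <- generate_cohort(spec0)
  expect_equal(c0$n_total, 10L)
  expect_true(all(c0$neonates$genetic_category == "negative"))
})

test_that("inconsistent specs are rejected with the violated margin named", {
  g <- data.frame(variants = "c.35delG", zygosity = "het", n = 3,
                  ip_sp = 1, ip_sr = 0, ir_sp = 0, ir_sr = 1)
  expect_error(cohort_spec(g, list(ip_sp = 1, ip_sr = 0, ir_sp = 0, ir_sr = 0)),
               "do not sum to n for group 'c.35delG:het'")
  g$n <- 2
  d <- data.frame(subject = 1, group = "c.35delG:het", route = "ip_sr",
                  sex = "male", age_months = 6, threshold_db = 50,
                  laterality = "bilateral", treatment = 3, ototoxic = FALSE)
  expect_error(cohort_spec(g, list(ip_sp = 0, ip_sr = 0, ir_sp = 0, ir_sr = 0),
                           d),
               "more diagnoses than neonates")
})

test_that("emitted raw curves round-trip through the caller at zero noise", {
  groups <- data.frame(
    variants = c("c.235delC", "c.919-2A>G/c.235delC"),
    zygosity = c("hom", "het/het"),
    n = c(1, 1), ip_sp = c(1, 1), ip_sr = 0, ir_sp = 0, ir_sr = 0)
  spec <- cohort_spec(groups, list(ip_sp = 1, ip_sr = 0, ir_sp = 0, ir_sr = 0),
                      seed = 7L)
  cohort <- generate_cohort(spec, the_panel,
                            melt_sim_params(noise_sd = 0), emit_curves = TRUE)
  for (id in cohort$neonates$id) {
    gs <- call_sample(cohort$curves[[id]], the_panel)
    want <- cohort$calls[cohort$calls$id == id, c("hgvs", "zygosity")]
    got <- gs$calls[, c("hgvs", "zygosity")]
    expect_equal(got[order(got$hgvs), ], want[order(want$hgvs), ],
                 ignore_attr = TRUE)
  }
})
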
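#' Per-variant allele and carrier frequencies
#'
#' Computes, for every panel variant, the carrier count (neonates with at
#' least one call of that variant) and two allele-frequency conventions, both
#' as percentages:
#' \describe{
#'   \item{paper convention}{`carriers / (2N) * 100` - the screening-report
#'     convention, which counts a homozygote once;}
#'   \item{strict convention}{allele counting with homozygotes contributing
#'     two alleles, `(het + 2 * hom) / (2N) * 100`. Mitochondrial variants
#'     have no diploid allele count and are excluded from the strict estimate
#'     (`NA`); their carrier proportion `carriers / N * 100` is reported
#'     instead.}
#' }
#' The two conventions differ by exactly `hom / (2N) * 100` per autosomal
#' variant; rows where they differ are flagged.
#'
#' @param cohort A `cohort_table`.
#' @param panel An `mmca_panel` giving the variant universe (zero-carrier
#'   variants are reported with frequency 0).
#' @return A data frame: `gene`, `hgvs`, `dbsnp`, `acmg_class`,
#'   `carrier_count`, `hom_count`, `allele_frequency_paper_pct`,
#'   `allele_frequency_strict_pct`, `carrier_proportion_pct`,
#'   `conventions_differ`.
#' @export
allele_frequencies <- function(cohort, panel = load_panel()) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- cohort$n_total
  if (n == 0) stop("empty cohort: no denominator", call. = FALSE)
  pv <- panel_variants(panel)
  calls <- cohort$calls
  carrier <- vapply(pv$hgvs, function(v) length(unique(calls$id[calls$hgvs == v])), 1L)
  hom <- vapply(pv$hgvs, function(v)
    sum(calls$hgvs == v & calls$zygosity == "hom"), 1L)
  is_mt <- pv$inheritance == "mitochondrial"
  paper <- carrier / (2 * n) * 100
  strict <- (carrier + hom) / (2 * n) * 100
  strict[is_mt] <- NA_real_
  data.frame(
    gene = pv$gene, hgvs = pv$hgvs, dbsnp = pv$dbsnp,
    acmg_class = pv$acmg_class, carrier_count = carrier, hom_count = hom,
    allele_frequency_paper_pct = paper,
    allele_frequency_strict_pct = strict,
    carrier_proportion_pct = carrier / n * 100,
    conventions_differ = !is_mt & hom > 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort carrier rate with exact binomial confidence interval
#'
#' Proportion of neonates carrying at least one panel variant, with a
#' Clopper-Pearson interval.
#'
#' @param cohort A `cohort_table`.
#' @param conf_level Confidence level.
#' @return A list: `carriers`, `n`, `rate` (proportion), `rate_pct`,
#'   `ci_lower`, `ci_upper` (proportions).
#' @export
carrier_rate <- function(cohort, conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- cohort$n_total
  if (n == 0) stop("empty cohort: no denominator", call. = FALSE)
  k <- length(unique(cohort$calls$id))
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(carriers = k, n = n, rate = k / n, rate_pct = k / n * 100,
       ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2])
}

#' Two-sided Fisher exact p by tail doubling
#'
#' The doubling convention: twice the smaller one-sided hypergeometric tail,
#' capped at 1. The default convention elsewhere in the package (and in
#' [stats::fisher.test()]) instead sums all tables at least as extreme as the
#' observed one.
#'
#' @param tab 2x2 integer matrix.
#' @return The doubled-tail p value.
#' @export
fisher_doubling_p <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  x <- tab[1, 1]; m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  lower <- stats::phyper(x, k, m + nn - k, m)
  upper <- stats::phyper(x - 1, k, m + nn - k, m, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Contingency tests on a genetic x hearing 2x2 table
#'
#' Builds the 2x2 table from two binary groupings of a cohort and runs the
#' Pearson chi-squared test (with and without Yates continuity correction,
#' 1 df) and the two-sided Fisher exact test (probability-summation
#' convention; the tail-doubling variant is also reported). Tables with an
#' expected cell below 5 carry an advisory flag; a zero margin makes the
#' tests undefined and is flagged instead of tested.
#'
#' @param cohort A `cohort_table`, or `NULL` when `table` is supplied.
#' @param genetic_grouping Either a logical vector over neonates or one of
#'   `"positive"` (any call) / `"refer"` (refer category).
#' @param hearing_endpoint Either a logical vector or one of
#'   `"initial_refer"`, `"second_refer"`, `"diagnosed"`.
#' @param table Optionally a ready-made 2x2 matrix (rows: grouping TRUE /
#'   FALSE; columns: endpoint TRUE / FALSE); overrides the cohort arguments.
#' @return A list: `table`, `chisq_stat`, `chisq_p`, `chisq_yates_stat`,
#'   `chisq_yates_p`, `fisher_p`, `fisher_doubling_p`, `flags`.
#' @export
crosstab_tests <- function(cohort = NULL, genetic_grouping = "positive",
                           hearing_endpoint = "initial_refer", table = NULL) {
  if (is.null(table)) {
    stopifnot(inherits(cohort, "cohort_table"))
    pos_ids <- unique(cohort$calls$id)
    gvec <- if (is.logical(genetic_grouping)) genetic_grouping else
      switch(genetic_grouping,
             positive = cohort$neonates$id %in% pos_ids,
             refer = cohort$neonates$genetic_category == "refer",
             stop("unknown genetic grouping: ", genetic_grouping, call. = FALSE))
    hvec <- if (is.logical(hearing_endpoint)) hearing_endpoint else
      switch(hearing_endpoint,
             initial_refer = cohort$neonates$initial_oae == "refer",
             second_refer = cohort$neonates$second_aabr == "refer",
             diagnosed = cohort$neonates$diagnosed,
             stop("unknown hearing endpoint: ", hearing_endpoint, call. = FALSE))
    table <- matrix(c(sum(gvec & hvec), sum(gvec & !hvec),
                      sum(!gvec & hvec), sum(!gvec & !hvec)),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(group = c("yes", "no"),
                                    endpoint = c("yes", "no")))
  }
  stopifnot(all(table >= 0))
  flags <- character()
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(table = table, chisq_stat = NA_real_, chisq_p = NA_real_,
                chisq_yates_stat = NA_real_, chisq_yates_p = NA_real_,
                fisher_p = NA_real_, fisher_doubling_p = NA_real_,
                flags = "zero_margin_tests_undefined"))
  }
  exp_cells <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_cells < 5)) flags <- c(flags, "expected_cell_below_5")
  cs <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  csy <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  fi <- stats::fisher.test(table)
  list(table = table,
       chisq_stat = unname(cs$statistic), chisq_p = cs$p.value,
       chisq_yates_stat = unname(csy$statistic), chisq_yates_p = csy$p.value,
       fisher_p = fi$p.value, fisher_doubling_p = fisher_doubling_p(table),
       flags = flags)
}

#' Diagnostic yield of combined genetic and hearing screening
#'
#' Summarises the diagnosed hearing-loss cases of a cohort: prevalence per
#' 1000 neonates, the number missed by the initial hearing screen but
#' carrying panel variants, and the relative increase in case finding that
#' genetic screening adds over the hearing screen alone
#' (`missed-but-variant-positive / diagnosed-initial-refer * 100`).
#'
#' @param cohort A `cohort_table`.
#' @return A list: `n_diagnosed`, `prevalence_per_1000`, `n_failed_nhs`
#'   (diagnosed with an initial-screen refer), `n_missed_found_by_genetics`
#'   (diagnosed, initial pass, at least one variant call),
#'   `n_diagnosed_variant_positive`, `yield_increase_pct` (NA with a flag
#'   when no diagnosed case failed the initial screen), `flags`.
#' @export
diagnostic_yield <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  nn <- cohort$neonates
  pos_ids <- unique(cohort$calls$id)
  diag <- nn[nn$diagnosed, , drop = FALSE]
  n_failed <- sum(diag$initial_oae == "refer")
  n_missed <- sum(diag$initial_oae == "pass" & diag$id %in% pos_ids)
  flags <- character()
  yield <- if (n_failed == 0) {
    flags <- "yield_undefined_no_nhs_failures"
    NA_real_
  } else n_missed / n_failed * 100
  list(n_diagnosed = nrow(diag),
       prevalence_per_1000 = nrow(diag) / cohort$n_total * 1000,
       n_failed_nhs = n_failed,
       n_missed_found_by_genetics = n_missed,
       n_diagnosed_variant_positive = sum(diag$id %in% pos_ids),
       yield_increase_pct = yield,
       flags = flags)
}

#' Headline summary statistics of a screening cohort
#'
#' One-stop aggregation used by reports and the command-line interface:
#' carrier rate, per-gene shares, double-heterozygote and homozygote counts,
#' hearing-screen totals, and the diagnostic yield block.
#'
#' @param cohort A `cohort_table`.
#' @param panel An `mmca_panel`.
#' @return A list of scalar summaries (see source for fields).
#' @export
cohort_summary <- function(cohort, panel = load_panel()) {
  stopifnot(inherits(cohort, "cohort_table"))
  nn <- cohort$neonates
  calls <- cohort$calls
  cr <- carrier_rate(cohort)
  af <- allele_frequencies(cohort, panel)
  per_id <- split(calls, calls$id)
  n_double_het <- sum(vapply(per_id, function(cc)
    sum(cc$zygosity == "het") >= 2, logical(1)))
  n_hom_carriers <- sum(vapply(per_id, function(cc)
    any(cc$zygosity == "hom"), logical(1)))
  gjb2_share <- if (cr$carriers > 0)
    sum(af$carrier_count[af$gene == "GJB2"]) / cr$carriers * 100 else NA_real_
  dy <- diagnostic_yield(cohort)
  list(
    n_total = cohort$n_total,
    n_positive = cr$carriers,
    carrier_rate_pct = cr$rate_pct,
    carrier_rate_ci = c(cr$ci_lower, cr$ci_upper) * 100,
    n_double_het = n_double_het,
    n_hom_carriers = n_hom_carriers,
    n_refer_category = sum(nn$genetic_category == "refer"),
    n_carrier_category = sum(nn$genetic_category == "carrier"),
    gjb2_share_pct = gjb2_share,
    initial_refer_total = sum(nn$initial_oae == "refer"),
    second_fail_total = sum(nn$second_aabr == "refer"),
    initial_pass_second_fail = sum(nn$initial_oae == "pass" &
                                   nn$second_aabr == "refer"),
    diagnostic_yield = dy,
    allele_frequencies = af)
}
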
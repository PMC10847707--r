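#' Read melt curves from long-format delimited text
#'
#' Expects a CSV with header
#' `sample_id,reaction,channel,temperature_c,fluorescence` (UTF-8, decimal
#' point). Rows are grouped by (sample, reaction, channel), sorted by
#' temperature and validated; a repeated temperature within one curve is a
#' parse error naming the offending line. Row order in the file does not
#' affect the result.
#'
#' @param path Path to the curves file.
#' @return A list of [melt_curve()] objects, ordered by sample, reaction,
#'   channel.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("curves file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "reaction", "channel", "temperature_c", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("curves file parse error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$temperature_c) || anyNA(df$fluorescence)) {
    bad <- which(is.na(df$temperature_c) | is.na(df$fluorescence))[1]
    stop("curves file parse error at line ", bad + 1L,
         ": missing or non-numeric value", call. = FALSE)
  }
  df$.line <- seq_len(nrow(df)) + 1L   # header is line 1
  groups <- split(df, list(df$sample_id, df$reaction, df$channel), drop = TRUE)
  curves <- lapply(groups, function(g) {
    g <- g[order(g$temperature_c), , drop = FALSE]
    dup <- which(duplicated(g$temperature_c))
    if (length(dup)) {
      stop("curves file parse error at line ", g$.line[dup[1]],
           ": repeated temperature ", g$temperature_c[dup[1]],
           " for curve ", g$sample_id[1], "/", g$reaction[1], "/",
           g$channel[1], call. = FALSE)
    }
    melt_curve(g$sample_id[1], g$reaction[1], g$channel[1],
               g$temperature_c, g$fluorescence)
  })
  ord <- order(vapply(curves, function(cv)
    paste(cv$sample_id, cv$reaction, cv$channel), ""))
  unname(curves[ord])
}

#' Write melt curves to long-format delimited text
#'
#' Inverse of [read_curves()].
#'
#' @param curves List of [melt_curve()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, reaction = cv$reaction,
               channel = cv$channel,
               temperature_c = sprintf("%.2f", cv$temperature),
               fluorescence = sprintf("%.6f", cv$fluorescence),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_pct <- function(x) ifelse(is.na(x), NA, sprintf("%.2f", x))
fmt_p <- function(x) ifelse(is.na(x), NA, signif(x, 3))

#' Write the per-neonate and cohort screening reports
#'
#' Emits two files: `<stem>_neonates.tsv`, one row per neonate (calls,
#' zygosity, heteroplasmy, genetic category, hearing states,
#' recommendations), and `<stem>_cohort.json` with the aggregate statistics
#' (both allele-frequency conventions, cross-tab tests, diagnostic yield).
#' Frequencies are printed as percentages with two decimals and p values to
#' three significant figures; output is byte-identical across reruns of the
#' same cohort.
#'
#' @param cohort A `cohort_table`.
#' @param panel An `mmca_panel`.
#' @param stem Output path stem (directory must exist).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_screen_report <- function(cohort, panel = load_panel(), stem = "screen") {
  stopifnot(inherits(cohort, "cohort_table"))
  nn <- cohort$neonates
  calls <- cohort$calls
  per <- lapply(nn$id, function(id) {
    cc <- calls[calls$id == id, , drop = FALSE]
    row <- nn[nn$id == id, , drop = FALSE]
    hearing <- hearing_trajectory(
      row$initial_oae, row$second_aabr,
      diagnosis = if (row$diagnosed)
        list(threshold_db = row$threshold_db, laterality = row$laterality,
             age_months = row$age_months) else NULL,
      late_diagnosis = row$late_diagnosis)
    rec <- recommend(cc, row$genetic_category, hearing)
    data.frame(
      id = id,
      calls = paste(cc$hgvs, collapse = ";"),
      zygosity = paste(cc$zygosity, collapse = ";"),
      heteroplasmy = paste(ifelse(is.na(cc$heteroplasmy_fraction), "",
                                  sprintf("%.3f", cc$heteroplasmy_fraction)),
                           collapse = ";"),
      genetic_category = row$genetic_category,
      initial_oae = row$initial_oae, second_aabr = row$second_aabr,
      diagnosed = row$diagnosed,
      severity = ifelse(is.na(row$severity), "", row$severity),
      laterality = ifelse(is.na(row$laterality), "", row$laterality),
      recommendations = paste(rec, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tsv_path <- paste0(stem, "_neonates.tsv")
  json_path <- paste0(stem, "_cohort.json")
  utils::write.table(do.call(rbind, per), tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  s <- cohort_summary(cohort, panel)
  af <- s$allele_frequencies
  xt_init <- crosstab_tests(cohort, "positive", "initial_refer")
  xt_second <- crosstab_tests(cohort, "positive", "second_refer")
  report <- list(
    seed = cohort$seed,
    n_total = s$n_total,
    n_positive = s$n_positive,
    carrier_rate_percent = as.numeric(fmt_pct(s$carrier_rate_pct)),
    carrier_rate_ci_percent = as.numeric(fmt_pct(s$carrier_rate_ci)),
    n_double_het = s$n_double_het,
    n_hom_carriers = s$n_hom_carriers,
    n_refer_category = s$n_refer_category,
    n_carrier_category = s$n_carrier_category,
    gjb2_share_percent = as.numeric(fmt_pct(s$gjb2_share_pct)),
    initial_refer_total = s$initial_refer_total,
    second_fail_total = s$second_fail_total,
    initial_pass_second_fail = s$initial_pass_second_fail,
    diagnostic_yield = list(
      n_diagnosed = s$diagnostic_yield$n_diagnosed,
      prevalence_per_1000 = round(s$diagnostic_yield$prevalence_per_1000, 1),
      n_failed_nhs = s$diagnostic_yield$n_failed_nhs,
      n_missed_found_by_genetics = s$diagnostic_yield$n_missed_found_by_genetics,
      n_diagnosed_variant_positive = s$diagnostic_yield$n_diagnosed_variant_positive,
      yield_increase_percent = fmt_p(s$diagnostic_yield$yield_increase_pct)),
    allele_frequencies = data.frame(
      gene = af$gene, hgvs = af$hgvs,
      carriers = af$carrier_count,
      af_paper_percent = fmt_pct(af$allele_frequency_paper_pct),
      af_strict_percent = fmt_pct(af$allele_frequency_strict_pct),
      carrier_proportion_percent = fmt_pct(af$carrier_proportion_pct),
      conventions_differ = af$conventions_differ,
      stringsAsFactors = FALSE),
    crosstab_initial_refer = list(
      table = as.vector(xt_init$table),
      chisq_p = fmt_p(xt_init$chisq_p), fisher_p = fmt_p(xt_init$fisher_p),
      flags = xt_init$flags),
    crosstab_second_refer = list(
      table = as.vector(xt_second$table),
      chisq_p = fmt_p(xt_second$chisq_p), fisher_p = fmt_p(xt_second$fisher_p),
      flags = xt_second$flags))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(tsv_path, json_path))
}
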
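#' Classify a delta-Tm value against one assay's calling windows
#'
#' The calling statistic for a peak at temperature `tm_peak` on a probe with
#' wild-type temperature `tm_wt` is `delta_tm = tm_wt - tm_peak`. A value
#' within one degree of zero is the wild-type duplex; a value inside a
#' variant's calibrated window `delta_tm_v +/- halfwidth_v` is that variant's
#' mutant duplex; anything else is unassigned.
#'
#' @param delta_tm Numeric vector of observed delta-Tm values.
#' @param assay One panel assay (see [panel_assay()]).
#' @return Character vector: `"wt"`, a variant HGVS label, or
#'   `"unassigned"`.
#' @export
classify_delta_tm <- function(delta_tm, assay) {
  v <- assay$variants
  vapply(delta_tm, function(dt) {
    if (abs(dt) <= WT_HALFWIDTH) return("wt")
    hit <- which(dt >= v$delta_tm - v$window_halfwidth &
                 dt <= v$delta_tm + v$window_halfwidth)
    if (length(hit) == 1) v$hgvs[hit] else "unassigned"
  }, character(1))
}

#' Call one probe from its detected melt peaks
#'
#' Implements the interpretation rules of the assay: the wild-type peak alone
#' is wild type; wild-type plus one mutant peak is a heterozygote (a
#' heteroplasmic mixture on mitochondrial probes, with fraction estimated from
#' the peak-area ratio); a single mutant peak without the wild-type peak is a
#' homozygote (homoplasmic on mitochondrial probes); two mutant peaks of
#' different variants without a wild-type peak are two heterozygous calls
#' flagged as a presumed compound heterozygote; any unassigned peak, a
#' wild-type peak with two mutant peaks, or more than three peaks yields
#' status `ambiguous`; no peaks yields `no_signal`. Abnormalities are
#' reported through flags, never errors, mirroring a screening lab's manual
#' review queue.
#'
#' @param peaks A `melt_peaks` data frame from one curve of this assay.
#' @param assay The matching panel assay.
#' @return A list with `status` (`"wt"`, `"called"`, `"no_signal"`,
#'   `"ambiguous"`), `calls` (data frame `gene`, `hgvs`, `zygosity`,
#'   `heteroplasmy_fraction`, `delta_tm_observed`), and `flags` (character).
#' @export
call_probe <- function(peaks, assay) {
  is_mt <- any(assay$variants$inheritance == "mitochondrial")
  no_calls <- data.frame(gene = character(), hgvs = character(),
                         zygosity = character(),
                         heteroplasmy_fraction = numeric(),
                         delta_tm_observed = numeric())
  if (!nrow(peaks)) {
    return(list(status = "no_signal", calls = no_calls, flags = "no_peaks"))
  }
  dt <- assay$tm_wt - peaks$tm
  lab <- classify_delta_tm(dt, assay)
  flags <- character()
  if (any(lab == "unassigned") || nrow(peaks) > 3) {
    if (any(lab == "unassigned")) flags <- c(flags, "unassigned_peak")
    if (nrow(peaks) > 3) flags <- c(flags, "too_many_peaks")
    return(list(status = "ambiguous", calls = no_calls, flags = flags))
  }
  wt_i <- which(lab == "wt")
  mut_i <- which(lab != "wt")
  if (length(wt_i) > 1 || length(mut_i) > 2 ||
      (length(wt_i) == 1 && length(mut_i) == 2)) {
    return(list(status = "ambiguous", calls = no_calls,
                flags = "uninterpretable_peak_pattern"))
  }
  if (!length(mut_i)) {
    return(list(status = "wt", calls = no_calls, flags = character()))
  }
  mk_call <- function(i, zyg, frac = NA_real_) {
    j <- match(lab[i], assay$variants$hgvs)
    data.frame(gene = assay$variants$gene[j], hgvs = lab[i], zygosity = zyg,
               heteroplasmy_fraction = frac, delta_tm_observed = dt[i])
  }
  if (length(wt_i) == 1 && length(mut_i) == 1) {
    if (is_mt) {
      p <- estimate_heteroplasmy(peaks[wt_i, ], peaks[mut_i, ])
      if (is.na(p)) flags <- c(flags, "zero_total_area")
      calls <- mk_call(mut_i, "heteroplasmic", p)
    } else {
      calls <- mk_call(mut_i, "het")
    }
    return(list(status = "called", calls = calls, flags = flags))
  }
  if (!length(wt_i) && length(mut_i) == 1) {
    calls <- mk_call(mut_i, if (is_mt) "homoplasmic" else "hom")
    return(list(status = "called", calls = calls, flags = flags))
  }
  # two distinct mutant peaks, no wild type
  if (lab[mut_i[1]] == lab[mut_i[2]]) {
    return(list(status = "ambiguous", calls = no_calls,
                flags = "duplicate_variant_peaks"))
  }
  calls <- rbind(mk_call(mut_i[1], "het"), mk_call(mut_i[2], "het"))
  list(status = "called", calls = calls,
       flags = c(flags, "presumed_compound_het"))
}

#' Estimate mitochondrial heteroplasmy from peak areas
#'
#' `p = area_mut / (area_mut + area_wt)`: the fraction of mitochondrial
#' genomes carrying the variant, taking the melt-peak area of each duplex as
#' proportional to its template share. Area is preferred over height because
#' it is less sensitive to differences in transition steepness; a
#' height-based estimate is available via `statistic = "height"`.
#'
#' @param wt_peak,mut_peak Single rows of a `melt_peaks` data frame.
#' @param statistic `"area"` (default) or `"height"`.
#' @return The fraction in (0, 1), or `NA` if the total is not positive.
#' @export
estimate_heteroplasmy <- function(wt_peak, mut_peak, statistic = c("area", "height")) {
  statistic <- match.arg(statistic)
  a_wt <- wt_peak[[statistic]]
  a_mut <- mut_peak[[statistic]]
  tot <- a_wt + a_mut
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  a_mut / tot
}

#' Call a whole sample from its melt curves
#'
#' Runs the peak pipeline ([find_melt_peaks()]) and [call_probe()] on every
#' assay of the panel and aggregates the results. A variant detectable on one
#' probe only is callable iff that probe's curve is present; missing assays
#' are reported with status `no_data`.
#'
#' @param curves List of [melt_curve()] objects for one sample (at most one
#'   per assay; duplicates are an error).
#' @param panel An `mmca_panel`.
#' @param curve_params Named list of overrides passed to [find_melt_peaks()]
#'   (e.g. `smooth_window`, `min_prominence_frac`).
#' @return A list of class `genotype_set`: `sample_id`, `calls` (data frame
#'   with `reaction`, `channel` prepended to the [call_probe()] columns),
#'   `probe_status` (one row per assay: `reaction`, `channel`, `status`,
#'   `flags`).
#' @export
call_sample <- function(curves, panel, curve_params = list()) {
  key <- vapply(curves, function(cv) paste(cv$reaction, cv$channel), "")
  if (anyDuplicated(key)) {
    stop("duplicate curves for assay(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  sample_id <- if (length(curves)) curves[[1]]$sample_id else NA_character_
  status_rows <- list()
  call_rows <- list()
  for (a in panel$assays) {
    k <- paste(a$reaction, a$channel)
    i <- match(k, key)
    if (is.na(i)) {
      status_rows[[k]] <- data.frame(reaction = a$reaction, channel = a$channel,
                                     status = "no_data", flags = "missing_curve")
      next
    }
    pk <- do.call(find_melt_peaks, c(list(curves[[i]]), curve_params))
    res <- call_probe(pk, a)
    status_rows[[k]] <- data.frame(
      reaction = a$reaction, channel = a$channel, status = res$status,
      flags = paste(res$flags, collapse = ";"))
    if (nrow(res$calls)) {
      call_rows[[k]] <- cbind(
        data.frame(reaction = a$reaction, channel = a$channel),
        res$calls)
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(reaction = character(), channel = character(),
               gene = character(), hgvs = character(), zygosity = character(),
               heteroplasmy_fraction = numeric(),
               delta_tm_observed = numeric())
  rownames(calls) <- NULL
  ps <- do.call(rbind, status_rows)
  rownames(ps) <- NULL
  structure(list(sample_id = sample_id, calls = calls, probe_status = ps),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set for sample ", x$sample_id, ": ", nrow(x$calls),
      " call(s)\n", sep = "")
  if (nrow(x$calls)) print(x$calls[, c("hgvs", "zygosity", "delta_tm_observed")])
  amb <- x$probe_status$status %in% c("ambiguous", "no_data", "no_signal")
  if (any(amb)) {
    cat("probes needing review:\n")
    print(x$probe_status[amb, ])
  }
  invisible(x)
}
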
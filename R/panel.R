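#' Load a multiplex melt-panel configuration
#'
#' Reads a JSON panel file describing the probe layout of a multiplex
#' melting-curve assay: one entry per (reaction, fluorescence channel) pair,
#' each carrying the wild-type probe melting temperature `tm_wt_c` and the
#' calibrated variant windows. A variant window is the interval
#' `delta_tm_c +/- window_halfwidth_c` on the delta-Tm axis, where
#' `delta_tm = Tm(wild-type) - Tm(mutant)`; the half-widths are three standard
#' deviations of the calibration replicates. A negative `delta_tm_c` means the
#' mutant duplex melts above the wild type.
#'
#' The shipped default panel (`system.file("extdata", "panel_hl20.json",
#' package = "mmcascreen")`) encodes a 20-variant newborn hearing-loss panel
#' over four PCR reactions: reaction A carries the GJB2 and GJB3 probes,
#' reactions B and C the SLC26A4 probes, and reaction D the two mitochondrial
#' MT-RNR1 probes. Absolute wild-type Tm values are instrument-specific and
#' not part of the calibration; the shipped values are plausible probe Tms
#' spaced so that the two probes sharing the ROX dye in reaction A occupy
#' disjoint temperature ranges.
#'
#' @param path Path to a panel JSON file. Defaults to the shipped panel.
#' @return An object of class `mmca_panel`: a list with `schema_version` and
#'   `assays`, each assay a list with `reaction`, `channel`, `tm_wt`, and a
#'   `variants` data frame (`gene`, `hgvs`, `dbsnp`, `acmg_class`,
#'   `inheritance`, `delta_tm`, `window_halfwidth`).
#' @export
load_panel <- function(path = default_panel_path()) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$schema_version) || is.null(raw$assays)) {
    stop("panel configuration error: top-level 'schema_version' and 'assays' required",
         call. = FALSE)
  }
  assays <- lapply(raw$assays, function(a) {
    for (fld in c("reaction", "channel", "tm_wt_c", "variants")) {
      if (is.null(a[[fld]])) {
        stop(sprintf("panel configuration error in assay %s/%s: missing field '%s'",
                     a$reaction %||% "?", a$channel %||% "?", fld), call. = FALSE)
      }
    }
    vdf <- do.call(rbind, lapply(a$variants, function(v) {
      for (fld in c("gene", "hgvs", "inheritance", "delta_tm_c", "window_halfwidth_c")) {
        if (is.null(v[[fld]])) {
          stop(sprintf("panel configuration error in assay %s/%s: variant missing field '%s'",
                       a$reaction, a$channel, fld), call. = FALSE)
        }
      }
      data.frame(
        gene = v$gene,
        hgvs = v$hgvs,
        dbsnp = if (is.null(v$dbsnp)) NA_character_ else v$dbsnp,
        acmg_class = if (is.null(v$acmg_class)) NA_character_ else v$acmg_class,
        inheritance = v$inheritance,
        delta_tm = as.numeric(v$delta_tm_c),
        window_halfwidth = as.numeric(v$window_halfwidth_c),
        stringsAsFactors = FALSE
      )
    }))
    list(reaction = a$reaction, channel = a$channel,
         tm_wt = as.numeric(a$tm_wt_c), variants = vdf)
  })
  panel <- structure(
    list(schema_version = raw$schema_version, assays = assays),
    class = "mmca_panel"
  )
  validate_panel(panel)
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_panel
#' @export
default_panel_path <- function() {
  system.file("extdata", "panel_hl20.json", package = "mmcascreen", mustWork = TRUE)
}

#' Write a panel configuration back to JSON
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p, f))` reproduces `p`
#' field for field.
#'
#' @param panel An `mmca_panel` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mmca_panel"))
  out <- list(
    schema_version = panel$schema_version,
    assays = lapply(panel$assays, function(a) {
      list(
        reaction = a$reaction, channel = a$channel, tm_wt_c = a$tm_wt,
        variants = lapply(seq_len(nrow(a$variants)), function(i) {
          v <- a$variants[i, ]
          list(gene = v$gene, hgvs = v$hgvs,
               dbsnp = if (is.na(v$dbsnp)) NULL else v$dbsnp,
               acmg_class = if (is.na(v$acmg_class)) NULL else v$acmg_class,
               inheritance = v$inheritance,
               delta_tm_c = v$delta_tm, window_halfwidth_c = v$window_halfwidth)
        })
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Wild-type pseudo-window on the delta-Tm axis: a peak within +/- 1 degree of
# the wild-type Tm is the wild-type duplex, so calibrated windows must stay
# clear of [-1, 1].
WT_HALFWIDTH <- 1.0

#' Validate a panel configuration
#'
#' Checks the structural invariants a callable panel must satisfy:
#' half-widths positive, `|delta_tm| > 1` (a difference within one degree of
#' the wild type is not a usable calling signal), variant windows on one probe
#' pairwise disjoint and excluding the wild-type pseudo-window, variant names
#' unique across the panel, mitochondrial inheritance if and only if the gene
#' is MT_RNR1, and probes sharing a dye in one reaction (ROX vs ROX2)
#' occupying disjoint absolute temperature ranges.
#'
#' @param panel An `mmca_panel` object.
#' @param guard_band Minimum separation, in degrees Celsius, between the total
#'   Tm ranges of two probes sharing a dye in one reaction.
#' @return `panel`, invisibly. Throws a validation error otherwise.
#' @export
validate_panel <- function(panel, guard_band = 2.0) {
  stopifnot(inherits(panel, "mmca_panel"))
  all_v <- panel_variants(panel)
  if (anyDuplicated(all_v$hgvs)) {
    stop("panel validation error: duplicated variant name(s): ",
         paste(unique(all_v$hgvs[duplicated(all_v$hgvs)]), collapse = ", "),
         call. = FALSE)
  }
  bad_inh <- (all_v$gene == "MT_RNR1") != (all_v$inheritance == "mitochondrial")
  if (any(bad_inh)) {
    stop("panel validation error: inheritance class inconsistent with gene for: ",
         paste(all_v$hgvs[bad_inh], collapse = ", "), call. = FALSE)
  }
  for (a in panel$assays) {
    v <- a$variants
    lab <- paste0(a$reaction, "/", a$channel)
    if (any(v$window_halfwidth <= 0)) {
      stop("panel validation error in assay ", lab,
           ": window_halfwidth must be > 0", call. = FALSE)
    }
    if (any(abs(v$delta_tm) <= WT_HALFWIDTH)) {
      stop("panel validation error in assay ", lab,
           ": |delta_tm| must exceed the wild-type pseudo-window (1 degree) for: ",
           paste(v$hgvs[abs(v$delta_tm) <= WT_HALFWIDTH], collapse = ", "),
           call. = FALSE)
    }
    lo <- v$delta_tm - v$window_halfwidth
    hi <- v$delta_tm + v$window_halfwidth
    if (any(lo <= WT_HALFWIDTH & hi >= -WT_HALFWIDTH)) {
      bad <- which(lo <= WT_HALFWIDTH & hi >= -WT_HALFWIDTH)
      stop("panel validation error in assay ", lab,
           ": calling window overlaps the wild-type pseudo-window for: ",
           paste(v$hgvs[bad], collapse = ", "), call. = FALSE)
    }
    if (nrow(v) > 1) {
      ord <- order(v$delta_tm)
      lo_s <- lo[ord]; hi_s <- hi[ord]
      for (i in seq_len(nrow(v) - 1)) {
        if (hi_s[i] >= lo_s[i + 1]) {
          stop("panel validation error in assay ", lab,
               ": overlapping calling windows for variant pair ",
               v$hgvs[ord][i], " and ", v$hgvs[ord][i + 1], call. = FALSE)
        }
      }
    }
  }
  # shared-dye probes in one reaction must occupy disjoint absolute Tm ranges
  base_dye <- function(ch) sub("[-_ ]?2$", "", ch)
  rx <- vapply(panel$assays, function(a) a$reaction, "")
  dye <- vapply(panel$assays, function(a) base_dye(a$channel), "")
  key <- paste(rx, dye)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    rng <- t(vapply(panel$assays[idx], function(a) {
      ext <- c(0, -a$variants$delta_tm - a$variants$window_halfwidth,
               -a$variants$delta_tm + a$variants$window_halfwidth,
               -WT_HALFWIDTH, WT_HALFWIDTH)
      a$tm_wt + range(ext)
    }, numeric(2)))
    ord <- order(rng[, 1])
    rng <- rng[ord, , drop = FALSE]
    for (i in seq_len(nrow(rng) - 1)) {
      if (rng[i, 2] + guard_band > rng[i + 1, 1]) {
        stop("panel validation error: probes sharing dye in reaction ",
             panel$assays[[idx[1]]]$reaction,
             " have overlapping total Tm ranges (guard band ", guard_band,
             " degrees)", call. = FALSE)
      }
    }
  }
  invisible(panel)
}

#' Flatten a panel to one row per variant
#'
#' @param panel An `mmca_panel` object.
#' @return A data frame with one row per panel variant and columns `reaction`,
#'   `channel`, `tm_wt`, `gene`, `hgvs`, `dbsnp`, `acmg_class`, `inheritance`,
#'   `delta_tm`, `window_halfwidth`.
#' @export
panel_variants <- function(panel) {
  stopifnot(inherits(panel, "mmca_panel"))
  do.call(rbind, lapply(panel$assays, function(a) {
    cbind(
      data.frame(reaction = a$reaction, channel = a$channel, tm_wt = a$tm_wt,
                 stringsAsFactors = FALSE)[rep(1, nrow(a$variants)), , drop = FALSE],
      a$variants,
      row.names = NULL
    )
  }))
}

#' Look up one assay of a panel
#'
#' @param panel An `mmca_panel` object.
#' @param reaction Reaction identifier (e.g. `"A"`).
#' @param channel Dye label (e.g. `"FAM"`).
#' @return The assay list, or an error if the pair is not in the panel.
#' @export
panel_assay <- function(panel, reaction, channel) {
  for (a in panel$assays) {
    if (identical(a$reaction, reaction) && identical(a$channel, channel)) return(a)
  }
  stop("no assay for reaction ", reaction, ", channel ", channel,
       " in this panel", call. = FALSE)
}

#' Separability report for a panel
#'
#' For each probe, computes the minimum gap between adjacent calling-window
#' edges on the delta-Tm axis, including the wild-type pseudo-window
#' `[-1, 1]`. A panel is only usable when every gap is positive; this report
#' makes the margin explicit and flags probes whose tightest gap falls below
#' `min_gap`.
#'
#' @param panel An `mmca_panel` object.
#' @param min_gap Gap threshold in degrees Celsius below which a probe is
#'   flagged.
#' @return A data frame with one row per assay: `reaction`, `channel`,
#'   `n_variants`, `min_gap` (degrees), and logical `pass`.
#' @export
validate_separability <- function(panel, min_gap = 0.5) {
  stopifnot(inherits(panel, "mmca_panel"))
  rows <- lapply(panel$assays, function(a) {
    v <- a$variants
    lo <- c(-WT_HALFWIDTH, v$delta_tm - v$window_halfwidth)
    hi <- c(WT_HALFWIDTH, v$delta_tm + v$window_halfwidth)
    ord <- order(lo)
    gaps <- lo[ord][-1] - hi[ord][-length(hi)]
    data.frame(reaction = a$reaction, channel = a$channel,
               n_variants = nrow(v), min_gap = min(gaps),
               pass = min(gaps) >= min_gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.mmca_panel <- function(x, ...) {
  nv <- nrow(panel_variants(x))
  cat("mmca_panel (schema ", x$schema_version, "): ",
      length(x$assays), " assays, ", nv, " variants\n", sep = "")
  for (a in x$assays) {
    cat(sprintf("  %s/%-4s tm_wt %.2f: %s\n", a$reaction, a$channel, a$tm_wt,
                paste(a$variants$hgvs, collapse = ", ")))
  }
  invisible(x)
}
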
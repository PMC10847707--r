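#' Genetic screening category of a genotype
#'
#' Screening results are categorised as `negative` (no variant call),
#' `carrier` (heterozygous or cross-gene compound findings, including any
#' mitochondrial call: mitochondrial variants are never biallelic in the
#' autosomal sense), or `refer` (a homozygote or two variant alleles in the
#' same autosomal gene, i.e. a presumed biallelic genotype of GJB2, SLC26A4
#' or GJB3 warranting diagnostic work-up). A genotype set containing an
#' ambiguous probe cannot be categorised and yields `review_required`.
#'
#' @param g A `genotype_set` from [call_sample()], or a plain calls data
#'   frame with columns `gene`, `hgvs`, `zygosity`.
#' @return One of `"negative"`, `"carrier"`, `"refer"`, `"review_required"`.
#' @export
categorize_genetics <- function(g) {
  if (inherits(g, "genotype_set")) {
    if (any(g$probe_status$status == "ambiguous")) return("review_required")
    calls <- g$calls
  } else {
    calls <- g
  }
  if (!nrow(calls)) return("negative")
  autosomal <- calls[!calls$zygosity %in% c("heteroplasmic", "homoplasmic") &
                     calls$gene != "MT_RNR1", , drop = FALSE]
  if (any(autosomal$zygosity == "hom")) return("refer")
  het_genes <- autosomal$gene[autosomal$zygosity == "het"]
  if (any(table(het_genes) >= 2)) return("refer")
  "carrier"
}

#' Severity bin of a hearing-loss threshold
#'
#' Bins a diagnostic hearing threshold into mild (26-40 dB), moderate
#' (41-60 dB), severe (61-80 dB) or profound (>= 81 dB); the printed 80-81 dB
#' gap in the source bins is closed at >= 81 profound. Thresholds of 25 dB or
#' below are not hearing loss and raise an error.
#'
#' @param threshold_db Hearing threshold in dB.
#' @return One of `"mild"`, `"moderate"`, `"severe"`, `"profound"`.
#' @export
classify_severity <- function(threshold_db) {
  vapply(threshold_db, function(x) {
    if (is.na(x) || x <= 25) {
      stop("threshold ", x, " dB is not hearing loss (must exceed 25 dB)",
           call. = FALSE)
    }
    if (x <= 40) "mild" else if (x <= 60) "moderate" else if (x <= 80) "severe"
    else "profound"
  }, character(1))
}

#' Hearing-screening trajectory
#'
#' Records one neonate's path through the two-stage hearing screen and
#' optional diagnosis: initial otoacoustic-emission screen at 24-48 h, second
#' automated auditory-brainstem-response screen at 42 days (taken by all
#' neonates regardless of the initial result), and a diagnostic work-up at
#' 3-6 months for rescreen failures. `late_diagnosis` marks a diagnosis made
#' outside the rescreen-failure route.
#'
#' @param initial_oae `"pass"`, `"refer"`, or `NA` (not yet done).
#' @param second_aabr `"pass"`, `"refer"`, or `"not_done"`.
#' @param diagnosis `NULL`, or a list with `threshold_db`, `laterality`
#'   (`"unilateral"`/`"bilateral"`), `age_months`; `severity` is derived.
#' @param late_diagnosis Logical flag for diagnoses outside the standard
#'   referral route.
#' @return A list of class `hearing_trajectory`.
#' @export
hearing_trajectory <- function(initial_oae = NA_character_,
                               second_aabr = "not_done", diagnosis = NULL,
                               late_diagnosis = FALSE) {
  if (!is.na(initial_oae)) stopifnot(initial_oae %in% c("pass", "refer"))
  stopifnot(second_aabr %in% c("pass", "refer", "not_done"))
  if (!is.null(diagnosis)) {
    stopifnot(!is.null(diagnosis$threshold_db), !is.null(diagnosis$laterality))
    diagnosis$severity <- classify_severity(diagnosis$threshold_db)
    if (!identical(second_aabr, "refer") && !late_diagnosis) {
      stop("a diagnosis requires a failed second screen or an explicit ",
           "late-diagnosis flag", call. = FALSE)
    }
  }
  structure(list(initial_oae = initial_oae, second_aabr = second_aabr,
                 diagnosis = diagnosis, late_diagnosis = late_diagnosis),
            class = "hearing_trajectory")
}

#' Advance a hearing trajectory by one event
#'
#' The legal order is initial screen, second screen (taken by all neonates),
#' then diagnosis (only reachable after a failed second screen, unless the
#' event carries `late = TRUE`). Out-of-order events are state errors.
#'
#' @param state A [hearing_trajectory()].
#' @param event A list with `stage` (`"initial"`, `"second"`, `"diagnosis"`)
#'   and stage-specific fields: `result` (`"pass"`/`"refer"`) for screens;
#'   `threshold_db`, `laterality`, `age_months`, optional `late` for a
#'   diagnosis.
#' @return The updated trajectory.
#' @export
advance_hearing <- function(state, event) {
  stopifnot(inherits(state, "hearing_trajectory"))
  stage <- event$stage
  if (identical(stage, "initial")) {
    if (!is.na(state$initial_oae)) {
      stop("initial screen already recorded", call. = FALSE)
    }
    stopifnot(event$result %in% c("pass", "refer"))
    state$initial_oae <- event$result
  } else if (identical(stage, "second")) {
    if (is.na(state$initial_oae)) {
      stop("second screen before initial screen", call. = FALSE)
    }
    if (state$second_aabr != "not_done") {
      stop("second screen already recorded", call. = FALSE)
    }
    stopifnot(event$result %in% c("pass", "refer"))
    state$second_aabr <- event$result
  } else if (identical(stage, "diagnosis")) {
    late <- isTRUE(event$late)
    if (state$second_aabr == "not_done") {
      stop("diagnosis before second screen", call. = FALSE)
    }
    if (state$second_aabr != "refer" && !late) {
      stop("diagnosis is only scheduled after a failed second screen",
           call. = FALSE)
    }
    state$late_diagnosis <- late
    state$diagnosis <- list(threshold_db = event$threshold_db,
                            severity = classify_severity(event$threshold_db),
                            laterality = event$laterality,
                            age_months = event$age_months)
  } else {
    stop("unknown event stage: ", stage, call. = FALSE)
  }
  state
}

#' Follow-up recommendations for one neonate
#'
#' Deterministic rule list combining the genetic category, the individual
#' calls and the hearing outcome:
#' any mitochondrial call adds `AVOID_AMINOGLYCOSIDES` and
#' `MATERNAL_LINEAGE_COUNSELING`; a GJB2 or SLC26A4 heterozygote adds
#' `HEARING_FOLLOWUP_DELAYED_ONSET`; a GJB3 heterozygote who passed hearing
#' screening adds `ROUTINE_FOLLOWUP`; category `refer` adds
#' `DIAGNOSTIC_AUDIOLOGY_REFERRAL` and `FAMILY_GENETIC_DIAGNOSIS`; a
#' diagnosed hearing loss adds `FAMILY_GENETIC_DIAGNOSIS`. The result is
#' sorted and unique, hence idempotent and independent of call order.
#'
#' @param calls Calls data frame (columns `gene`, `zygosity`).
#' @param category Genetic category from [categorize_genetics()].
#' @param hearing A [hearing_trajectory()], or `NULL`.
#' @return Sorted character vector of recommendation codes.
#' @export
recommend <- function(calls, category, hearing = NULL) {
  rec <- character()
  if (nrow(calls)) {
    if (any(calls$gene == "MT_RNR1")) {
      rec <- c(rec, "AVOID_AMINOGLYCOSIDES", "MATERNAL_LINEAGE_COUNSELING")
    }
    het_auto <- calls$zygosity == "het"
    if (any(het_auto & calls$gene %in% c("GJB2", "SLC26A4"))) {
      rec <- c(rec, "HEARING_FOLLOWUP_DELAYED_ONSET")
    }
    passed <- !is.null(hearing) && identical(hearing$second_aabr, "pass") &&
      is.null(hearing$diagnosis)
    if (any(het_auto & calls$gene == "GJB3") && passed) {
      rec <- c(rec, "ROUTINE_FOLLOWUP")
    }
  }
  if (identical(category, "refer")) {
    rec <- c(rec, "DIAGNOSTIC_AUDIOLOGY_REFERRAL", "FAMILY_GENETIC_DIAGNOSIS")
  }
  if (!is.null(hearing) && !is.null(hearing$diagnosis)) {
    rec <- c(rec, "FAMILY_GENETIC_DIAGNOSIS")
  }
  sort(unique(rec))
}
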
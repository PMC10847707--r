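#' Construct a cohort specification
#'
#' A cohort specification describes a screening cohort by marginal counts: one
#' row per genotype group (a variant or variant pair at a given zygosity) with
#' joint hearing-outcome counts, the hearing-outcome cell counts of the
#' genetics-negative remainder, and a table of diagnosed cases tied to
#' specific group/outcome cells. [generate_cohort()] materialises it into
#' per-neonate records whose re-aggregated margins reproduce the
#' specification exactly.
#'
#' Hearing-outcome cells are `ip_sp`, `ip_sr`, `ir_sp`, `ir_sr`: initial
#' screen pass/refer crossed with second screen pass/refer.
#'
#' @param groups Data frame with columns `variants` (HGVS labels, `/`
#'   separated for multi-variant carriers), `zygosity` (matching labels,
#'   `het`, `hom` or `mt`, `/` separated), `n`, `ip_sp`, `ip_sr`, `ir_sp`,
#'   `ir_sr`.
#' @param negatives Named list or vector with `ip_sp`, `ip_sr`, `ir_sp`,
#'   `ir_sr` counts for genetics-negative neonates.
#' @param diagnoses Data frame with columns `subject`, `group` (a
#'   `variants:zygosity` key, or `"negative"`), `route` (`"ip_sr"` or
#'   `"ir_sr"`), `sex`, `age_months`, `threshold_db`, `laterality`,
#'   `treatment`, `ototoxic`.
#' @param seed Integer seed used for the stochastic parts of cohort
#'   materialisation (mitochondrial heteroplasmy fractions).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, negatives, diagnoses = NULL, seed = 1L) {
  groups <- as.data.frame(groups)
  need <- c("variants", "zygosity", "n", "ip_sp", "ip_sr", "ir_sp", "ir_sr")
  if (!all(need %in% names(groups))) {
    stop("cohort spec groups must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cells <- c("ip_sp", "ip_sr", "ir_sp", "ir_sr")
  bad <- which(groups$n != rowSums(groups[, cells]))
  if (length(bad)) {
    stop("cohort spec validation error: hearing cells do not sum to n for group '",
         groups$variants[bad[1]], ":", groups$zygosity[bad[1]], "'",
         call. = FALSE)
  }
  negatives <- as.list(negatives)
  if (!all(cells %in% names(negatives))) {
    stop("cohort spec negatives must supply ", paste(cells, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(subject = integer(), group = character(),
                            route = character(), sex = character(),
                            age_months = numeric(), threshold_db = numeric(),
                            laterality = character(), treatment = integer(),
                            ototoxic = logical())
  }
  key <- paste(groups$variants, groups$zygosity, sep = ":")
  if (anyDuplicated(key)) {
    stop("cohort spec validation error: duplicated group '",
         key[duplicated(key)][1], "'", call. = FALSE)
  }
  for (i in seq_len(nrow(diagnoses))) {
    d <- diagnoses[i, ]
    if (!d$route %in% c("ip_sr", "ir_sr")) {
      stop("diagnosis route must be a second-screen-refer cell; got '",
           d$route, "' for subject ", d$subject, call. = FALSE)
    }
    avail <- if (identical(d$group, "negative")) negatives[[d$route]] else {
      j <- match(d$group, key)
      if (is.na(j)) {
        stop("cohort spec validation error: diagnosis subject ", d$subject,
             " references unknown group '", d$group, "'", call. = FALSE)
      }
      groups[[d$route]][j]
    }
    n_in_cell <- sum(diagnoses$group == d$group & diagnoses$route == d$route)
    if (n_in_cell > avail) {
      stop("cohort spec validation error: more diagnoses than neonates in cell ",
           d$group, "/", d$route, call. = FALSE)
    }
  }
  n_total <- sum(groups$n) + sum(unlist(negatives[cells]))
  structure(list(groups = groups, negatives = negatives,
                 diagnoses = diagnoses, n_total = n_total, seed = seed),
            class = "cohort_spec")
}

#' The packaged screening-cohort fixture
#'
#' Reconstructs the study cohort of 2488 neonates as a [cohort_spec()]: 170
#' neonates with at least one panel variant (each variant/zygosity group with
#' its initial and second hearing-screen outcomes), 11 diagnosed hearing-loss
#' cases with severity, laterality, age and treatment, 144 initial-screen
#' referrals, 32 second-screen failures of whom 7 passed the initial screen,
#' and one diagnosed, genetics-negative neonate with an ototoxic-drug
#' history.
#'
#' Two reconciliation records are appended beyond the printed per-group
#' rows - one c.235delC and one c.919-2A>G heterozygote, both passing all
#' screens - because the per-variant carrier totals (58 and 39) and the
#' cohort-wide positive count (170) each exceed the per-group accounting by
#' exactly one for these two variants.
#'
#' @param seed Seed stored in the spec (drives heteroplasmy draws during
#'   materialisation).
#' @return A [cohort_spec()].
#' @export
fixture_cohort_spec <- function(seed = 20220101L) {
  g <- function(variants, zygosity, ip_sp = 0, ip_sr = 0, ir_sp = 0, ir_sr = 0) {
    data.frame(variants = variants, zygosity = zygosity,
               n = ip_sp + ip_sr + ir_sp + ir_sr,
               ip_sp = ip_sp, ip_sr = ip_sr, ir_sp = ir_sp, ir_sr = ir_sr,
               stringsAsFactors = FALSE)
  }
  groups <- rbind(
    g("c.35delG", "het", ip_sp = 4, ir_sp = 1),
    g("c.176_191del16", "het", ip_sp = 5, ir_sr = 1),
    g("c.235delC", "het", ip_sp = 50, ir_sp = 2, ir_sr = 2),
    g("c.235delC", "hom", ir_sr = 1),
    g("c.235delC/c.176_191del16", "het/het", ip_sr = 1),
    g("c.299_300delAT", "het", ip_sp = 12, ir_sp = 1),
    g("c.538C>T", "het", ip_sp = 9),
    g("c.547G>A", "het", ip_sp = 4),
    g("m.1494C>T", "mt", ip_sp = 1),
    g("m.1555A>G", "mt", ip_sp = 9),
    g("c.919-2A>G", "het", ip_sp = 34, ir_sr = 2),
    g("c.1174A>T", "het", ip_sp = 2),
    g("c.1226G>A", "het", ip_sp = 1),
    g("c.1226G>A", "hom", ip_sr = 1, ir_sr = 1),
    g("c.1229C>T", "het", ip_sp = 4, ir_sp = 1),
    g("c.1707+5G>A", "het", ip_sp = 4),
    g("c.2168A>G", "het", ip_sp = 7, ir_sp = 1),
    g("c.2027T>A", "het", ip_sp = 2),
    g("c.2162C>T", "het", ip_sp = 2),
    g("c.754T>C", "het", ip_sp = 1),
    g("c.176_191del16/c.919-2A>G", "het/het", ip_sp = 1),
    g("c.235delC/c.919-2A>G", "het/het", ir_sp = 1),
    g("c.235delC/c.754T>C", "het/het", ip_sp = 1),
    g("c.299_300delAT/c.919-2A>G", "het/het", ip_sp = 1)
  )
  # genetics-negative remainder: 2318 neonates, 130 initial referrals,
  # 23 second-screen failures of whom 5 passed the initial screen
  negatives <- list(ip_sp = 2183, ip_sr = 5, ir_sp = 112, ir_sr = 18)
  d <- function(subject, group, route, sex, age, thr, lat, treat, oto = FALSE) {
    data.frame(subject = subject, group = group, route = route, sex = sex,
               age_months = age, threshold_db = thr, laterality = lat,
               treatment = treat, ototoxic = oto, stringsAsFactors = FALSE)
  }
  diagnoses <- rbind(
    d(1, "c.235delC/c.176_191del16:het/het", "ip_sr", "male", 11, 75, "bilateral", 2),
    d(2, "c.235delC:het", "ir_sr", "female", 9, 75, "bilateral", 2),
    d(3, "negative", "ir_sr", "female", 9, 50, "unilateral", 3),
    d(4, "c.919-2A>G:het", "ir_sr", "male", 7, 70, "unilateral", 3),
    d(5, "negative", "ip_sr", "female", 12, 50, "bilateral", 2, oto = TRUE),
    d(6, "negative", "ir_sr", "female", 7, 70, "unilateral", 3),
    d(7, "negative", "ir_sr", "male", 8, 50, "unilateral", 3),
    d(8, "c.1226G>A:hom", "ip_sr", "male", 10, 90, "bilateral", 1),
    d(9, "c.235delC:hom", "ir_sr", "male", 6, 90, "bilateral", 1),
    d(10, "c.1226G>A:hom", "ir_sr", "female", 7, 50, "bilateral", 3),
    d(11, "c.176_191del16:het", "ir_sr", "male", 6, 50, "unilateral", 3)
  )
  cohort_spec(groups, negatives, diagnoses, seed = seed)
}

# split "a/b" and "het/het" group labels into per-variant (hgvs, zygosity) pairs
split_group <- function(variants, zygosity) {
  v <- strsplit(variants, "/", fixed = TRUE)[[1]]
  z <- strsplit(zygosity, "/", fixed = TRUE)[[1]]
  if (length(z) == 1 && length(v) > 1) z <- rep(z, length(v))
  if (length(v) != length(z)) {
    stop("group '", variants, ":", zygosity, "' has mismatched variant and ",
         "zygosity counts", call. = FALSE)
  }
  data.frame(hgvs = v, zygosity = z, stringsAsFactors = FALSE)
}

#' Materialise a cohort specification into per-neonate records
#'
#' Expands the marginal counts of a [cohort_spec()] into one record per
#' neonate with its genotype calls, hearing trajectory and (where specified)
#' diagnosis. Mitochondrial carriers receive a seeded heteroplasmy fraction
#' drawn uniformly from 0.2-0.8 (the study reports all mitochondrial cases as
#' heteroplasmic without printing fractions). Re-aggregating the records
#' reproduces every specification margin exactly.
#'
#' @param spec A [cohort_spec()].
#' @param panel An `mmca_panel`; variant labels in the spec must exist in the
#'   panel (gene assignment is taken from it).
#' @param params A [melt_sim_params()], used only when `emit_curves = TRUE`.
#' @param emit_curves If `TRUE`, also simulate the raw melt curves of every
#'   neonate (all panel assays); intended for small cohorts in end-to-end
#'   caller tests.
#' @param seed Overrides the seed stored in the spec.
#' @return A list of class `cohort_table`: `neonates` (one row per neonate:
#'   `id`, `initial_oae`, `second_aabr`, `diagnosed`, `threshold_db`,
#'   `severity`, `laterality`, `age_months`, `late_diagnosis`, `sex`,
#'   `treatment`, `ototoxic_history`, `genetic_category`), `calls` (one row
#'   per variant call: `id`, `gene`, `hgvs`, `zygosity`,
#'   `heteroplasmy_fraction`), `n_total`, and optionally `curves` (a list
#'   keyed by neonate id).
#' @export
generate_cohort <- function(spec, panel = load_panel(),
                            params = melt_sim_params(),
                            emit_curves = FALSE, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  pv <- panel_variants(panel)
  seed <- if (is.null(seed)) spec$seed else seed
  set.seed(seed)
  cells <- c("ip_sp", "ip_sr", "ir_sp", "ir_sr")
  cell_outcome <- list(ip_sp = c("pass", "pass"), ip_sr = c("pass", "refer"),
                       ir_sp = c("refer", "pass"), ir_sr = c("refer", "refer"))
  key <- paste(spec$groups$variants, spec$groups$zygosity, sep = ":")

  neonate_rows <- list()
  call_rows <- list()
  nid <- 0L
  diag_used <- rep(FALSE, nrow(spec$diagnoses))

  emit <- function(group_key, members, cell) {
    nid <<- nid + 1L
    id <- sprintf("N%04d", nid)
    oc <- cell_outcome[[cell]]
    di <- which(!diag_used & spec$diagnoses$group == group_key &
                spec$diagnoses$route == cell)
    diag <- NULL
    if (length(di)) {
      di <- di[1]
      diag_used[di] <<- TRUE
      diag <- spec$diagnoses[di, ]
    }
    neonate_rows[[id]] <<- data.frame(
      id = id, initial_oae = oc[1], second_aabr = oc[2],
      diagnosed = !is.null(diag),
      threshold_db = if (is.null(diag)) NA_real_ else diag$threshold_db,
      severity = if (is.null(diag)) NA_character_ else
        classify_severity(diag$threshold_db),
      laterality = if (is.null(diag)) NA_character_ else diag$laterality,
      age_months = if (is.null(diag)) NA_real_ else diag$age_months,
      late_diagnosis = FALSE,
      sex = if (is.null(diag)) NA_character_ else diag$sex,
      treatment = if (is.null(diag)) NA_integer_ else diag$treatment,
      ototoxic_history = if (is.null(diag)) FALSE else isTRUE(diag$ototoxic),
      stringsAsFactors = FALSE)
    if (!is.null(members) && nrow(members)) {
      frac <- ifelse(members$zygosity == "mt",
                     stats::runif(nrow(members), 0.2, 0.8), NA_real_)
      call_rows[[id]] <<- data.frame(
        id = id, gene = pv$gene[match(members$hgvs, pv$hgvs)],
        hgvs = members$hgvs,
        zygosity = ifelse(members$zygosity == "mt", "heteroplasmic",
                          members$zygosity),
        heteroplasmy_fraction = frac, stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(nrow(spec$groups))) {
    members <- split_group(spec$groups$variants[i], spec$groups$zygosity[i])
    if (anyNA(match(members$hgvs, pv$hgvs))) {
      stop("cohort spec references variant(s) not in the panel: ",
           paste(setdiff(members$hgvs, pv$hgvs), collapse = ", "),
           call. = FALSE)
    }
    for (cell in cells) {
      for (r in seq_len(spec$groups[[cell]][i])) emit(key[i], members, cell)
    }
  }
  for (cell in cells) {
    for (r in seq_len(spec$negatives[[cell]])) emit("negative", NULL, cell)
  }
  if (!all(diag_used)) {
    stop("internal error: diagnosis subjects ",
         paste(spec$diagnoses$subject[!diag_used], collapse = ", "),
         " could not be placed", call. = FALSE)
  }

  neonates <- do.call(rbind, neonate_rows)
  rownames(neonates) <- NULL
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(id = character(), gene = character(), hgvs = character(),
               zygosity = character(), heteroplasmy_fraction = numeric())
  rownames(calls) <- NULL
  neonates$genetic_category <- vapply(neonates$id, function(id) {
    categorize_genetics(calls[calls$id == id, , drop = FALSE])
  }, character(1))

  out <- structure(list(neonates = neonates, calls = calls,
                        n_total = nrow(neonates), seed = seed),
                   class = "cohort_table")
  if (emit_curves) {
    out$curves <- lapply(seq_len(nrow(neonates)), function(i) {
      id <- neonates$id[i]
      cc <- calls[calls$id == id, , drop = FALSE]
      gt <- calls_to_genotype(cc)
      p <- params
      p$seed <- (seed + i) %% .Machine$integer.max
      simulate_sample(panel, gt, p, sample_id = id)
    })
    names(out$curves) <- neonates$id
  }
  out
}

#' Convert one neonate's cohort calls to a simulatable genotype
#'
#' @param calls Rows of a `cohort_table` calls data frame for one neonate
#'   (columns `hgvs`, `zygosity`, `heteroplasmy_fraction`).
#' @return A [sample_genotype()].
#' @export
calls_to_genotype <- function(calls) {
  mt <- calls$zygosity %in% c("heteroplasmic", "homoplasmic")
  mtv <- calls$heteroplasmy_fraction[mt]
  mtv[calls$zygosity[mt] == "homoplasmic"] <- 1
  names(mtv) <- calls$hgvs[mt]
  sample_genotype(het = calls$hgvs[calls$zygosity == "het"],
                  hom = calls$hgvs[calls$zygosity == "hom"],
                  mt = mtv)
}

#' Re-aggregate a cohort into specification-style margins
#'
#' Inverse of [generate_cohort()]: collapses per-neonate records back to one
#' row per genotype group with joint hearing-outcome counts, for checking
#' that materialisation is a bijection on the margins.
#'
#' @param cohort A `cohort_table`.
#' @return A data frame with columns `variants`, `zygosity`, `n`, `ip_sp`,
#'   `ip_sr`, `ir_sp`, `ir_sr`, sorted by `variants`/`zygosity`.
#' @export
cohort_margins <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  calls <- cohort$calls
  grp <- vapply(cohort$neonates$id, function(id) {
    cc <- calls[calls$id == id, , drop = FALSE]
    if (!nrow(cc)) return("negative:")
    ord <- order(cc$hgvs)
    z <- ifelse(cc$zygosity[ord] == "heteroplasmic", "mt", cc$zygosity[ord])
    paste(paste(cc$hgvs[ord], collapse = "/"), paste(z, collapse = "/"),
          sep = ":")
  }, character(1))
  cell <- paste0(ifelse(cohort$neonates$initial_oae == "pass", "ip", "ir"),
                 "_",
                 ifelse(cohort$neonates$second_aabr == "pass", "sp", "sr"))
  tab <- table(grp, factor(cell, levels = c("ip_sp", "ip_sr", "ir_sp", "ir_sr")))
  df <- as.data.frame.matrix(tab)
  parts <- strsplit(rownames(df), ":", fixed = TRUE)
  out <- data.frame(
    variants = vapply(parts, `[`, "", 1),
    zygosity = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
    n = rowSums(df), df, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$variants, out$zygosity), , drop = FALSE]
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: ", x$n_total, " neonates, ",
      length(unique(x$calls$id)), " variant-positive, ",
      sum(x$neonates$diagnosed), " diagnosed\n", sep = "")
  invisible(x)
}
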
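#' Simulation parameters for synthetic melt curves
#'
#' Bundles the temperature grid and signal-model parameters used by
#' [simulate_curve()]. The melt transition of each probe-target duplex is
#' modelled as a logistic step in temperature (the standard two-state duplex
#' approximation): fluorescence is high below the melting temperature and
#' decays to the baseline above it, so the negative derivative -dF/dT shows a
#' peak at each transition.
#'
#' @param temp_start,temp_end,temp_step Temperature grid in degrees Celsius.
#'   The default 40-90 at 0.1 covers every shipped-panel transition with at
#'   least a 10-degree margin.
#' @param transition_slope Logistic steepness in degrees Celsius. The default
#'   0.5 gives a 10-90% melt width of about 2.2 degrees, a sharp but
#'   realistic probe melt; it keeps the -dF/dT peak of one transition
#'   essentially unshifted by its neighbour at the panel's closest spacing
#'   (4.26 degrees) and leaves twin heterozygote peaks well resolved after
#'   the smoothing the peak caller applies.
#' @param amplitude_wt,amplitude_mut Fluorescence step heights for wild-type
#'   and mutant duplexes (arbitrary units).
#' @param baseline_slope,baseline_intercept Linear background added to the
#'   signal.
#' @param noise_sd Standard deviation of i.i.d. Gaussian fluorescence noise.
#' @param seed Optional integer seed making simulation deterministic.
#' @return A list of class `melt_sim_params`.
#' @export
melt_sim_params <- function(temp_start = 40, temp_end = 90, temp_step = 0.1,
                            transition_slope = 0.5,
                            amplitude_wt = 1, amplitude_mut = 1,
                            baseline_slope = -0.002, baseline_intercept = 0.1,
                            noise_sd = 0.01, seed = NULL) {
  stopifnot(temp_start < temp_end, temp_step > 0, transition_slope > 0,
            noise_sd >= 0)
  structure(list(temp_start = temp_start, temp_end = temp_end,
                 temp_step = temp_step, transition_slope = transition_slope,
                 amplitude_wt = amplitude_wt, amplitude_mut = amplitude_mut,
                 baseline_slope = baseline_slope,
                 baseline_intercept = baseline_intercept,
                 noise_sd = noise_sd, seed = seed),
            class = "melt_sim_params")
}

#' Construct a sample genotype
#'
#' Represents one neonate's genotype over the panel variants. Autosomal
#' variants are `het` or `hom`; mitochondrial variants carry a heteroplasmy
#' fraction `p` in (0, 1], the proportion of mitochondrial genomes bearing
#' the variant (`p = 1` is homoplasmic).
#'
#' @param het,hom Character vectors of variant names (HGVS labels as printed
#'   in the panel) carried in the heterozygous / homozygous state.
#' @param mt Named numeric vector of heteroplasmy fractions, names being
#'   mitochondrial variant labels, values in (0, 1].
#' @return A data frame of class `sample_genotype` with columns `hgvs`,
#'   `zygosity` (`"het"`, `"hom"`, or `"mt"`) and `fraction` (NA for
#'   autosomal states).
#' @export
sample_genotype <- function(het = character(), hom = character(),
                            mt = numeric()) {
  if (length(intersect(het, hom))) {
    stop("a variant cannot be both het and hom: ",
         paste(intersect(het, hom), collapse = ", "), call. = FALSE)
  }
  if (length(mt) && (is.null(names(mt)) || any(!nzchar(names(mt))))) {
    stop("mt must be a named vector of heteroplasmy fractions", call. = FALSE)
  }
  if (any(mt <= 0 | mt > 1)) {
    stop("heteroplasmy fractions must lie in (0, 1]", call. = FALSE)
  }
  g <- data.frame(
    hgvs = c(het, hom, names(mt)),
    zygosity = c(rep("het", length(het)), rep("hom", length(hom)),
                 rep("mt", length(mt))),
    fraction = c(rep(NA_real_, length(het) + length(hom)), unname(mt)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(g$hgvs)) {
    stop("duplicated variant in genotype: ",
         paste(g$hgvs[duplicated(g$hgvs)], collapse = ", "), call. = FALSE)
  }
  class(g) <- c("sample_genotype", "data.frame")
  g
}

#' Construct a melt curve container
#'
#' @param sample_id Sample identifier.
#' @param reaction,channel Assay coordinates.
#' @param temperature Strictly increasing temperature grid (>= 50 points).
#' @param fluorescence Fluorescence readings, same length, no missing values.
#' @return A list of class `melt_curve`.
#' @export
melt_curve <- function(sample_id, reaction, channel, temperature, fluorescence) {
  if (length(temperature) < 50) {
    stop("melt curve must have at least 50 points", call. = FALSE)
  }
  if (length(temperature) != length(fluorescence)) {
    stop("temperature and fluorescence lengths differ", call. = FALSE)
  }
  if (anyNA(temperature) || anyNA(fluorescence)) {
    stop("melt curve contains missing values", call. = FALSE)
  }
  if (any(diff(temperature) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  structure(list(sample_id = sample_id, reaction = reaction, channel = channel,
                 temperature = temperature, fluorescence = fluorescence),
            class = "melt_curve")
}

# Melt species (Tm, amplitude) contributed by a genotype on one assay.
# Each probe target is an allele mixture: het contributes dose 0.5 to the
# mutant duplex, hom dose 1, mitochondrial variants dose p; the wild-type
# duplex takes the remaining dose.
probe_species <- function(assay, genotype, params) {
  v <- assay$variants
  dose_mut <- numeric(nrow(v))
  if (nrow(genotype)) {
    for (i in seq_len(nrow(genotype))) {
      j <- match(genotype$hgvs[i], v$hgvs)
      if (is.na(j)) next
      dose_mut[j] <- switch(genotype$zygosity[i],
                            het = 0.5, hom = 1, mt = genotype$fraction[i],
                            stop("unknown zygosity: ", genotype$zygosity[i]))
    }
  }
  if (sum(dose_mut) > 1 + 1e-9) {
    stop("total mutant dose on assay ", assay$reaction, "/", assay$channel,
         " exceeds 1", call. = FALSE)
  }
  dose_wt <- 1 - sum(dose_mut)
  tm <- c(assay$tm_wt, assay$tm_wt - v$delta_tm)
  amp <- c(params$amplitude_wt * dose_wt, params$amplitude_mut * dose_mut)
  keep <- amp > 0
  data.frame(tm = tm[keep], amplitude = amp[keep])
}

#' Simulate one melt curve
#'
#' Generates the fluorescence trace of one assay (reaction x channel) for a
#' genotype:
#' `F(T) = baseline(T) + sum_species amplitude * logistic((Tm - T) / slope) + noise`.
#' A wild-type-only genotype yields a single transition at the probe's
#' wild-type Tm; a heterozygote yields two equal-amplitude transitions at
#' `tm_wt` and `tm_wt - delta_tm`; a homozygote a single shifted transition;
#' a mitochondrial mixture weights the two transitions by `(1 - p, p)`.
#'
#' @param panel An `mmca_panel`.
#' @param reaction,channel Assay coordinates (must exist in the panel).
#' @param genotype A [sample_genotype()]. Variants not on this assay are
#'   ignored.
#' @param params A [melt_sim_params()].
#' @param sample_id Sample identifier stored in the curve.
#' @return A [melt_curve()].
#' @export
simulate_curve <- function(panel, reaction, channel, genotype,
                           params = melt_sim_params(), sample_id = "S1") {
  assay <- panel_assay(panel, reaction, channel)
  temps <- seq(params$temp_start, params$temp_end, by = params$temp_step)
  lo <- min(assay$tm_wt - assay$variants$delta_tm, assay$tm_wt)
  hi <- max(assay$tm_wt - assay$variants$delta_tm, assay$tm_wt)
  if (params$temp_start > lo - 10 || params$temp_end < hi + 10) {
    stop("temperature grid must cover all probe transitions +/- 10 degrees",
         call. = FALSE)
  }
  sp <- probe_species(assay, genotype, params)
  f <- params$baseline_intercept + params$baseline_slope * temps
  for (i in seq_len(nrow(sp))) {
    f <- f + sp$amplitude[i] *
      stats::plogis((sp$tm[i] - temps) / params$transition_slope)
  }
  if (params$noise_sd > 0) {
    if (!is.null(params$seed)) {
      seed_i <- (params$seed + 131 * match(reaction, LETTERS) +
                 17 * sum(utf8ToInt(channel))) %% .Machine$integer.max
      f <- f + withr_seed_rnorm(seed_i, length(temps), params$noise_sd)
    } else {
      f <- f + stats::rnorm(length(temps), 0, params$noise_sd)
    }
  }
  melt_curve(sample_id, reaction, channel, temps, f)
}

# rnorm under a local seed without disturbing the global RNG state
withr_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

#' Simulate all melt curves of one sample
#'
#' One curve per panel assay. Genotype states for variants not on a probe do
#' not affect that probe's curve.
#'
#' @inheritParams simulate_curve
#' @return A list of [melt_curve()] objects, one per assay, in panel order.
#' @export
simulate_sample <- function(panel, genotype, params = melt_sim_params(),
                            sample_id = "S1") {
  lapply(panel$assays, function(a) {
    simulate_curve(panel, a$reaction, a$channel, genotype, params, sample_id)
  })
}
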
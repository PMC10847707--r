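# shared helpers: tiny panels, closed-form oracles, genotype sweeps

the_panel <- load_panel()

# a minimal single-probe panel built in code
tiny_panel <- function(delta_tm = 5, halfwidth = 1, tm_wt = 70,
                       gene = "GJB2", hgvs = "c.35delG",
                       inheritance = "autosomal") {
  structure(list(
    schema_version = "test",
    assays = list(list(
      reaction = "A", channel = "FAM", tm_wt = tm_wt,
      variants = data.frame(gene = gene, hgvs = hgvs, dbsnp = NA_character_,
                            acmg_class = NA_character_,
                            inheritance = inheritance, delta_tm = delta_tm,
                            window_halfwidth = halfwidth,
                            stringsAsFactors = FALSE)))),
    class = "mmca_panel")
}

# closed-form -dF/dT of a logistic mixture (the simulator's signal model,
# evaluated analytically - independent of the Savitzky-Golay pipeline)
mixture_deriv <- function(temps, tms, amps, slope) {
  d <- numeric(length(temps))
  for (i in seq_along(tms)) {
    l <- stats::plogis((tms[i] - temps) / slope)
    d <- d + amps[i] * l * (1 - l) / slope
  }
  d
}

# oracle peak positions: argmax of the closed form on a 0.001-degree grid
oracle_peak_tms <- function(tms, amps, slope, lo = 40, hi = 90) {
  grid <- seq(lo, hi, by = 0.001)
  d <- mixture_deriv(grid, tms, amps, slope)
  # local maxima above 5% of global max
  n <- length(d)
  i <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  i <- i[d[i] >= 0.05 * max(d)]
  sort(grid[i])
}

# every single-variant genotype of a panel: one row per (variant, zygosity)
panel_genotype_sweep <- function(panel) {
  pv <- panel_variants(panel)
  out <- list()
  for (i in seq_len(nrow(pv))) {
    v <- pv[i, ]
    for (zyg in c("het", "hom")) {
      gt <- if (v$inheritance == "mitochondrial") {
        sample_genotype(mt = stats::setNames(if (zyg == "het") 0.5 else 1, v$hgvs))
      } else if (zyg == "het") sample_genotype(het = v$hgvs) else
        sample_genotype(hom = v$hgvs)
      want <- if (v$inheritance == "mitochondrial") {
        if (zyg == "het") "heteroplasmic" else "homoplasmic"
      } else zyg
      out[[paste(v$hgvs, zyg)]] <- list(
        genotype = gt, hgvs = v$hgvs, zygosity = want,
        reaction = v$reaction, channel = v$channel)
    }
  }
  out
}

# the five double-heterozygote combinations observed in the study cohort
double_het_sweep <- function() {
  combos <- list(c("c.176_191del16", "c.919-2A>G"),
                 c("c.235delC", "c.919-2A>G"),
                 c("c.176_191del16", "c.235delC"),
                 c("c.235delC", "c.754T>C"),
                 c("c.299_300delAT", "c.919-2A>G"))
  lapply(combos, function(pair) list(
    genotype = sample_genotype(het = pair), hgvs = sort(pair)))
}

# brute-force two-sided Fisher p: direct hypergeometric enumeration
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form Pearson chi-squared statistic for a 2x2 table
chisq_closed_form <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}
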
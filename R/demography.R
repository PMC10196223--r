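#' Effective population size from linkage disequilibrium
#'
#' Single-sample LD method: Burrows composite disequilibrium is computed
#' for every allele pair at every pair of loci, squared correlations are
#' averaged (weighted by the number of individuals scored at both loci),
#' and the sampling expectation of r-squared under random mating is
#' subtracted using the piecewise sample-size correction
#' (1/S + 3.19/S^2 for S >= 30; 0.0018 + 0.907/S + 4.44/S^2 otherwise).
#' Ne is then obtained from the drift component of r-squared; negative
#' estimates (drift signal smaller than sampling noise) are returned
#' verbatim, as is an infinite upper confidence bound. The confidence
#' interval is parametric, treating n' (the number of pairwise
#' comparisons) as chi-square degrees of freedom.
#'
#' Alleles at frequency `maf_cutoff` or below are excluded; loci left with
#' fewer than two alleles are dropped. For diallelic loci a single allele
#' is used (the second is redundant).
#'
#' @param gt a `genotype_table`
#' @param pop population label(s) to analyse; default all
#' @param maf_cutoff allele-frequency exclusion threshold in [0, 0.5)
#' @return tibble: `pop`, `S` (harmonic-mean sample size), `n_comparisons`,
#'   `r2_mean`, `r2_drift`, `Ne_LD`, `CI_low`, `CI_high`
#' @export
ld_ne <- function(gt, pop = NULL, maf_cutoff = 0.02) {
  stopifnot(maf_cutoff >= 0, maf_cutoff < 0.5)
  gt <- as_genotype_table(gt)
  pops <- pop %||% gt_pops(gt)
  dplyr::bind_rows(lapply(pops, function(p) ld_ne_one(gt, p, maf_cutoff)))
}

ld_ne_one <- function(gt, pop, maf_cutoff) {
  sub <- gt[gt$pop == pop, ]
  if (!nrow(sub)) stop("unknown population: ", pop)
  loci <- gt_loci(sub)
  inds <- unique(sub$individual)
  if (length(inds) < 8) stop("need at least 8 individuals for the LD method")
  # dosage matrix per locus: individuals x usable alleles
  dosages <- list()
  for (l in loci) {
    sl <- sub[sub$locus == l, ]
    sl <- sl[match(inds, sl$individual), ]
    ok <- !is.na(sl$allele1) & !is.na(sl$allele2)
    all_copies <- c(sl$allele1[ok], sl$allele2[ok])
    if (!length(all_copies)) next
    freqs <- table(all_copies) / length(all_copies)
    usable <- names(freqs)[freqs > maf_cutoff]
    if (length(usable) < 2) next  # monomorphic after cutoff: dropped
    if (length(usable) == 2) usable <- usable[1]
    dos <- sapply(usable, function(a) {
      av <- as.integer(a)
      d <- (sl$allele1 == av) + (sl$allele2 == av)
      d[!ok] <- NA
      d
    })
    dosages[[l]] <- dos
  }
  if (length(dosages) < 2)
    stop("no polymorphic locus pair after frequency cutoff in ", pop)
  lnames <- names(dosages)
  r2s <- numeric(0); ws <- numeric(0); ss <- numeric(0)
  for (i in seq_along(lnames)[-length(lnames)]) {
    for (j in (i + 1):length(lnames)) {
      X <- dosages[[lnames[i]]]; Y <- dosages[[lnames[j]]]
      both <- stats::complete.cases(X) & stats::complete.cases(Y)
      s <- sum(both)
      if (s < 8) next
      Xb <- X[both, , drop = FALSE]; Yb <- Y[both, , drop = FALSE]
      for (a in seq_len(ncol(Xb))) {
        for (b in seq_len(ncol(Yb))) {
          x <- Xb[, a]; y <- Yb[, b]
          ph <- mean(x) / 2; qh <- mean(y) / 2
          # Burrows composite disequilibrium (with the S/(S-1) small-sample
          # factor) and HW-departure-adjusted denominators
          delta <- (mean(x * y) / 2 - 2 * ph * qh) * s / (s - 1)
          d_a <- mean(x == 2) - ph^2
          d_b <- mean(y == 2) - qh^2
          den <- (ph * (1 - ph) + d_a) * (qh * (1 - qh) + d_b)
          if (den <= 0) next
          r2s <- c(r2s, delta^2 / den)
          ws <- c(ws, s)
          ss <- c(ss, s)
        }
      }
    }
  }
  if (!length(r2s)) stop("no usable locus-pair comparison in ", pop)
  r2_mean <- sum(r2s * ws) / sum(ws)
  s_harm <- length(ss) / sum(1 / ss)
  e_r2 <- if (s_harm >= 30) 1 / s_harm + 3.19 / s_harm^2
  else 0.0018 + 0.907 / s_harm + 4.44 / s_harm^2
  ne_from_r2 <- function(r2d, s) {
    if (!is.finite(r2d) || r2d == 0) return(Inf)
    if (s >= 30) {
      (1 / 3 + sqrt(pmax(0, 1 / 9 - 2.76 * r2d))) / (2 * r2d)
    } else {
      (0.308 + sqrt(pmax(0, 0.308^2 - 2.08 * r2d))) / (2 * r2d)
    }
  }
  r2_drift <- r2_mean - e_r2
  ne <- ne_from_r2(r2_drift, s_harm)
  # parametric chi-square CI on the mean r2 with n' = #comparisons
  nprime <- length(r2s)
  r2_lo <- r2_mean * nprime / stats::qchisq(0.975, nprime)
  r2_hi <- r2_mean * nprime / stats::qchisq(0.025, nprime)
  ci <- sort(c(ne_from_r2(r2_lo - e_r2, s_harm),
               ne_from_r2(r2_hi - e_r2, s_harm)))
  # a negative bound means "no upper limit": report Inf, NeEstimator-style
  ci_low <- ci[1]; ci_high <- ci[2]
  if (ci_high < 0) ci_high <- Inf
  tibble::tibble(pop = pop, S = s_harm, n_comparisons = nprime,
                 r2_mean = r2_mean, r2_drift = r2_drift, Ne_LD = ne,
                 CI_low = ci_low, CI_high = ci_high)
}

#' Convert mutation-scaled theta to effective population size
#'
#' For diploid nuclear loci theta = 4 Ne mu, so the literal conversion is
#' Ne = theta / (4 mu) (`convention = "stated"`). Published tables in this
#' workflow's lineage are instead consistent with Ne = 4 theta / mu
#' rounded to an integer (`convention = "table"`, the default for
#' reproduction runs); the two differ by exactly a factor of 16. Both are
#' exposed; choose deliberately.
#'
#' @param theta non-negative mutation-scaled population size
#' @param mu mutation rate per generation (> 0)
#' @param convention `"table"` or `"stated"`
#' @return Ne (numeric; integer-valued under `"table"`)
#' @export
theta_to_ne <- function(theta, mu, convention = c("table", "stated")) {
  convention <- match.arg(convention)
  if (any(theta < 0)) stop("theta must be non-negative")
  if (any(mu <= 0)) stop("mutation rate must be positive")
  switch(convention,
         table = round(4 * theta / mu),
         stated = theta / (4 * mu))
}

#' Garza-Williamson M-ratio per locus
#'
#' M = k / (r + 1) with k the number of distinct alleles and r the allele
#' size range in repeat units. Monomorphic loci give M = 1 and are kept.
#'
#' @param gt a `genotype_table`
#' @param pop population label(s); default all
#' @param repeat_unit repeat length in bp (single value or named per-locus
#'   vector)
#' @return tibble: `pop`, `locus`, `k`, `r`, `M`
#' @export
m_ratio <- function(gt, pop = NULL, repeat_unit = 2) {
  gt <- as_genotype_table(gt)
  pops <- pop %||% gt_pops(gt)
  loci <- gt_loci(gt)
  ru <- if (length(repeat_unit) == 1)
    stats::setNames(rep(repeat_unit, length(loci)), loci) else repeat_unit
  rows <- list()
  for (p in pops) {
    sub <- gt[gt$pop == p, ]
    for (l in loci) {
      v <- c(sub$allele1[sub$locus == l], sub$allele2[sub$locus == l])
      v <- v[!is.na(v)]
      if (!length(v)) next
      rng <- (max(v) - min(v)) / ru[[l]]
      if (abs(rng - round(rng)) > 1e-9)
        stop("allele sizes at locus ", l, " are not on a lattice of repeat unit ",
             ru[[l]])
      k <- length(unique(v))
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop = p, locus = l, k = k, r = round(rng), M = k / (round(rng) + 1))
    }
  }
  dplyr::bind_rows(rows)
}

#' Equilibrium M-ratio null distribution under the two-phase model
#'
#' Coalescent simulation of a neutral microsatellite locus at
#' mutation-drift equilibrium: coalescence times are exponential with
#' rate k(k-1)/2 (time in units of 2Ne generations), mutations fall on
#' each lineage as a Poisson process of rate theta/2, and each mutation
#' is a single repeat step with probability `p_ss` or a geometric
#' multistep of mean `mean_jump` otherwise, with random sign. Returns the
#' simulated per-locus M values and their mean, the equilibrium
#' expectation M_eq against which observed M-ratios are tested.
#'
#' @param theta mutation-scaled population size of the locus
#' @param p_ss single-step mutation probability (two-phase model)
#' @param mean_jump mean multistep jump length in repeats
#' @param nsim number of simulated loci
#' @param n_gene_copies sample size in gene copies
#' @return list with `M` (vector of length `nsim`) and `M_eq` (their mean)
#' @export
m_eq_null <- function(theta, p_ss = 0.88, mean_jump = 2.8, nsim = 1000,
                      n_gene_copies = 60) {
  stopifnot(theta >= 0, nsim >= 1, n_gene_copies >= 2)
  m_vals <- numeric(nsim)
  for (s in seq_len(nsim)) {
    n <- n_gene_copies
    offset <- integer(n)       # repeat-unit displacement from the root
    memb <- seq_len(n)         # lineage membership of each tip
    active <- seq_len(n)
    k <- n
    while (k > 1) {
      t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
      nmut <- stats::rpois(k, theta / 2 * t_k)
      for (li in which(nmut > 0)) {
        jumps <- rep(1L, nmut[li])
        multi <- stats::runif(nmut[li]) >= p_ss
        if (any(multi))
          jumps[multi] <- 1L + stats::rgeom(sum(multi), prob = 1 / mean_jump)
        disp <- sum(jumps * sample(c(-1L, 1L), nmut[li], replace = TRUE))
        sel <- memb == active[li]
        offset[sel] <- offset[sel] + disp
      }
      pair <- sample.int(k, 2)
      memb[memb == active[pair[2]]] <- active[pair[1]]
      active <- active[-pair[2]]
      k <- k - 1
    }
    kk <- length(unique(offset))
    rr <- max(offset) - min(offset)
    m_vals[s] <- kk / (rr + 1)
  }
  list(M = m_vals, M_eq = mean(m_vals))
}

#' Wilcoxon signed-rank test for M-ratio deficiency
#'
#' One-sided paired test of observed per-locus M-ratios against their
#' equilibrium expectations, alternative = deficiency (bottleneck).
#' Zero differences are dropped; if all differences are zero the test is
#' uninformative and p = 1. The exact distribution is used for up to 25
#' loci.
#'
#' @param m_obs numeric vector of observed per-locus M values (>= 5 loci)
#' @param m_eq equilibrium expectation(s): scalar or per-locus vector
#' @return the one-sided p-value
#' @export
bottleneck_test <- function(m_obs, m_eq) {
  if (length(m_eq) == 1) m_eq <- rep(m_eq, length(m_obs))
  stopifnot(length(m_obs) == length(m_eq))
  if (length(m_obs) < 5) stop("need at least 5 loci")
  d <- m_obs - m_eq
  d <- d[d != 0]
  if (!length(d)) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, alternative = "less", mu = 0, exact = exact)$p.value)
}

#' Estimate theta from expected heterozygosity under stepwise mutation
#'
#' Fallback when no external theta is supplied: under the strict stepwise
#' model He = 1 - 1/sqrt(1 + 2 theta), inverted per locus and averaged.
#'
#' @param gt a `genotype_table`
#' @param pop population label
#' @return theta estimate (numeric scalar)
#' @export
theta_from_he <- function(gt, pop) {
  gt <- as_genotype_table(gt)
  sub <- gt[gt$pop == pop, ]
  loci <- gt_loci(sub)
  th <- sapply(loci, function(l) {
    v <- c(sub$allele1[sub$locus == l], sub$allele2[sub$locus == l])
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    n <- length(v)
    he <- (1 - sum((table(v) / n)^2)) * n / (n - 1)
    if (he >= 1) he <- 1 - 1e-9
    ((1 / (1 - he))^2 - 1) / 2
  })
  mean(th, na.rm = TRUE)
}

#' Demography summary table (Ne and bottleneck) per population
#'
#' Combines the LD-based Ne estimate, the theta-based coalescent Ne, and
#' the M-ratio bottleneck test into one table shaped like the standard
#' per-population report.
#'
#' @param gt a `genotype_table`
#' @param theta named vector of per-population theta values; populations
#'   absent from it fall back to [theta_from_he()]
#' @param mu mutation rate per generation
#' @param convention theta-to-Ne convention (see [theta_to_ne()])
#' @param maf_cutoff allele-frequency cutoff for the LD method
#' @param repeat_unit microsatellite repeat unit (bp)
#' @param nsim coalescent simulations per population for the M-ratio null
#' @param p_ss,mean_jump two-phase mutation model parameters
#' @return tibble: `pop`, `Ne_LD`, `CI_low`, `CI_high`, `theta`,
#'   `Ne_COAL`, `MR`, `MReq`, `p_bottleneck`
#' @export
demography_table <- function(gt, theta = NULL, mu = 5.47e-5,
                             convention = "table", maf_cutoff = 0.02,
                             repeat_unit = 2, nsim = 1000, p_ss = 0.88,
                             mean_jump = 2.8) {
  gt <- as_genotype_table(gt)
  pops <- gt_pops(gt)
  ld <- ld_ne(gt, maf_cutoff = maf_cutoff)
  mr <- m_ratio(gt, repeat_unit = repeat_unit)
  rows <- lapply(pops, function(p) {
    th <- if (!is.null(theta) && p %in% names(theta)) theta[[p]]
    else theta_from_he(gt, p)
    n_copies <- 2 * length(unique(gt$individual[gt$pop == p]))
    null <- m_eq_null(th, p_ss = p_ss, mean_jump = mean_jump, nsim = nsim,
                      n_gene_copies = n_copies)
    m_p <- mr$M[mr$pop == p]
    tibble::tibble(
      pop = p, theta = th,
      Ne_COAL = theta_to_ne(th, mu, convention),
      MR = mean(m_p), MReq = null$M_eq,
      p_bottleneck = bottleneck_test(m_p, null$M_eq))
  })
  dplyr::left_join(ld[c("pop", "Ne_LD", "CI_low", "CI_high")],
                   dplyr::bind_rows(rows), by = "pop")
}

#' Read per-population theta values from CSV
#'
#' Expects columns `pop` and `theta` (e.g. exported from a coalescent
#' sampler); returns the named vector [demography_table()] accepts.
#'
#' @param path CSV file path
#' @return named numeric vector of theta values
#' @export
read_theta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pop", "theta") %in% names(df)))
    stop("theta CSV needs columns `pop` and `theta`")
  stats::setNames(df$theta, df$pop)
}
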
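`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent oracle implementations used across the
# test files. Oracles deliberately use different algorithms (sums of
# squares, exhaustive enumeration, explicit eigendecomposition) than the
# package code they check.

# Build a genotype table from a named list pop -> list of c(a1, a2)
# genotype pairs per locus: toy_gt(list(A = list(L1 = rbind(c(100,102), ...))))
toy_gt <- function(pops) {
  rows <- list()
  for (p in names(pops)) {
    for (l in names(pops[[p]])) {
      g <- pops[[p]][[l]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = sprintf("%s_%03d", p, seq_len(nrow(g))),
        pop = p, locus = l, allele1 = g[, 1], allele2 = g[, 2])
    }
  }
  as_genotype_table(dplyr::bind_rows(rows))
}

# Weir-Cockerham theta for one locus and one allele via the classical
# three-level ANOVA sums of squares (pops / individuals / gametes) --
# an algebraically equivalent but computationally distinct route from the
# package's moment formulas.
wc_anova_theta <- function(pop_alleles) {
  # pop_alleles: list per pop of gene-copy vectors paired (1..n, n+1..2n)
  alleles <- sort(unique(unlist(pop_alleles)))
  a_tot <- b_tot <- c_tot <- 0
  r <- length(pop_alleles)
  n_i <- lengths(pop_alleles) / 2
  n <- sum(n_i)
  n_c <- (n - sum(n_i^2) / n) / (r - 1)
  for (al in alleles) {
    y <- lapply(pop_alleles, function(v) {
      ni <- length(v) / 2
      cbind(v[seq_len(ni)] == al, v[ni + seq_len(ni)] == al) * 1
    })
    ybar <- mean(unlist(y))
    ybar_i <- sapply(y, mean)
    ss_p <- sum(2 * n_i * (ybar_i - ybar)^2)
    ss_i <- sum(unlist(lapply(seq_along(y), function(i) {
      yb_ind <- rowMeans(y[[i]])
      2 * (yb_ind - ybar_i[i])^2
    })))
    ss_g <- sum(unlist(lapply(y, function(m) (m - rowMeans(m))^2)))
    msp <- ss_p / (r - 1)
    msi <- ss_i / (n - r)
    msg <- ss_g / n
    s2a <- (msp - msi) / (2 * n_c)
    s2b <- (msi - msg) / 2
    s2c <- msg
    a_tot <- a_tot + s2a; b_tot <- b_tot + s2b; c_tot <- c_tot + s2c
  }
  a_tot / (a_tot + b_tot + c_tot)
}

# Exhaustive rarefaction: mean number of distinct alleles over all
# C(n, g) subsets of the gene copies.
rarefaction_oracle <- function(copies, g) {
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2, function(idx) length(unique(copies[idx]))))
}

# AUC by exhaustive pair counting (ties count 1/2).
auc_oracle <- function(presence, background) {
  tot <- 0
  for (p in presence) for (b in background)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(presence) * length(background))
}

# Exhaustive minimum set cover size over all subsets of populations.
min_cover_oracle <- function(inc) {
  need <- which(colSums(inc) > 0)
  n <- nrow(inc)
  for (k in 1:n) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      if (all(colSums(inc[s, , drop = FALSE])[need] > 0)) return(k)
    }
  }
  n
}

# Explicit dbRDA: principal coordinates of the dissimilarity (positive
# eigenvalues only) regressed on X by OLS; R2 = ||H Y||^2 / ||Y||^2.
# Conditionals are partialled out of both Y and X first; the semipartial
# R2 keeps the original total inertia in the denominator.
dbrda_oracle <- function(d, x, z = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > 1e-10
  y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                sum(keep))
  total <- sum(y^2)
  hat <- function(m) {
    m <- scale(m, scale = FALSE)
    m %*% MASS::ginv(crossprod(m)) %*% t(m)
  }
  if (!is.null(z)) {
    hz <- hat(z)
    y <- y - hz %*% y
    x <- x - hz %*% x
  }
  fitted <- hat(as.matrix(x)) %*% y
  sum(fitted^2) / total
}

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_world(sim_config(
        n_pops = 8, n_ind_per_pop = 20, n_loci = 6, generations = 60,
        base_deme_size = 80, seed = 101))
    cache
  }
})

# Random population-by-allele incidence with every allele present
# somewhere. Per-allele occupancy follows a U-shaped mixture (common
# alleles shared by most populations, rare alleles held by few), the
# pattern real microsatellite data shows.
random_incidence <- function(n_pops, n_alleles) {
  pr <- stats::rbeta(n_alleles, 0.6, 0.9)
  inc <- sapply(pr, function(p) stats::runif(n_pops) < pmax(p, 0.05))
  dimnames(inc) <- list(sprintf("P%02d", seq_len(n_pops)),
                        paste0("a", seq_len(n_alleles)))
  for (j in which(colSums(inc) == 0)) inc[sample.int(n_pops, 1), j] <- TRUE
  inc
}

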
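#' Labelled symmetric dissimilarity matrices
#'
#' A small wrapper used for every pairwise matrix in the pipeline
#' (FST, linearized FST, geographic, climatic, terrain-ruggedness):
#' a symmetric numeric matrix with population dimnames and a `kind` tag.
#'
#' @param values symmetric numeric matrix with dimnames
#' @param kind one of `"fst"`, `"linearized_fst"`, `"geographic"`,
#'   `"climatic"`, `"tri"`
#' @return object of class `dist_matrix`
#' @export
dist_matrix <- function(values, kind) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("dist_matrix values must be symmetric")
  diag(values) <- 0
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @exportS3Method generics::tidy
tidy.dist_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(pop1 = labs[idx[, 1]], pop2 = labs[idx[, 2]],
                 value = x[idx], kind = attr(x, "kind"))
}

#' Per-population diversity: mean alleles, rarefied richness, private alleles
#'
#' `A` is the mean over loci of the number of distinct alleles; `A_r` is
#' allelic richness rarefied to `g` gene copies by the hypergeometric
#' formula (the expected number of distinct alleles among `g` copies drawn
#' without replacement); `A_p` counts alleles observed in exactly one
#' population across the full dataset.
#'
#' @param gt a `genotype_table`
#' @param g rarefaction size in gene copies; default twice the smallest
#'   per-population sample size over all populations and loci (missing
#'   data removed). Must not exceed that minimum.
#' @return tibble: `pop`, `A`, `A_r`, `A_p` (one row per population)
#' @export
diversity <- function(gt, g = NULL) {
  gt <- as_genotype_table(gt)
  loci <- gt_loci(gt); pops <- gt_pops(gt)
  copies <- lapply(loci, function(l) gene_copies(gt, l))
  names(copies) <- loci
  counts <- sapply(copies, function(cl)
    sapply(pops, function(p) length(cl[[p]] %||% integer())))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(pops),
                                             dimnames = list(pops, loci))
  gmin <- min(counts)
  if (is.null(g)) g <- gmin
  if (g > gmin) {
    lim <- which(counts == gmin, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "rarefaction size g = %d exceeds the %d gene copies available for population %s at locus %s",
      g, gmin, pops[lim[1]], loci[lim[2]]))
  }
  # private alleles over the full dataset
  priv <- stats::setNames(numeric(length(pops)), pops)
  for (l in loci) {
    present <- lapply(copies[[l]], unique)
    tab <- table(unlist(present))
    only_once <- names(tab)[tab == 1]
    for (p in pops) {
      priv[p] <- priv[p] + sum(as.character(present[[p]] %||% integer()) %in% only_once)
    }
  }
  rarefied <- function(v, g) {
    n <- length(v)
    tab <- table(v)
    # expected distinct alleles in g copies drawn without replacement
    sum(1 - exp(lchoose(n - tab, g) - lchoose(n, g)))
  }
  out <- lapply(pops, function(p) {
    a <- mean(sapply(loci, function(l) length(unique(copies[[l]][[p]]))))
    ar <- mean(sapply(loci, function(l) rarefied(copies[[l]][[p]], g)))
    tibble::tibble(pop = p, A = a, A_r = ar, A_p = unname(priv[p]))
  })
  dplyr::bind_rows(out)
}

# Weir-Cockerham (1984) variance components for one locus and a set of
# populations; returns the summed a, b, c over alleles.
wc_components <- function(pop_alleles) {
  pop_alleles <- pop_alleles[lengths(pop_alleles) >= 2]
  r <- length(pop_alleles)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  n_i <- lengths(pop_alleles) / 2          # individuals with data
  alleles <- sort(unique(unlist(pop_alleles)))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  n_bar <- mean(n_i); r_ <- r
  n_c <- (r_ * n_bar - sum(n_i^2) / (r_ * n_bar)) / (r_ - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (al in alleles) {
    p_i <- sapply(pop_alleles, function(v) mean(v == al))
    # observed heterozygote frequency for this allele, per population
    h_i <- sapply(pop_alleles, function(v) {
      n <- length(v) / 2  # pairs are (1..n, n+1..2n)
      g1 <- v[seq_len(n)]; g2 <- v[n + seq_len(n)]
      mean((g1 == al) != (g2 == al))
    })
    p_bar <- sum(n_i * p_i) / (r_ * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r_ - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r_ * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - s2 * (r_ - 1) / r_ - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - s2 * (r_ - 1) / r_ - h_bar * (2 * n_bar - 1) / (4 * n_bar))
    cc <- h_bar / 2
    a_tot <- a_tot + a; b_tot <- b_tot + b; c_tot <- c_tot + cc
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

# gene_copies keeps allele order as c(allele1 vector, allele2 vector) per
# pop; wc_components relies on that pairing to recover genotypes.

#' Pairwise multilocus Weir-Cockerham FST
#'
#' Theta estimated per population pair as the ratio of summed
#' among-population variance components to total components across loci
#' (ratio-of-sums). Negative estimates are preserved. Loci with fewer than
#' two gene copies in either population are skipped for that pair;
#' monomorphic loci contribute nothing.
#'
#' @param gt a `genotype_table`
#' @return a `dist_matrix` of kind `"fst"`
#' @export
pairwise_fst <- function(gt) {
  gt <- as_genotype_table(gt)
  pops <- gt_pops(gt); loci <- gt_loci(gt)
  if (length(pops) < 2) stop("need at least two populations")
  copies <- lapply(loci, function(l) gene_copies(gt, l))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  any_poly <- FALSE
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      acc <- c(a = 0, b = 0, c = 0)
      for (l in seq_along(loci)) {
        pa <- copies[[l]][c(pops[i], pops[j])]
        if (any(lengths(pa) < 2)) next
        acc <- acc + wc_components(pa)
      }
      denom <- sum(acc)
      if (denom == 0) {
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        any_poly <- TRUE
        m[i, j] <- m[j, i] <- acc[["a"]] / denom
      }
    }
  }
  if (!any_poly) stop("all loci monomorphic: FST undefined")
  dist_matrix(m, "fst")
}

#' Slatkin linearization F/(1-F)
#'
#' Elementwise transform of an FST matrix. Negative inputs are clamped to
#' 0; values at or above `1 - eps` are clamped to `(1 - eps)/eps` with a
#' warning, so the result is always finite and non-negative.
#'
#' @param d a `dist_matrix` of kind `"fst"` (or plain matrix)
#' @param eps clamping tolerance near 1
#' @return a `dist_matrix` of kind `"linearized_fst"`
#' @export
slatkin_linearize <- function(d, eps = 1e-6) {
  v <- unclass(d)
  if (any(v >= 1 - eps, na.rm = TRUE))
    warning("FST values at or above 1 - eps clamped")
  v <- pmin(pmax(v, 0), 1 - eps)
  out <- v / (1 - v)
  diag(out) <- 0
  dist_matrix(out, "linearized_fst")
}

#' Principal components of an ancestry (Q) matrix
#'
#' Centered (unscaled) PCA of per-population membership proportions,
#' returning the first two score columns (`anc1`, `anc2`). The sign of
#' each component is fixed so that the loading with the largest absolute
#' value is positive.
#'
#' @param q an `ancestry_matrix` (tibble with `pop` and `Q*` columns) or a
#'   plain matrix of memberships
#' @return tibble: `pop`, `anc1`, `anc2`
#' @export
ancestry_pca <- function(q) {
  if (is.data.frame(q)) {
    labs <- q$pop %||% rownames(q)
    qm <- as.matrix(q[grep("^Q", names(q))])
  } else {
    labs <- rownames(q) %||% paste0("pop", seq_len(nrow(q)))
    qm <- q
  }
  if (ncol(qm) < 2) stop("ancestry PCA needs K >= 2 clusters")
  pc <- stats::prcomp(qm, center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble::tibble(pop = labs, anc1 = scores[, 1],
                        anc2 = if (k >= 2) scores[, 2] else 0)
  out
}

#' Geographic distance matrix between sites (km, haversine)
#' @param sites tibble with `pop`, `lon`, `lat`
#' @return a `dist_matrix` of kind `"geographic"`
#' @export
geographic_dist <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n, dimnames = list(sites$pop, sites$pop))
  xy <- as.matrix(sites[c("lon", "lat")])
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(xy[i, ], xy) / 1000
  }
  m <- (m + t(m)) / 2
  dist_matrix(m, "geographic")
}
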
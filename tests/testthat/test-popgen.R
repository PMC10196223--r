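test_that("diversity handles monomorphic populations and full rarefaction", {
  gt <- toy_gt(list(
    mono = list(L1 = rbind(c(100, 100), c(100, 100)),
                L2 = rbind(c(120, 120), c(120, 120))),
    rich = list(L1 = rbind(c(100, 102), c(104, 106)),
                L2 = rbind(c(120, 122), c(120, 122)))))
  d <- diversity(gt, g = 4)
  mono <- d[d$pop == "mono", ]
  expect_equal(mono$A, 1)
  expect_equal(mono$A_r, 1)
  # g equals the gene copies: rarefied richness equals the full count
  rich <- d[d$pop == "rich", ]
  expect_equal(rich$A_r, mean(c(4, 2)))
  # alleles 102..106 and 122 appear only in "rich"; 100/120 are shared? no:
  # mono holds only 100 and 120, which also occur in rich -> mono has none
  expect_equal(mono$A_p, 0)
  expect_equal(rich$A_p, 4)
})

test_that("rarefied richness matches exhaustive subset enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    copies <- sample(c(100, 102, 104, 106), 8, replace = TRUE)
    gt <- toy_gt(list(
      X = list(L1 = matrix(copies, ncol = 2)),
      Y = list(L1 = rbind(c(100, 100), c(100, 100), c(100, 100),
                          c(100, 100)))))
    for (g in 2:6) {
      d <- diversity(gt, g = g)
      expect_equal(d$A_r[d$pop == "X"], rarefaction_oracle(copies, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("rarefaction size is validated with a named limiting locus", {
  gt <- toy_gt(list(A = list(L1 = rbind(c(100, 102), c(100, 104))),
                    B = list(L1 = rbind(c(100, 102)))))
  expect_error(diversity(gt, g = 3), "L1")
  expect_silent(diversity(gt, g = 2))
})

test_that("A_r is monotone non-decreasing in the rarefaction size", {
  world <- small_world()
  ar <- sapply(c(4, 8, 12, 16), function(g) diversity(world$genotypes, g)$A_r)
  expect_true(all(apply(ar, 1, function(v) all(diff(v) >= -1e-12))))
})

test_that("FST is 1 for fixed differences and <= 0 for duplicated samples", {
  fixed <- toy_gt(list(
    A = list(L1 = rbind(c(100, 100), c(100, 100), c(100, 100))),
    B = list(L1 = rbind(c(104, 104), c(104, 104), c(104, 104)))))
  expect_equal(unname(pairwise_fst(fixed)[1, 2]), 1)
  # identical allele-frequency populations: theta at or below 0
  g <- rbind(c(100, 102), c(100, 104), c(102, 104), c(100, 100))
  dup <- toy_gt(list(A = list(L1 = g), B = list(L1 = g)))
  expect_lte(pairwise_fst(dup)[1, 2], 0)
  mono <- toy_gt(list(
    A = list(L1 = rbind(c(100, 100), c(100, 100))),
    B = list(L1 = rbind(c(100, 100), c(100, 100)))))
  expect_error(pairwise_fst(mono), "monomorphic")
})

test_that("FST matches the independent ANOVA sums-of-squares oracle", {
  # hand-built 2 pops x 4 diploids x 1 locus table
  gt <- toy_gt(list(
    A = list(L1 = rbind(c(100, 102), c(100, 100), c(102, 102), c(100, 102))),
    B = list(L1 = rbind(c(102, 104), c(104, 104), c(102, 104), c(104, 104)))))
  got <- pairwise_fst(gt)[1, 2]
  cop <- priogen:::gene_copies(gt, "L1")
  expect_equal(unname(got), wc_anova_theta(cop), tolerance = 1e-10)
  # and on random multi-pop tables, per locus
  set.seed(7)
  for (rep in 1:5) {
    g1 <- matrix(sample(c(100, 102, 104, 106), 12, TRUE), ncol = 2)
    g2 <- matrix(sample(c(100, 102, 104), 10, TRUE), ncol = 2)
    gt2 <- toy_gt(list(A = list(L1 = g1), B = list(L1 = g2)))
    cop2 <- priogen:::gene_copies(gt2, "L1")
    if (length(unique(unlist(cop2))) < 2) next
    expect_equal(unname(pairwise_fst(gt2)[1, 2]), wc_anova_theta(cop2),
                 tolerance = 1e-10)
  }
})

test_that("FST is invariant to locus order and allele relabeling", {
  world <- small_world()
  gt <- world$genotypes
  base <- pairwise_fst(gt)
  shuffled <- dplyr::arrange(gt, dplyr::desc(locus), individual)
  expect_equal(unclass(pairwise_fst(as_genotype_table(shuffled))),
               unclass(base))
  relabeled <- dplyr::mutate(gt, allele1 = allele1 * 3 + 7,
                             allele2 = allele2 * 3 + 7)
  expect_equal(unclass(pairwise_fst(as_genotype_table(relabeled))),
               unclass(base), tolerance = 1e-12)
})

test_that("Slatkin linearization follows the closed form and clamps", {
  m <- matrix(c(0, 0, 0.5, 0, 0, 0.2, 0.5, 0.2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  lin <- slatkin_linearize(dist_matrix(m, "fst"))
  expect_equal(lin["a", "c"], 1.0)
  expect_equal(lin["b", "c"], 0.25)
  expect_equal(lin["a", "b"], 0)
  # negative values clamp to zero; values near 1 clamp with a warning
  m2 <- matrix(c(0, -0.05, -0.05, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(slatkin_linearize(dist_matrix(m2, "fst"))["a", "b"], 0)
  m3 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(l3 <- slatkin_linearize(dist_matrix(m3, "fst")), "clamped")
  expect_true(is.finite(l3["a", "b"]))
  # strictly increasing on [0, 1 - eps)
  x <- seq(0, 0.99, by = 0.01)
  mx <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  y <- sapply(x, function(v) {
    mx[1, 2] <- mx[2, 1] <- v
    slatkin_linearize(dist_matrix(mx, "fst"))[1, 2]
  })
  expect_true(all(diff(y) > 0))
})

test_that("ancestry PCA matches an explicit eigendecomposition", {
  q <- tibble::tibble(pop = paste0("p", 1:4),
                      Q1 = c(0.7, 0.2, 0.55, 0.1),
                      Q2 = c(0.2, 0.5, 0.25, 0.3),
                      Q3 = c(0.1, 0.3, 0.20, 0.6))
  sc <- ancestry_pca(q)
  qm <- as.matrix(q[paste0("Q", 1:3)])
  cen <- scale(qm, scale = FALSE)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)
  expected1 <- as.numeric(cen %*% ev$vectors[, 1])
  expect_equal(abs(sc$anc1), abs(expected1), tolerance = 1e-10)
  # sign convention: the largest-|loading| element of each axis positive
  pc <- stats::prcomp(qm, center = TRUE)
  for (j in 1:2) {
    load <- pc$rotation[, j]
    flip <- if (load[which.max(abs(load))] < 0) -1 else 1
    expect_equal(sc[[paste0("anc", j)]], unname(pc$x[, j] * flip),
                 tolerance = 1e-10)
  }
})

test_that("ancestry PCA handles symmetry and degenerate input", {
  q <- tibble::tibble(pop = c("a", "b"), Q1 = c(0.8, 0.2), Q2 = c(0.2, 0.8))
  sc <- ancestry_pca(q)
  expect_equal(sc$anc1[1], -sc$anc1[2], tolerance = 1e-12)
  flat <- tibble::tibble(pop = c("a", "b", "c"), Q1 = 0.5, Q2 = 0.5)
  expect_true(all(abs(ancestry_pca(flat)$anc1) < 1e-12))
  k1 <- tibble::tibble(pop = "a", Q1 = 1)
  expect_error(ancestry_pca(k1), "K >= 2")
})
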
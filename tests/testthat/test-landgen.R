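make_dist <- function(m, labels = NULL) {
  labels <- labels %||% paste0("p", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  dist_matrix(m, "geographic")
}

test_that("PCNM of equidistant points gives orthonormal paired eigenvectors", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  sc <- pcnm_scores(make_dist(m), n_axes = 2)
  ev <- attr(sc, "eigenvalues")
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  v <- as.matrix(sc[c("PCNM1", "PCNM2")])
  expect_equal(crossprod(v), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(colSums(v))), 1e-8)
})

test_that("PCNM with a large threshold recovers the PCoA of a line", {
  x <- c(0, 1, 2, 3, 5, 8)
  d <- as.matrix(stats::dist(x))
  sc <- pcnm_scores(make_dist(d), truncation = max(d) + 1, n_axes = 2)
  pcoa <- stats::cmdscale(stats::as.dist(d), k = 1)
  expect_gt(abs(stats::cor(sc$PCNM1, pcoa[, 1])), 1 - 1e-10)
  expect_error(pcnm_scores(make_dist(matrix(0, 3, 3))), "degenerate")
})

test_that("PCNM eigenvector count never exceeds n - 1 and stays orthogonal", {
  world <- small_world()
  g <- geographic_dist(world$sites)
  sc <- pcnm_scores(g, n_axes = 10)
  v <- as.matrix(sc[grep("PCNM", names(sc))])
  expect_lte(ncol(v), nrow(world$sites) - 1)
  expect_equal(crossprod(v), diag(ncol(v)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("dbRDA explains a Euclidean response generated by the predictors", {
  set.seed(31)
  n <- 10
  data <- tibble::tibble(pop = paste0("p", 1:n), x = rnorm(n), y = rnorm(n))
  d <- as.matrix(stats::dist(data[c("x", "y")]))
  dimnames(d) <- list(data$pop, data$pop)
  fit <- dbrda_fit(dist_matrix(d, "geographic"), data, c("x", "y"),
                   nperm = 99)
  expect_equal(fit$R2, 1, tolerance = 1e-8)
  # a perfectly explanatory model gets the smallest attainable p
  expect_equal(fit$p, 1 / (99 + 1), tolerance = 1e-12)
})

test_that("dbRDA R2 matches an explicit PCoA + OLS oracle", {
  set.seed(32)
  n <- 6
  data <- tibble::tibble(pop = paste0("p", 1:n), x = rnorm(n), y = rnorm(n),
                         z = rnorm(n))
  resp <- as.matrix(stats::dist(cbind(rnorm(n), rnorm(n))))
  dimnames(resp) <- list(data$pop, data$pop)
  d <- dist_matrix(resp, "geographic")
  fit <- dbrda_fit(d, data, c("x", "y"), nperm = 0)
  expect_equal(fit$R2, dbrda_oracle(resp, as.matrix(data[c("x", "y")])),
               tolerance = 1e-8)
  # partial model against the residualized oracle
  pfit <- dbrda_fit(d, data, "x", conditionals = "z", nperm = 0)
  expect_equal(pfit$R2,
               dbrda_oracle(resp, as.matrix(data["x"]),
                            z = as.matrix(data["z"])),
               tolerance = 1e-8)
})

test_that("R2 of nested dbRDA models is monotone", {
  world <- small_world()
  lin <- slatkin_linearize(pairwise_fst(world$genotypes))
  preds <- priogen:::landgen_predictors(world)
  r2 <- sapply(list("bio19", c("bio19", "bio15"),
                    c("bio19", "bio15", "lon", "lat")),
               function(v) dbrda_fit(lin, preds$data, v, nperm = 0)$R2)
  expect_true(all(diff(r2) >= -1e-12))
  # empty conditioning equals conditioning on a constant column
  d2 <- preds$data; d2$const <- 0
  plain <- dbrda_fit(lin, preds$data, "bio19", nperm = 0)
  cond <- suppressWarnings(dbrda_fit(lin, d2, "bio19",
                                     conditionals = "const", nperm = 0))
  expect_equal(plain$R2, cond$R2, tolerance = 1e-9)
})

test_that("permutation p-values are valid and never zero", {
  world <- small_world()
  lin <- slatkin_linearize(pairwise_fst(world$genotypes))
  preds <- priogen:::landgen_predictors(world)
  fit <- dbrda_fit(lin, preds$data, "bio19", nperm = 199)
  p <- permutation_anova(fit, nperm = 199)
  expect_gt(p, 0)
  expect_lte(p, 1)
  expect_gte(p, 1 / 200)
})

test_that("permutation p is approximately uniform under the null", {
  # small-n calibration: noise predictor against a noise response
  set.seed(33)
  n <- 12
  ps <- replicate(80, {
    data <- tibble::tibble(pop = paste0("p", 1:n), x = rnorm(n))
    resp <- as.matrix(stats::dist(rnorm(n)))
    dimnames(resp) <- list(data$pop, data$pop)
    dbrda_fit(dist_matrix(resp, "geographic"), data, "x", nperm = 499)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("forward selection recovers a planted causal predictor", {
  set.seed(34)
  n <- 16
  hits <- replicate(10, {
    causal <- rnorm(n)
    data <- tibble::tibble(pop = paste0("p", 1:n), causal = causal)
    for (j in 1:8) data[[paste0("noise", j)]] <- rnorm(n)
    resp <- as.matrix(stats::dist(2 * causal + 0.2 * rnorm(n)))
    dimnames(resp) <- list(data$pop, data$pop)
    sel <- forward_select(dist_matrix(resp, "geographic"), data,
                          setdiff(names(data), "pop"), alpha = 0.01,
                          nperm = 199)
    nrow(sel) >= 1 && sel$variable[1] == "causal" && nrow(sel) <= 2
  })
  expect_gte(mean(hits), 0.9)
})

test_that("forward selection handles null data and duplicate candidates", {
  set.seed(35)
  n <- 12
  data <- tibble::tibble(pop = paste0("p", 1:n), a = rnorm(n))
  data$b <- data$a            # exact duplicate
  data$c <- rnorm(n)
  resp <- as.matrix(stats::dist(rnorm(n)))
  dimnames(resp) <- list(data$pop, data$pop)
  d <- dist_matrix(resp, "geographic")
  sel_null <- forward_select(d, data, c("a", "c"), alpha = 0.01, nperm = 199)
  expect_lte(nrow(sel_null), 1)    # noise rarely qualifies at alpha = .01
  sel_dup <- forward_select(d, data, c("a", "b", "c"), alpha = 0.9,
                            nperm = 99)
  expect_lte(sum(sel_dup$variable %in% c("a", "b")), 1)
})

test_that("variance partitioning closes and handles orthogonal blocks", {
  # two orthogonal predictors each generating half the response variance
  n <- 8
  x <- rep(c(-1, 1), each = 4); y <- rep(c(-1, 1), times = 4)
  data <- tibble::tibble(pop = paste0("p", 1:n), x = x, y = y)
  resp <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(resp) <- list(data$pop, data$pop)
  d <- dist_matrix(resp, "geographic")
  part <- suppressMessages(variance_partition(d, data,
                                              list(bx = "x", by = "y"),
                                              nperm = 99))
  pure <- part[part$model != "full", ]
  expect_equal(pure$explained, c(0.5, 0.5), tolerance = 1e-8)
  # orthogonal blocks share no variance
  expect_true(all(abs(pure$shared) < 1e-8))
  closure <- pure$explained + pure$confounded + pure$unexplained
  expect_true(all(abs(closure - 1) < 1e-6))
})

test_that("a duplicated block is fully confounded", {
  set.seed(36)
  n <- 9
  data <- tibble::tibble(pop = paste0("p", 1:n), x = rnorm(n))
  data$x2 <- data$x
  resp <- as.matrix(stats::dist(data$x + 0.1 * rnorm(n)))
  dimnames(resp) <- list(data$pop, data$pop)
  part <- suppressWarnings(variance_partition(
    dist_matrix(resp, "geographic"), data,
    list(b1 = "x", b2 = "x2"), nperm = 99))
  pure <- part[part$model != "full", ]
  expect_true(all(pure$explained < 1e-8))
  full_expl <- part$explained[part$model == "full"]
  expect_equal(pure$confounded, rep(full_expl, 2), tolerance = 1e-8)
})

test_that("climate-driven divergence shows up as the dominant pure block", {
  world <- small_world()
  lin <- slatkin_linearize(pairwise_fst(world$genotypes))
  preds <- priogen:::landgen_predictors(world)
  part <- variance_partition(lin, preds$data,
                             list(clim = c("bio19", "bio15"),
                                  geo = c("lon", "lat")), nperm = 99)
  closure <- part$explained[-1] + part$confounded[-1] + part$unexplained[-1]
  expect_true(all(abs(closure - 1) < 1e-6))
  # cascade keeps refitting until every remaining block is significant
  part2 <- variance_partition(lin, preds$data,
                              list(clim = c("bio19", "bio15"),
                                   geo = c("lon", "lat")),
                              nperm = 199, cascade = TRUE)
  expect_true(all(c("stage", "model", "adjR2", "p") %in% names(part2)))
})
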
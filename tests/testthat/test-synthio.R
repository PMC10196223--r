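test_that("configuration validates counts and cluster bound", {
  expect_error(sim_config(n_clusters = 10, n_pops = 5), "n_clusters")
  expect_error(sim_config(migration_rate = 1.5))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("the default design yields 630 complete individuals at 9 loci", {
  gt <- simulate_genotypes(sim_config(n_pops = 21, n_ind_per_pop = 30,
                                      n_loci = 9, generations = 40,
                                      seed = 1))
  expect_equal(length(unique(gt$individual)), 21 * 30)
  expect_equal(length(unique(gt$locus)), 9)
  expect_false(any(is.na(gt$allele1)) || any(is.na(gt$allele2)))
  expect_equal(length(unique(gt$pop)), 21)
})

test_that("identical seeds give identical worlds; different seeds differ", {
  cfg <- sim_config(n_pops = 4, n_ind_per_pop = 10, n_loci = 3,
                    generations = 25, base_deme_size = 40, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g2))
  cfg2 <- sim_config(n_pops = 4, n_ind_per_pop = 10, n_loci = 3,
                     generations = 25, base_deme_size = 40, seed = 10)
  g3 <- simulate_genotypes(cfg2)
  expect_false(identical(tibble::as_tibble(g1), tibble::as_tibble(g3)))
})

test_that("no migration plus long divergence drives FST towards fixation", {
  gt <- simulate_genotypes(sim_config(n_pops = 2, n_clusters = 2, n_ind_per_pop = 15,
                                      n_loci = 5, generations = 400,
                                      base_deme_size = 25,
                                      n_ancestral_alleles = 4,
                                      migration_rate = 0,
                                      diversity_gradient = 0, seed = 21))
  fst <- pairwise_fst(gt)
  expect_gt(fst[1, 2], 0.5)
})

test_that("a panmictic deme split into two labels shows FST near zero", {
  gt <- simulate_genotypes(sim_config(n_pops = 1, n_clusters = 1, n_ind_per_pop = 200,
                                      n_loci = 6, generations = 50,
                                      base_deme_size = 400,
                                      diversity_gradient = 0, seed = 22))
  half <- gt
  ind_id <- as.integer(sub(".*_", "", half$individual))
  half$pop <- ifelse(ind_id <= 100, "A", "B")
  fst <- pairwise_fst(as_genotype_table(half))
  expect_lt(abs(fst[1, 2]), 0.02)
})

test_that("expected FST rises as migration falls", {
  mean_fst <- function(m) {
    vals <- sapply(1:6, function(i) {
      gt <- simulate_genotypes(sim_config(
        n_pops = 3, n_clusters = 3, n_ind_per_pop = 15, n_loci = 4,
        generations = 80,
        base_deme_size = 40, migration_rate = m,
        diversity_gradient = 0, seed = 3000 + i))
      mean(tidy(pairwise_fst(gt))$value)
    })
    mean(vals)
  }
  f <- sapply(c(0.2, 0.02, 0), mean_fst)
  expect_true(all(diff(f) > 0))
})

test_that("allelic richness declines along the west-east gradient", {
  gt <- simulate_genotypes(sim_config(n_pops = 10, n_ind_per_pop = 25,
                                      n_loci = 6, generations = 150,
                                      base_deme_size = 200,
                                      diversity_gradient = 0.85,
                                      n_ancestral_alleles = 14, seed = 25))
  div <- diversity(gt)
  # regression of richness on deme index is negative
  expect_lt(stats::coef(stats::lm(div$A_r ~ seq_len(nrow(div))))[2], 0)
  expect_gte(sum(div$A_p[1:5]), sum(div$A_p[6:10]))
})

test_that("climate stacks have the planted structure", {
  cfg <- sim_config(seed = 2)
  cur <- simulate_climate_stack(cfg, "current")
  # strict west-east decline of precipitation layers along every row
  expect_true(all(apply(cur$bio18$values, 1, function(r) all(diff(r) < 0))))
  expect_true(all(apply(cur$bio19$values, 1, function(r) all(diff(r) < 0))))
  # exactly collinear pair by construction
  expect_equal(abs(stats::cor(as.vector(cur$aridityIndexThornthwaite$values),
                              as.vector(cur$climaticMoistureIndex$values))),
               1)
  # zero shift, zero noise -> future identical to current
  fut0 <- simulate_climate_stack(cfg, "future", shift = c(bio1 = 0),
                                 noise_sd = 0)
  expect_equal(fut0$bio19$values, cur$bio19$values)
  # a uniform -50 shift moves every cell by exactly -50
  fut <- simulate_climate_stack(cfg, "future", shift = c(bio18 = -50),
                                noise_sd = 0)
  expect_equal(fut$bio18$values, cur$bio18$values - 50)
})

test_that("simulated ancestry follows the planted softmax structure", {
  cfg <- sim_config(n_pops = 10, seed = 3)
  cur <- simulate_climate_stack(cfg, "current")
  sites <- population_sites(cfg)
  q0 <- simulate_ancestry(cfg, cur, effect = c(bio19 = 0), sites = sites)
  expect_true(all(abs(as.matrix(q0[paste0("Q", 1:4)]) - 0.25) < 1e-12))
  q <- simulate_ancestry(cfg, cur, effect = c(bio19 = 3), sites = sites)
  qm <- as.matrix(q[paste0("Q", 1:4)])
  expect_equal(unname(rowSums(qm)), rep(1, 10))
  # modal cluster is a monotone step function of bio19 at the sites
  b19 <- extract_climate(cur, sites, "bio19")$bio19
  modal <- apply(qm, 1, which.max)
  expect_true(all(diff(modal[order(b19)]) <= 0) ||
                all(diff(modal[order(b19)]) >= 0))
  cfg1 <- sim_config(n_pops = 10, n_clusters = 1, seed = 3)
  q1 <- simulate_ancestry(cfg1, cur, effect = c(bio19 = 3), sites = sites)
  expect_true(all(q1$Q1 == 1))
})

test_that("fixtures round-trip and the manifest checksums match", {
  world <- small_world()
  dir <- withr::local_tempdir()
  manifest <- write_fixtures(world, dir)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_equal(unname(tools::md5sum(file.path(dir, manifest$file))),
               manifest$md5)
  back_gt <- read_genepop(file.path(dir, "genotypes.gen"))
  expect_equal(dplyr::arrange(tibble::as_tibble(back_gt), individual, locus),
               dplyr::arrange(tibble::as_tibble(world$genotypes),
                              individual, locus),
               ignore_attr = TRUE)
  back_dem <- read_esri_ascii(file.path(dir, "dem.asc"))
  expect_equal(back_dem$values, world$dem$values, tolerance = 1e-12)
  back_b19 <- read_esri_ascii(file.path(dir, "climate_future", "bio19.asc"))
  expect_equal(back_b19$values, world$climate_future$bio19$values,
               tolerance = 1e-12)
})
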
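#' Simulation configuration
#'
#' Bundles every knob of the synthetic world: a west-to-east chain of
#' demes genotyped at microsatellite loci, with ancestry clusters, climate
#' rasters and occurrence points. Defaults mirror the study design the
#' package targets: 21 populations of ~30 diploid individuals, nine loci,
#' four ancestral clusters, stepwise mutation at 5.47e-5 per generation,
#' and a west-to-east decline in allelic richness.
#'
#' @param n_pops number of populations (demes), arranged west to east.
#' @param n_ind_per_pop diploid individuals sampled per population.
#' @param n_loci number of microsatellite loci.
#' @param n_clusters number of ancestral clusters K (must be <= n_pops).
#' @param migration_rate per-generation fraction of immigrant gene copies
#'   in each deme (stepping-stone, split between the two neighbours).
#' @param mutation_rate per-generation stepwise mutation probability.
#' @param diversity_gradient relative decline in deme effective size from
#'   the westernmost to the easternmost deme (0 = none, 0.8 = eastern deme
#'   is 20% the size of the western one); drives the allelic-richness and
#'   private-allele gradient.
#' @param base_deme_size diploid effective size of the westernmost deme.
#' @param generations forward Wright-Fisher generations simulated.
#' @param n_ancestral_alleles allele states segregating in the founding
#'   pool at each locus.
#' @param missing_rate fraction of genotypes set to missing in the output.
#' @param p_multistep probability that a mutation jumps more than one
#'   repeat (geometric tail); shared with the two-phase-model null.
#' @param mean_multistep mean jump length of multistep mutations (repeats).
#' @param seed integer seed; identical seeds give identical worlds.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 21, n_ind_per_pop = 30, n_loci = 9,
                       n_clusters = 4, migration_rate = 0.05,
                       mutation_rate = 5.47e-5, diversity_gradient = 0.8,
                       base_deme_size = 250, generations = 150,
                       n_ancestral_alleles = 12, missing_rate = 0,
                       p_multistep = 0.12, mean_multistep = 2.8,
                       seed = 1L) {
  stopifnot(n_pops >= 1, n_ind_per_pop >= 1, n_loci >= 1, n_clusters >= 1,
            migration_rate >= 0, migration_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            base_deme_size >= 2, generations >= 1)
  if (n_clusters > n_pops) stop("n_clusters must not exceed n_pops")
  structure(list(
    n_pops = as.integer(n_pops), n_ind_per_pop = as.integer(n_ind_per_pop),
    n_loci = as.integer(n_loci), n_clusters = as.integer(n_clusters),
    migration_rate = migration_rate, mutation_rate = mutation_rate,
    diversity_gradient = diversity_gradient,
    base_deme_size = as.integer(base_deme_size),
    generations = as.integer(generations),
    n_ancestral_alleles = as.integer(n_ancestral_alleles),
    missing_rate = missing_rate, p_multistep = p_multistep,
    mean_multistep = mean_multistep, seed = as.integer(seed)),
    class = "sim_config")
}

# Deme effective sizes declining west to east.
deme_sizes <- function(cfg) {
  p <- cfg$n_pops
  frac <- if (p == 1) 0 else (seq_len(p) - 1) / (p - 1)
  pmax(4L, as.integer(round(cfg$base_deme_size * (1 - cfg$diversity_gradient * frac))))
}

#' Population site table for a configuration
#'
#' Deterministic coordinates along a 41-48 degree E transect between 40.9
#' and 42.7 degrees N, with altitudes drawn from the synthetic DEM.
#'
#' @param cfg a [sim_config()]
#' @return tibble with `pop`, `lon`, `lat`, `altitude`
#' @export
population_sites <- function(cfg) {
  p <- cfg$n_pops
  lon <- seq(41.6, 47.9, length.out = max(p, 2))[seq_len(p)]
  lat <- 41.8 + 0.6 * sin(seq_len(p) * 1.7)  # within 40.9-42.7
  dem <- simulate_dem(cfg)
  tibble::tibble(
    pop = sprintf("P%02d", seq_len(p)), lon = lon, lat = lat,
    altitude = extract_at(dem, lon, lat))
}

# Founding allele pool for one locus: a compact ladder of adjacent
# repeat states (as mutation-drift equilibrium produces), with
# geometric-like frequencies. Keeps the ancestral M-ratio near 1.
founding_locus <- function(n_alleles) {
  base <- sample.int(20L, 1)
  states <- 100L + 2L * (base + seq_len(n_alleles) - 1L)
  freq <- sort(stats::rexp(n_alleles), decreasing = TRUE)
  # shuffle mildly so the commonest allele is not always the smallest
  ord <- sample(seq_len(n_alleles))
  list(states = states, freq = (freq / sum(freq))[ord])
}

# One stepwise/TPM mutation step applied in place to a vector of repeat
# counts; `idx` marks the mutating copies.
tpm_mutate <- function(alleles, idx, p_multistep, mean_multistep) {
  if (length(idx) == 0) return(alleles)
  n <- length(idx)
  jump <- rep(1L, n)
  multi <- stats::runif(n) < p_multistep
  if (any(multi) && mean_multistep > 1) {
    jump[multi] <- 1L + stats::rgeom(sum(multi), prob = 1 / mean_multistep)
  }
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  alleles[idx] <- pmax(1L, alleles[idx] + sign * jump)
  alleles
}

#' Forward Wright-Fisher simulation of a single population
#'
#' Simulates unlinked microsatellite loci in one random-mating diploid
#' deme whose effective size follows the trajectory `ne`, starting from a
#' diverse founding pool, then samples `n_sample` individuals. Used for
#' estimator-calibration experiments (LD-Ne recovery, bottleneck power).
#'
#' @param ne integer vector of diploid effective sizes, one per generation
#'   (e.g. `rep(50, 100)`; a crash is expressed in the trajectory).
#' @param n_loci number of loci.
#' @param n_sample diploid individuals sampled at the end.
#' @param mutation_rate stepwise mutation probability per copy/generation.
#' @param n_ancestral_alleles founding allele states per locus.
#' @param p_multistep,mean_multistep two-phase mutation tail (see
#'   [sim_config()]).
#' @param pop label for the sampled population.
#' @param seed integer seed.
#' @return a `genotype_table`
#' @export
simulate_wf_population <- function(ne, n_loci = 20, n_sample = 50,
                                   mutation_rate = 5e-4,
                                   n_ancestral_alleles = 10,
                                   p_multistep = 0.12, mean_multistep = 2.8,
                                   pop = "simpop", seed = 1L) {
  stopifnot(all(ne >= 2), n_sample >= 1)
  with_seed(seed, {
    # diploid individuals carried jointly across loci so that finite
    # parentage generates genuine inter-locus LD (the LD-Ne signal)
    geno <- array(0L, dim = c(ne[1], 2, n_loci))
    for (l in seq_len(n_loci)) {
      f <- founding_locus(n_ancestral_alleles)
      geno[, , l] <- sample(f$states, 2 * ne[1], replace = TRUE,
                            prob = f$freq)
    }
    for (g in seq_along(ne)) {
      geno <- wf_generation(geno, ne[g], mutation_rate, p_multistep,
                            mean_multistep)
    }
    sample_genotype_array(geno, min(n_sample, dim(geno)[1]), pop)
  })
}

# One Wright-Fisher generation: random union of gametes from `n_new`
# parent pairs drawn from the diploid array `geno` [N x 2 x L], then
# stepwise/TPM mutation on the 2-bp lattice.
wf_generation <- function(geno, n_new, mutation_rate, p_multistep,
                          mean_multistep) {
  n_old <- dim(geno)[1]; n_loci <- dim(geno)[3]
  mothers <- sample.int(n_old, n_new, replace = TRUE)
  fathers <- sample.int(n_old, n_new, replace = TRUE)
  new <- array(0L, dim = c(n_new, 2, n_loci))
  for (l in seq_len(n_loci)) {
    new[, 1, l] <- geno[cbind(mothers, sample.int(2, n_new, TRUE), l)]
    new[, 2, l] <- geno[cbind(fathers, sample.int(2, n_new, TRUE), l)]
  }
  if (mutation_rate > 0) {
    mut <- which(stats::runif(length(new)) < mutation_rate)
    if (length(mut)) {
      ru <- (new - 100L) %/% 2L
      ru <- tpm_mutate(ru, mut, p_multistep, mean_multistep)
      new <- 100L + 2L * ru
    }
  }
  new
}

# Draw n_ind individuals from a diploid array into a genotype_table.
sample_genotype_array <- function(geno, n_ind, pop) {
  take <- sample.int(dim(geno)[1], n_ind)
  n_loci <- dim(geno)[3]
  out <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    out[[l]] <- tibble::tibble(
      individual = sprintf("%s_%03d", pop, seq_len(n_ind)),
      pop = pop, locus = sprintf("L%02d", l),
      allele1 = as.integer(geno[take, 1, l]),
      allele2 = as.integer(geno[take, 2, l]))
  }
  as_genotype_table(dplyr::bind_rows(out))
}

#' Simulate genotypes for a structured set of populations
#'
#' Forward Wright-Fisher stepping-stone chain: demes exchange migrants with
#' their neighbours at `migration_rate` per generation, mutation is
#' stepwise on a 2-bp repeat lattice, and deme sizes decline west to east
#' (`diversity_gradient`), producing the expected longitudinal decline in
#' allelic richness and private alleles. Returns complete data unless
#' `missing_rate > 0`.
#'
#' @param cfg a [sim_config()]
#' @return a `genotype_table` with attribute `truth` (deme sizes, site
#'   table, configuration)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- deme_sizes(cfg)
  p <- cfg$n_pops
  sites <- population_sites(cfg)
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    nl <- cfg$n_loci
    # found every deme from a shared ancestral pool, one frequency
    # spectrum per locus
    demes <- vector("list", p)
    founding <- lapply(seq_len(nl), function(l)
      founding_locus(cfg$n_ancestral_alleles))
    for (i in seq_len(p)) {
      gi <- array(0L, dim = c(sizes[i], 2, nl))
      for (l in seq_len(nl))
        gi[, , l] <- sample(founding[[l]]$states, 2 * sizes[i],
                            replace = TRUE, prob = founding[[l]]$freq)
      demes[[i]] <- gi
    }
    m <- cfg$migration_rate
    for (g in seq_len(cfg$generations)) {
      new_demes <- vector("list", p)
      for (i in seq_len(p)) {
        n_new <- sizes[i]
        nb <- c(if (i > 1) i - 1L, if (i < p) i + 1L)
        # each parent independently drawn from the local deme or a
        # neighbour (stepping-stone kernel)
        pick_parents <- function() {
          if (length(nb) && m > 0) {
            src <- sample(c(i, nb), n_new, replace = TRUE,
                          prob = c(1 - m, rep(m / length(nb), length(nb))))
          } else src <- rep(i, n_new)
          idx <- integer(n_new)
          for (s in unique(src)) {
            k <- src == s
            idx[k] <- sample.int(dim(demes[[s]])[1], sum(k), replace = TRUE)
          }
          list(src = src, idx = idx)
        }
        mo <- pick_parents(); fa <- pick_parents()
        gi <- array(0L, dim = c(n_new, 2, nl))
        for (l in seq_len(nl)) {
          ch1 <- sample.int(2, n_new, TRUE); ch2 <- sample.int(2, n_new, TRUE)
          for (s in unique(c(mo$src, fa$src))) {
            k1 <- mo$src == s
            if (any(k1))
              gi[k1, 1, l] <- demes[[s]][cbind(mo$idx[k1], ch1[k1], l)]
            k2 <- fa$src == s
            if (any(k2))
              gi[k2, 2, l] <- demes[[s]][cbind(fa$idx[k2], ch2[k2], l)]
          }
        }
        if (cfg$mutation_rate > 0) {
          mut <- which(stats::runif(length(gi)) < cfg$mutation_rate)
          if (length(mut)) {
            ru <- (gi - 100L) %/% 2L
            ru <- tpm_mutate(ru, mut, cfg$p_multistep, cfg$mean_multistep)
            gi <- 100L + 2L * ru
          }
        }
        new_demes[[i]] <- gi
      }
      demes <- new_demes
    }
    gt <- dplyr::bind_rows(lapply(seq_len(p), function(i)
      sample_genotype_array(demes[[i]], min(cfg$n_ind_per_pop, sizes[i]),
                            sites$pop[i])))
    if (cfg$missing_rate > 0) {
      drop <- stats::runif(nrow(gt)) < cfg$missing_rate
      gt$allele1[drop] <- NA
      gt$allele2[drop] <- NA
    }
    gt <- as_genotype_table(gt)
    attr(gt, "truth") <- list(deme_sizes = sizes, sites = sites, config = cfg)
    gt
  })
}

# Smooth deterministic field used by the raster generators.
field_on_grid <- function(lon, lat, f) {
  outer(lat, lon, f)  # rows = latitudes; caller flips to north-first
}

synth_grid_axes <- function(cfg, cellsize = 0.05) {
  list(lon = seq(41 + cellsize / 2, 48 - cellsize / 2, by = cellsize),
       lat = seq(40.9 + cellsize / 2, 42.7 - cellsize / 2, by = cellsize),
       cellsize = cellsize)
}

make_grid <- function(ax, f) {
  m <- field_on_grid(ax$lon, ax$lat, f)
  m <- m[rev(seq_along(ax$lat)), , drop = FALSE]  # row 1 = north
  raster_grid(m, 41, 40.9, ax$cellsize)
}

#' Synthetic digital elevation model
#'
#' Altitude rises towards the north-eastern ridge with a sinusoidal
#' valley structure; values in metres above sea level.
#'
#' @param cfg a [sim_config()]
#' @param cellsize cell size in degrees
#' @return a `raster_grid`
#' @export
simulate_dem <- function(cfg, cellsize = 0.05) {
  ax <- synth_grid_axes(cfg, cellsize)
  make_grid(ax, function(lat, lon)
    pmax(0, 200 + 900 * (lat - 40.9) + 120 * (lon - 41) +
           350 * sin(3 * lon) * cos(5 * lat)))
}

#' Synthetic forest-cover raster (fraction 0-1), denser in the west
#' @inheritParams simulate_dem
#' @return a `raster_grid`
#' @export
simulate_forest <- function(cfg, cellsize = 0.05) {
  ax <- synth_grid_axes(cfg, cellsize)
  make_grid(ax, function(lat, lon)
    pmin(1, pmax(0, 0.92 - 0.09 * (lon - 41) + 0.15 * sin(2.5 * lon + lat))))
}

#' Simulate a co-registered climate raster stack
#'
#' Builds the bioclimatic layers the analysis consumes (bio1, bio3, bio4,
#' bio8, bio9, bio15, bio18, bio19 plus `annualPET`,
#' `aridityIndexThornthwaite` and `climaticMoistureIndex`) as smooth
#' fields on a lon/lat grid. Precipitation layers bio18/bio19 decline
#' strictly monotonically west to east — the gradient the genetic and
#' niche analyses are designed to detect. `climaticMoistureIndex` is an
#' exact linear function of `aridityIndexThornthwaite`, giving the stack
#' one perfectly collinear pair by construction.
#'
#' The future stack is `current + shift` per layer (named `shift` vector)
#' plus optional cellwise Gaussian noise.
#'
#' @param cfg a [sim_config()]
#' @param period `"current"` or `"future"`
#' @param shift named numeric vector of uniform layer offsets applied when
#'   `period = "future"`; defaults to a warming/drying scenario.
#' @param noise_sd cellwise noise standard deviation for the future stack.
#' @param cellsize cell size in degrees
#' @return a named list of `raster_grid` of class `climate_stack`
#' @export
simulate_climate_stack <- function(cfg, period = c("current", "future"),
                                   shift = NULL, noise_sd = 0,
                                   cellsize = 0.05) {
  period <- match.arg(period)
  ax <- synth_grid_axes(cfg, cellsize)
  dem <- simulate_dem(cfg, cellsize)
  alt <- dem$values
  layers <- list()
  g <- function(f) make_grid(ax, f)
  layers$bio1 <- g(function(lat, lon) 14 - 1.2 * (lat - 40.9))
  layers$bio1$values <- layers$bio1$values - 0.0055 * alt  # lapse rate
  layers$bio3 <- g(function(lat, lon) 32 + 1.5 * sin(2 * lon) + 0.8 * (lon - 41))
  layers$bio4 <- g(function(lat, lon) 600 + 55 * (lon - 41) + 15 * cos(3 * lat))
  layers$bio8 <- g(function(lat, lon) 11 + 0.9 * sin(1.3 * lon + 2 * lat))
  layers$bio9 <- g(function(lat, lon) 16 - 0.9 * (lon - 41) + 0.5 * cos(2 * lon))
  layers$bio15 <- g(function(lat, lon) 35 + 6 * (lon - 41) + 2 * sin(4 * lat))
  # strict west->east decline in warm/cold-quarter precipitation
  layers$bio18 <- g(function(lat, lon) 420 - 42 * (lon - 41) + 18 * sin(3 * lat))
  layers$bio19 <- g(function(lat, lon) 900 - 95 * (lon - 41) + 25 * cos(2 * lat))
  layers$annualPET <- g(function(lat, lon) 800 + 40 * (lon - 41) - 12 * (lat - 40.9))
  layers$aridityIndexThornthwaite <-
    g(function(lat, lon) 30 + 7 * (lon - 41) - 4 * cos(2 * lat))
  cmi <- layers$aridityIndexThornthwaite
  cmi$values <- 0.8 - 0.012 * cmi$values  # exactly collinear pair
  layers$climaticMoistureIndex <- cmi
  if (period == "future") {
    shift <- shift %||% c(bio1 = 3.1, bio4 = 40, bio8 = 2.5, bio9 = 3.4,
                          bio15 = 5, bio18 = -95, bio19 = -190,
                          annualPET = 120, aridityIndexThornthwaite = 9,
                          climaticMoistureIndex = -0.1)
    with_seed(derive_seed(cfg$seed, paste0("climate_future")), {
      for (nm in names(layers)) {
        d <- if (nm %in% names(shift)) shift[[nm]] else 0
        v <- layers[[nm]]$values + d
        if (noise_sd > 0)
          v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), nrow(v))
        layers[[nm]]$values <- v
      }
    })
  }
  structure(layers, class = "climate_stack", period = period)
}

#' Extract climate values at population sites
#'
#' @param stack a `climate_stack`
#' @param sites tibble with `pop`, `lon`, `lat`
#' @param layers layer names to extract (default all)
#' @return tibble: `pop` plus one column per layer (point-sampled)
#' @export
extract_climate <- function(stack, sites, layers = names(stack)) {
  out <- tibble::tibble(pop = sites$pop)
  for (nm in layers)
    out[[nm]] <- extract_at(stack[[nm]], sites$lon, sites$lat)
  out
}

#' Simulate an ancestry (Q) matrix driven by climate
#'
#' Population-level membership proportions follow a softmax whose linear
#' predictor for cluster k is `w_k * (effect . z)`, with `z` the
#' standardized climate covariates at each site and `w_k` equally spaced
#' on [-1, 1]. A zero effect vector gives uniform membership 1/K; a single
#' strong positive effect makes the modal cluster a monotone step function
#' of that covariate.
#'
#' @param cfg a [sim_config()]
#' @param climate a `climate_stack`
#' @param effect named numeric vector, one entry per climate covariate
#'   used (e.g. `c(bio19 = 2)`).
#' @param sites site table; defaults to [population_sites()]
#' @return tibble of class `ancestry_matrix`: `pop` + `Q1..QK` columns
#' @export
simulate_ancestry <- function(cfg, climate, effect = c(bio19 = 2.5),
                              sites = population_sites(cfg)) {
  k <- cfg$n_clusters
  covs <- extract_climate(climate, sites, names(effect))
  z <- scale(as.matrix(covs[names(effect)]))
  z[is.nan(z)] <- 0
  lin <- as.numeric(z %*% effect)
  w <- if (k == 1) 0 else seq(-1, 1, length.out = k)
  eta <- outer(lin, w)
  q <- exp(eta - apply(eta, 1, max))
  q <- q / rowSums(q)
  out <- tibble::as_tibble(q, .name_repair = ~ paste0("Q", seq_len(k)))
  out <- dplyr::bind_cols(tibble::tibble(pop = sites$pop), out)
  class(out) <- c("ancestry_matrix", class(out))
  out
}

#' Assemble a complete synthetic world
#'
#' Genotypes, ancestry, current/future climate, DEM, forest cover and
#' occurrence points, all co-registered, plus a `truth` record (deme
#' sizes, cluster labels, ancestry effect sizes, suitability drivers)
#' sufficient for parameter-recovery tests.
#'
#' @param cfg a [sim_config()]
#' @param n_occurrences occurrence points sampled from the true
#'   suitability surface (logistic in bio19 and bio18).
#' @param ancestry_effect passed to [simulate_ancestry()]
#' @param future_shift,future_noise_sd passed to [simulate_climate_stack()]
#' @return list of class `synthetic_world`
#' @export
simulate_world <- function(cfg, n_occurrences = 88,
                           ancestry_effect = c(bio19 = 2.5),
                           future_shift = NULL, future_noise_sd = 0) {
  sites <- population_sites(cfg)
  genotypes <- simulate_genotypes(cfg)
  climate_current <- simulate_climate_stack(cfg, "current")
  climate_future <- simulate_climate_stack(cfg, "future",
                                           shift = future_shift,
                                           noise_sd = future_noise_sd)
  dem <- simulate_dem(cfg)
  forest <- simulate_forest(cfg)
  q <- simulate_ancestry(cfg, climate_current, ancestry_effect, sites)
  # true suitability: logistic in scaled bio19 + bio18
  b19 <- climate_current$bio19$values; b18 <- climate_current$bio18$values
  eta <- 1.6 * scale_mat(b19) + 0.8 * scale_mat(b18) - 0.2
  suit_true <- 1 / (1 + exp(-eta))
  occ <- with_seed(derive_seed(cfg$seed, "occurrences"), {
    idx <- sample.int(length(suit_true), n_occurrences,
                      prob = as.vector(suit_true)^2)
    rc <- arrayInd(idx, dim(suit_true))
    tibble::tibble(lon = grid_lon(dem)[rc[, 2]], lat = grid_lat(dem)[rc[, 1]])
  })
  truth <- c(attr(genotypes, "truth"),
             list(cluster_labels = apply(as.matrix(
               q[grep("^Q", names(q))]), 1, which.max),
               ancestry_effect = ancestry_effect,
               true_suitability = raster_grid(suit_true, dem$xll, dem$yll,
                                              dem$cellsize)))
  structure(list(
    config = cfg, sites = sites, genotypes = genotypes, q_matrix = q,
    climate_current = climate_current, climate_future = climate_future,
    dem = dem, forest = forest, occurrences = occ, truth = truth),
    class = "synthetic_world")
}

scale_mat <- function(m) (m - mean(m, na.rm = TRUE)) / stats::sd(m, na.rm = TRUE)

#' Write a synthetic world to disk as plain-text fixtures
#'
#' Emits GENEPOP and STRUCTURE genotype files, site/Q/occurrence CSVs and
#' ESRI ASCII grids for every raster, then returns (and writes) a JSON
#' manifest listing each file with its md5 checksum. Round-tripping any
#' file through the package readers reproduces the in-memory values.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created if needed)
#' @return tibble manifest (file, md5), invisibly; also written as
#'   `manifest.json`
#' @export
write_fixtures <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_genepop(world$genotypes, fp("genotypes.gen"))
  write_structure(world$genotypes, fp("genotypes.str"))
  utils::write.csv(world$sites, fp("sites.csv"), row.names = FALSE)
  utils::write.csv(world$q_matrix, fp("q_matrix.csv"), row.names = FALSE)
  utils::write.csv(world$occurrences, fp("occurrences.csv"), row.names = FALSE)
  write_esri_ascii(world$dem, fp("dem.asc"))
  write_esri_ascii(world$forest, fp("forest.asc"))
  for (per in c("climate_current", "climate_future")) {
    dir.create(fp(per), showWarnings = FALSE)
    for (nm in names(world[[per]]))
      write_esri_ascii(world[[per]][[nm]], fp(per, paste0(nm, ".asc")))
  }
  files <- list.files(dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))))
  jsonlite::write_json(manifest, fp("manifest.json"), pretty = TRUE)
  invisible(manifest)
}
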
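#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: the synthetic-world
#' parameters, per-stage toggles and the tuning parameters of every
#' stage. Also constructible from a YAML file via
#' [read_pipeline_config()].
#'
#' @param sim named list of [sim_config()] overrides (e.g.
#'   `list(n_pops = 12)`)
#' @param stages character vector of stages to run, from
#'   `c("metrics", "landgen", "demography", "enm", "forecast",
#'   "prioritize")`
#' @param nperm permutations for dbRDA tests
#' @param nsim coalescent simulations per population (M-ratio null)
#' @param g rarefaction size (NULL = automatic)
#' @param maf_cutoff LD-method allele-frequency cutoff
#' @param thresholds suitability thresholds for area accounting
#' @param k_categories number of priority categories
#' @param ne_convention theta-to-Ne convention (`"table"` or `"stated"`)
#' @param mu microsatellite mutation rate per generation
#' @param seed master seed for the run
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = list(), stages = c("metrics", "landgen",
                                                     "demography", "enm",
                                                     "forecast",
                                                     "prioritize"),
                            nperm = 499, nsim = 500, g = NULL,
                            maf_cutoff = 0.02, thresholds = c(0.15, 0.70),
                            k_categories = 5, ne_convention = "table",
                            mu = 5.47e-5, seed = 1L) {
  structure(list(sim = sim, stages = stages, nperm = nperm, nsim = nsim,
                 g = g, maf_cutoff = maf_cutoff, thresholds = thresholds,
                 k_categories = k_categories, ne_convention = ne_convention,
                 mu = mu, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()]'s fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates the synthetic world, then executes the enabled stages in
#' dependency order (metrics, landscape genetics, demography, niche
#' model, ancestry forecast, prioritization), writing every stage table
#' as CSV into `outdir` together with a JSON manifest (file checksums)
#' and a run report (seed, parameters, timings). Reruns with the same
#' configuration and seed produce byte-identical outputs. A populated
#' output directory is not overwritten unless `force = TRUE`.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory
#' @param force overwrite an existing, non-empty output directory?
#' @return the run report (list), invisibly
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, force = FALSE) {
  t0 <- Sys.time()
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory is not empty; use force = TRUE to overwrite")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  stages <- config$stages
  timings <- list()
  clock <- function(label, expr) {
    t <- system.time(res <- force(expr))
    timings[[label]] <<- unname(t["elapsed"])
    res
  }
  message("simulating synthetic world (seed ", config$seed, ")")
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  world <- clock("simulate", simulate_world(cfg))
  outputs <- character()
  emit <- function(df, name) {
    utils::write.csv(df, fp(name), row.names = FALSE)
    outputs <<- c(outputs, name)
  }
  emit_matrix <- function(m, name) {
    utils::write.csv(as.data.frame(unclass(m)), fp(name), row.names = TRUE)
    outputs <<- c(outputs, name)
  }
  div <- fst <- lin <- NULL
  if ("metrics" %in% stages) {
    message("stage: diversity and differentiation metrics")
    clock("metrics", {
      div <- diversity(world$genotypes, g = config$g)
      emit(div, "diversity.csv")
      fst <- pairwise_fst(world$genotypes)
      emit_matrix(fst, "fst.csv")
      lin <- slatkin_linearize(fst)
      emit_matrix(lin, "fst_linearized.csv")
      emit(ancestry_pca(world$q_matrix), "ancestry_pca.csv")
    })
  }
  if ("landgen" %in% stages) {
    if (is.null(lin)) stop("landgen stage requires metrics")
    message("stage: landscape genetics")
    clock("landgen", with_seed(derive_seed(config$seed, "landgen"), {
      preds <- landgen_predictors(world)
      sel <- forward_select(lin, preds$data, preds$blocks$clim,
                            alpha = 0.01, nperm = config$nperm)
      emit(sel, "forward_selection.csv")
      clim_cols <- if (nrow(sel)) sel$variable else preds$blocks$clim[1]
      blocks <- list(clim = clim_cols, geo = preds$blocks$geo,
                     oro = preds$blocks$oro, anc = preds$blocks$anc)
      part <- variance_partition(lin, preds$data, blocks,
                                 nperm = config$nperm, cascade = TRUE)
      emit(part, "variance_partition.csv")
    }))
  }
  if ("demography" %in% stages) {
    message("stage: effective population size and bottlenecks")
    clock("demography", with_seed(derive_seed(config$seed, "demography"), {
      demo <- demography_table(world$genotypes, mu = config$mu,
                               convention = config$ne_convention,
                               maf_cutoff = config$maf_cutoff,
                               nsim = config$nsim)
      emit(demo, "demography.csv")
    }))
  }
  suit_cur <- suit_fut <- NULL
  if ("enm" %in% stages) {
    message("stage: niche model and area accounting")
    clock("enm", {
      bioclim <- c("bio1", "bio3", "bio4", "bio8", "bio9", "bio15",
                   "bio18", "bio19")
      suit_cur <- fit_suitability(world$occurrences, world$climate_current,
                                  layers = bioclim,
                                  seed = derive_seed(config$seed, "enm"))
      suit_fut <- project_suitability(suit_cur, world$climate_future)
      thr <- config$thresholds
      area_tbl <- dplyr::bind_rows(lapply(
        list(list(p = "current", m = suit_cur),
             list(p = "future", m = suit_fut)),
        function(it) {
          alt <- altitudinal_stats(it$m, world$dem, thr[1])
          tibble::tibble(
            period = it$p, auc = it$m$auc, tss = it$m$tss,
            area_low = threshold_area(it$m, thr[1]),
            area_high = threshold_area(it$m, thr[2]),
            alt_min = alt$alt_min, alt_mean = alt$alt_mean,
            alt_max = alt$alt_max)
        }))
      area_tbl$area_low_change <- area_tbl$area_low - area_tbl$area_low[1]
      area_tbl$area_high_change <- area_tbl$area_high - area_tbl$area_high[1]
      emit(area_tbl, "suitability_summary.csv")
      write_esri_ascii(suit_cur$raster, fp("suitability_current.asc"))
      write_esri_ascii(suit_fut$raster, fp("suitability_future.asc"))
      outputs <- c(outputs, "suitability_current.asc",
                   "suitability_future.asc")
      clim_tbl <- extract_climate(world$climate_current, world$sites, bioclim)
      pca <- climate_pca(clim_tbl)
      emit(pca$scores, "climate_pca_scores.csv")
      emit(tibble::tibble(axis = seq_along(pca$variance_fraction),
                          variance_fraction = pca$variance_fraction),
           "climate_pca_variance.csv")
    })
  }
  if ("forecast" %in% stages) {
    if (is.null(suit_cur)) {
      message("skipping forecast: requires the enm stage")
    } else {
      message("stage: ancestry forecast")
      clock("forecast", {
        covs <- extract_climate(world$climate_current, world$sites,
                                c("bio1", "bio3", "bio18", "bio19"))
        model <- fit_ancestry_climate(world$q_matrix, covs)
        proj_cur <- project_ancestry(model, world$climate_current,
                                     mask = suit_cur)
        fut_covs <- world$climate_future
        proj_fut <- project_ancestry(model, fut_covs, mask = suit_fut)
        pers <- cluster_persistence(proj_cur, proj_fut)
        emit(pers, "cluster_persistence.csv")
        jsonlite::write_json(list(
          entropy_current = attr(pers, "entropy_current"),
          entropy_future = attr(pers, "entropy_future")),
          fp("homogenization.json"), auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, "homogenization.json")
        write_esri_ascii(proj_cur$cluster, fp("clusters_current.asc"))
        write_esri_ascii(proj_fut$cluster, fp("clusters_future.asc"))
        outputs <- c(outputs, "clusters_current.asc", "clusters_future.asc")
      })
    }
  }
  if ("prioritize" %in% stages) {
    message("stage: prioritization")
    clock("prioritize", {
      inc <- allele_incidence(world$genotypes)
      emit(reserve_selection(inc), "reserve_selection.csv")
      pri <- prioritize_populations(
        world$genotypes, world$sites, world$forest,
        world$climate_current, world$climate_future,
        g = config$g, k = config$k_categories)
      emit(dplyr::left_join(world$sites, pri, by = "pop"),
           "prioritization.csv")
    })
  }
  outputs <- unique(outputs)
  manifest <- tibble::tibble(
    file = outputs, md5 = unname(tools::md5sum(fp(outputs))))
  jsonlite::write_json(manifest, fp("manifest.json"), pretty = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("priogen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = stages,
    parameters = config[setdiff(names(config), "sim")],
    sim = config$sim,
    timings_s = timings,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = outputs)
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 6)
  invisible(report)
}

# Predictor table + block map for the landscape-genetics stage of the
# pipeline: climate candidates at the sites, geographic coordinates,
# first PCNM axis of the TRI dissimilarity, and ancestry PC scores.
landgen_predictors <- function(world) {
  sites <- world$sites
  clim_vars <- c("bio1", "bio3", "bio4", "bio8", "bio9", "bio15", "bio18",
                 "bio19", "aridityIndexThornthwaite")
  clim <- extract_climate(world$climate_current, sites, clim_vars)
  tri <- compute_tri(world$dem)
  tri_vals <- extract_at(tri, sites$lon, sites$lat)
  tri_d <- dist_matrix(
    abs(outer(tri_vals, tri_vals, `-`)) |>
      (\(m) {dimnames(m) <- list(sites$pop, sites$pop); m})(),
    kind = "tri")
  oro <- pcnm_scores(tri_d, n_axes = 1)
  anc <- ancestry_pca(world$q_matrix)
  data <- standardize_predictors(
    dplyr::left_join(clim, sites[c("pop", "lon", "lat")], by = "pop") |>
      dplyr::left_join(oro, by = "pop") |>
      dplyr::left_join(anc, by = "pop"))
  list(data = data,
       blocks = list(clim = clim_vars, geo = c("lon", "lat"),
                     oro = "PCNM1", anc = c("anc1", "anc2")))
}
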
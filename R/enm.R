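#' Stepwise variance-inflation-factor filter
#'
#' Iteratively removes the variable with the largest VIF while that VIF
#' exceeds `threshold`, recomputing after each removal. Perfectly
#' collinear variables (infinite VIF) are removed first; ties break
#' alphabetically on the variable name.
#'
#' @param data data frame of candidate variables (a `pop` column, if
#'   present, is ignored)
#' @param threshold VIF threshold above which variables are dropped
#' @return list with `retained` (character vector) and `log` (tibble of
#'   dropped variables with the VIF that removed them)
#' @export
vif_filter <- function(data, threshold = 10) {
  df <- as.data.frame(data)[setdiff(names(data), "pop")]
  stopifnot(ncol(df) >= 2, nrow(df) >= ncol(df) + 1)
  vif_of <- function(df) {
    sapply(names(df), function(v) {
      others <- setdiff(names(df), v)
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(others, response = v), data = df))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    })
  }
  log <- list()
  while (ncol(df) > 1) {
    v <- vif_of(df)
    if (max(v) <= threshold) break
    worst <- sort(names(v)[v == max(v)])[1]
    log[[length(log) + 1]] <- tibble::tibble(
      step = length(log) + 1L, variable = worst, vif = unname(v[worst]))
    df <- df[setdiff(names(df), worst)]
  }
  list(retained = names(df),
       log = if (length(log)) dplyr::bind_rows(log)
       else tibble::tibble(step = integer(), variable = character(),
                           vif = numeric()))
}

# Linear + quadratic + pairwise-product feature expansion of raw layer
# values, standardized by the stored means/sds (built on first use).
build_features <- function(x, meta = NULL) {
  x <- as.matrix(x)
  if (is.null(meta)) {
    meta <- list(mean = colMeans(x, na.rm = TRUE),
                 sd = apply(x, 2, stats::sd, na.rm = TRUE),
                 vars = colnames(x))
    meta$sd[meta$sd == 0 | is.na(meta$sd)] <- 1
  }
  z <- sweep(sweep(x[, meta$vars, drop = FALSE], 2, meta$mean), 2, meta$sd, "/")
  p <- ncol(z)
  feats <- list(z, z^2)
  names2 <- c(colnames(z), paste0(colnames(z), "_sq"))
  if (p > 1) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      feats[[length(feats) + 1]] <- z[, i] * z[, j]
      names2 <- c(names2, paste0(colnames(z)[i], "_x_", colnames(z)[j]))
    }
  }
  out <- do.call(cbind, feats)
  colnames(out) <- names2
  attr(out, "meta") <- meta
  out
}

#' Fit a maximum-entropy-style suitability model
#'
#' A minimal MaxEnt surrogate: L1-regularized logistic regression of
#' presence cells against background cells on linear, quadratic and
#' pairwise-product features of the climate layers, with logistic output
#' in [0, 1]. Occurrences are deduplicated at cell level; 20% of them are
#' held out (by `seed`) and scored against held-out background for AUC
#' and TSS (presence-versus-background convention).
#'
#' @param occ tibble of occurrence points (`lon`, `lat`)
#' @param stack a `climate_stack`
#' @param layers layer names used as predictors (default all)
#' @param bg_n maximum number of background cells sampled
#' @param reg regularization multiplier (scales the L1 penalty)
#' @param test_fraction fraction of occurrences held out for evaluation
#' @param seed integer seed for the background sample and the split
#' @return object of class `suitability_map`: `raster` (suitability),
#'   `auc`, `tss`, plus the fitted coefficients
#' @export
fit_suitability <- function(occ, stack, layers = names(stack), bg_n = 10000,
                            reg = 1, test_fraction = 0.2, seed = 1L) {
  ref <- stack[[layers[1]]]
  # cell-level dedup
  cell <- paste(floor((occ$lon - ref$xll) / ref$cellsize),
                floor((occ$lat - ref$yll) / ref$cellsize))
  occ <- occ[!duplicated(cell), , drop = FALSE]
  if (nrow(occ) < 10) stop("need at least 10 unique occurrence cells")
  pres_x <- sapply(layers, function(nm) extract_at(stack[[nm]], occ$lon, occ$lat))
  keep <- stats::complete.cases(pres_x)
  pres_x <- pres_x[keep, , drop = FALSE]
  if (length(unique(paste(pres_x[, 1]))) < 2 && nrow(unique(pres_x)) < 2)
    stop("degenerate occurrences: all points fall in identical climate")
  with_seed(seed, {
    all_vals <- sapply(layers, function(nm) as.vector(stack[[nm]]$values))
    ok_cells <- which(stats::complete.cases(all_vals))
    bg_idx <- sample(ok_cells, min(bg_n, length(ok_cells)))
    bg_x <- all_vals[bg_idx, , drop = FALSE]
    n_test <- max(1, round(test_fraction * nrow(pres_x)))
    test_i <- sample.int(nrow(pres_x), n_test)
    bg_test_i <- sample.int(nrow(bg_x), min(nrow(bg_x), 5 * n_test))
    feats_train <- build_features(rbind(pres_x[-test_i, , drop = FALSE],
                                        bg_x[-bg_test_i, , drop = FALSE]))
    meta <- attr(feats_train, "meta")
    y <- c(rep(1, nrow(pres_x) - n_test), rep(0, nrow(bg_x) - length(bg_test_i)))
    # presences and background weighted equally in total
    w <- c(rep(1, sum(y == 1)), rep(sum(y == 1) / sum(y == 0), sum(y == 0)))
    fit <- glmnet::glmnet(feats_train, y, family = "binomial", alpha = 1,
                          weights = w, lambda = reg * 1e-3,
                          standardize = FALSE)
    predict_suit <- function(x)
      as.numeric(stats::predict(fit, build_features(x, meta),
                                type = "response"))
    test_scores <- predict_suit(pres_x[test_i, , drop = FALSE])
    bg_scores <- predict_suit(bg_x[bg_test_i, , drop = FALSE])
    ev <- evaluate_scores(test_scores, bg_scores)
    suit <- rep(NA_real_, nrow(all_vals))
    suit[ok_cells] <- predict_suit(all_vals[ok_cells, , drop = FALSE])
    raster <- raster_grid(matrix(suit, nrow(ref$values), ncol(ref$values)),
                          ref$xll, ref$yll, ref$cellsize)
    structure(list(raster = raster, auc = ev$auc, tss = ev$tss,
                   coefficients = stats::coef(fit), layers = layers,
                   feature_meta = meta, glmnet_fit = fit),
              class = "suitability_map")
  })
}

#' Project a fitted suitability model onto another climate stack
#' @param map a `suitability_map`
#' @param stack a co-registered `climate_stack` (e.g. a future scenario)
#' @return a `suitability_map` sharing the fitted model, with evaluation
#'   statistics carried over
#' @export
project_suitability <- function(map, stack) {
  ref <- stack[[map$layers[1]]]
  all_vals <- sapply(map$layers, function(nm) as.vector(stack[[nm]]$values))
  ok <- stats::complete.cases(all_vals)
  suit <- rep(NA_real_, nrow(all_vals))
  suit[ok] <- as.numeric(stats::predict(
    map$glmnet_fit, build_features(all_vals[ok, , drop = FALSE],
                                   map$feature_meta), type = "response"))
  out <- map
  out$raster <- raster_grid(matrix(suit, nrow(ref$values), ncol(ref$values)),
                            ref$xll, ref$yll, ref$cellsize)
  out
}

#' AUC and TSS from presence and background scores
#'
#' AUC by the rank (Mann-Whitney) statistic over presence-versus-
#' background scores; TSS as the maximum over candidate thresholds of
#' sensitivity + specificity - 1.
#'
#' @param presence,background numeric score vectors (both non-empty)
#' @return list with `auc` and `tss`
#' @export
evaluate_scores <- function(presence, background) {
  if (!length(presence) || !length(background))
    stop("need both presence and background scores")
  n1 <- length(presence); n0 <- length(background)
  r <- rank(c(presence, background))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(c(presence, background)))
  tss <- max(sapply(thr, function(t)
    mean(presence >= t) + mean(background < t) - 1))
  list(auc = auc, tss = tss)
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> AUC = %.3f, TSS = %.3f\n", x$auc, x$tss))
  print(x$raster)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.suitability_map <- function(x, ...) {
  tibble::tibble(auc = x$auc, tss = x$tss,
                 area_15 = threshold_area(x, 0.15),
                 area_70 = threshold_area(x, 0.70))
}

#' @exportS3Method ggplot2::autoplot
autoplot.suitability_map <- function(object, ...) {
  autoplot.raster_grid(object$raster) +
    ggplot2::labs(fill = "Suitability")
}

#' Cellwise mean of suitability maps (multi-model ensemble)
#'
#' @param maps list of co-registered `suitability_map` (or `raster_grid`)
#' @return object of the same type as the inputs, with evaluation
#'   statistics averaged when present
#' @export
ensemble_mean <- function(maps) {
  rasters <- lapply(maps, function(m)
    if (inherits(m, "suitability_map")) m$raster else m)
  for (r in rasters[-1]) stop_if_misaligned(rasters[[1]], r)
  vals <- Reduce(`+`, lapply(rasters, function(r) r$values)) / length(rasters)
  out_raster <- raster_grid(vals, rasters[[1]]$xll, rasters[[1]]$yll,
                            rasters[[1]]$cellsize)
  if (inherits(maps[[1]], "suitability_map")) {
    out <- maps[[1]]
    out$raster <- out_raster
    out$auc <- mean(sapply(maps, `[[`, "auc"))
    out$tss <- mean(sapply(maps, `[[`, "tss"))
    out
  } else out_raster
}

#' Suitable area above a threshold, in square kilometres
#'
#' Sums cosine-latitude-corrected cell areas over cells with suitability
#' at or above `thr`; NODATA cells never count.
#'
#' @param map a `suitability_map` or `raster_grid` of suitabilities
#' @param thr suitability threshold in (0, 1), e.g. 0.15 or 0.70
#' @return area in km^2
#' @export
threshold_area <- function(map, thr) {
  stopifnot(thr > 0, thr < 1)
  r <- if (inherits(map, "suitability_map")) map$raster else map
  a <- cell_area_km2(r)
  sum(a[!is.na(r$values) & r$values >= thr])
}

#' Signed change in suitable area between two periods
#' @param future_area,current_area areas in km^2 (>= 0)
#' @return future minus current (km^2)
#' @export
area_change <- function(future_area, current_area) {
  stopifnot(future_area >= 0, current_area >= 0)
  future_area - current_area
}

#' Altitudinal statistics of the suitable range
#'
#' Order statistics of the DEM over the cells at or above the suitability
#' threshold. An empty mask returns a zero-row count with NA statistics
#' rather than zeros.
#'
#' @param map a `suitability_map` or `raster_grid`
#' @param dem co-registered elevation `raster_grid`
#' @param thr suitability threshold
#' @return tibble: `n_cells`, `alt_min`, `alt_mean`, `alt_max`
#' @export
altitudinal_stats <- function(map, dem, thr = 0.15) {
  r <- if (inherits(map, "suitability_map")) map$raster else map
  stop_if_misaligned(r, dem)
  sel <- !is.na(r$values) & r$values >= thr & !is.na(dem$values)
  z <- dem$values[sel]
  if (!length(z))
    return(tibble::tibble(n_cells = 0L, alt_min = NA_real_,
                          alt_mean = NA_real_, alt_max = NA_real_))
  tibble::tibble(n_cells = length(z), alt_min = min(z), alt_mean = mean(z),
                 alt_max = max(z))
}

#' PCA of population-level climate
#'
#' Centered and scaled principal component analysis of a populations-by-
#' variables climate table, reporting scores, loadings and the fraction
#' of variance per axis.
#'
#' @param data data frame with `pop` and numeric climate columns
#' @return object of class `climate_pca`: `scores` (tibble),
#'   `loadings` (tibble), `variance_fraction` (numeric)
#' @export
climate_pca <- function(data) {
  labs <- data$pop %||% rownames(data)
  x <- as.matrix(data[setdiff(names(data), "pop")])
  keep <- apply(x, 2, stats::sd) > 0
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(pop = labs),
                              tibble::as_tibble(pc$x)),
    loadings = tibble::as_tibble(pc$rotation, rownames = "variable"),
    variance_fraction = vf), class = "climate_pca")
}

#' @exportS3Method generics::tidy
tidy.climate_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.climate_pca <- function(x, ...) {
  tibble::tibble(pc1_fraction = x$variance_fraction[1],
                 pc2_fraction = if (length(x$variance_fraction) > 1)
                   x$variance_fraction[2] else NA_real_)
}

#' @exportS3Method ggplot2::autoplot
autoplot.climate_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$pop), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2]))
}
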
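#' Fit an ancestry-by-climate model
#'
#' Deterministic surrogate for MCMC ancestry-projection software:
#' multinomial softmax regression of fractional ancestry memberships (Q)
#' on climate covariates, minimizing cross-entropy with a small L2
#' penalty (lambda) for identifiability. The optimizer is BFGS with
#' analytic gradient and fixed zero initialization, so refits are
#' bit-reproducible.
#'
#' @param q an `ancestry_matrix` (tibble with `pop` and `Q*` columns)
#' @param covariates data frame with `pop` and the climate covariate
#'   columns (default covariate set: bio1, bio3, bio18, bio19)
#' @param vars covariate column names to use
#' @param lambda L2 penalty on all coefficients
#' @return object of class `ancestry_climate_model`: `K`, `vars`,
#'   `coefficients` (K x (p+1)), `scaling`, `cross_entropy`,
#'   `null_cross_entropy`
#' @export
fit_ancestry_climate <- function(q, covariates,
                                 vars = intersect(c("bio1", "bio3", "bio18",
                                                    "bio19"),
                                                  names(covariates)),
                                 lambda = 1e-3) {
  qm <- as.matrix(q[grep("^Q", names(q))])
  k <- ncol(qm)
  if (k < 2) stop("need K >= 2 clusters")
  covariates <- covariates[match(q$pop, covariates$pop), , drop = FALSE]
  x <- as.matrix(covariates[vars])
  if (any(!is.finite(x))) stop("non-finite covariate values")
  if (ncol(x) >= nrow(x)) stop("more covariates than populations")
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- cbind(1, sweep(sweep(x, 2, ctr), 2, scl, "/"))
  n <- nrow(z); p1 <- ncol(z)
  softmax <- function(eta) {
    e <- exp(eta - apply(eta, 1, max))
    e / rowSums(e)
  }
  obj <- function(b) {
    bm <- matrix(b, k, p1)
    pr <- softmax(z %*% t(bm))
    -sum(qm * log(pmax(pr, 1e-300))) + lambda / 2 * sum(bm^2)
  }
  grad <- function(b) {
    bm <- matrix(b, k, p1)
    pr <- softmax(z %*% t(bm))
    as.vector(t(pr - qm) %*% z + lambda * bm)
  }
  fit <- stats::optim(rep(0, k * p1), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  bm <- matrix(fit$par, k, p1,
               dimnames = list(paste0("Q", seq_len(k)),
                               c("(Intercept)", vars)))
  pr <- softmax(z %*% t(bm))
  ce <- -mean(rowSums(qm * log(pmax(pr, 1e-300))))
  null_ce <- -mean(rowSums(qm * log(
    matrix(colMeans(qm), n, k, byrow = TRUE))))
  structure(list(K = k, vars = vars, coefficients = bm,
                 scaling = list(center = ctr, scale = scl),
                 cross_entropy = ce, null_cross_entropy = null_ce,
                 fitted = pr, converged = fit$convergence == 0),
            class = "ancestry_climate_model")
}

#' @export
print.ancestry_climate_model <- function(x, ...) {
  cat(sprintf("<ancestry_climate_model> K = %d, covariates: %s\n  cross-entropy %.4f (null %.4f)\n",
              x$K, paste(x$vars, collapse = ", "), x$cross_entropy,
              x$null_cross_entropy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ancestry_climate_model <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "term",
                        values_to = "estimate")
}

#' @exportS3Method generics::glance
glance.ancestry_climate_model <- function(x, ...) {
  tibble::tibble(K = x$K, cross_entropy = x$cross_entropy,
                 null_cross_entropy = x$null_cross_entropy,
                 converged = x$converged)
}

predict_membership <- function(model, x) {
  z <- cbind(1, sweep(sweep(x, 2, model$scaling$center), 2,
                      model$scaling$scale, "/"))
  eta <- z %*% t(model$coefficients)
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

#' Project cluster membership onto a climate grid
#'
#' Applies a fitted ancestry-climate model to every cell of a climate
#' stack, yielding per-cluster membership probability rasters and a hard
#' cluster map (argmax). Cells outside the suitability mask (below `thr`,
#' or NODATA) are NODATA.
#'
#' @param model an `ancestry_climate_model`
#' @param stack a `climate_stack` containing the model covariates
#' @param mask optional `suitability_map` (or raster) restricting the
#'   projection
#' @param thr suitability threshold applied to `mask`
#' @return object of class `ancestry_projection`: `membership` (list of
#'   `raster_grid`), `cluster` (integer `raster_grid`), `K`
#' @export
project_ancestry <- function(model, stack, mask = NULL, thr = 0.15) {
  miss <- setdiff(model$vars, names(stack))
  if (length(miss)) stop("stack is missing covariates: ",
                         paste(miss, collapse = ", "))
  ref <- stack[[model$vars[1]]]
  vals <- sapply(model$vars, function(nm) as.vector(stack[[nm]]$values))
  ok <- stats::complete.cases(vals)
  if (!is.null(mask)) {
    mr <- if (inherits(mask, "suitability_map")) mask$raster else mask
    stop_if_misaligned(ref, mr)
    ok <- ok & !is.na(as.vector(mr$values)) & as.vector(mr$values) >= thr
  }
  n_cell <- nrow(vals)
  memb <- matrix(NA_real_, n_cell, model$K)
  if (any(ok)) memb[ok, ] <- predict_membership(model, vals[ok, , drop = FALSE])
  cl <- rep(NA_real_, n_cell)
  if (any(ok)) cl[ok] <- max.col(memb[ok, , drop = FALSE], ties.method = "first")
  shape <- function(v) raster_grid(matrix(v, nrow(ref$values),
                                          ncol(ref$values)),
                                   ref$xll, ref$yll, ref$cellsize)
  structure(list(
    membership = lapply(seq_len(model$K), function(j) shape(memb[, j])),
    cluster = shape(cl), K = model$K), class = "ancestry_projection")
}

#' Average ancestry projections across climate models
#'
#' Cellwise mean of membership probabilities over projections (e.g. one
#' per global climate model), then argmax for the consensus cluster map.
#'
#' @param projections list of co-registered `ancestry_projection`
#' @return an `ancestry_projection`
#' @export
ensemble_ancestry <- function(projections) {
  k <- projections[[1]]$K
  memb <- lapply(seq_len(k), function(j)
    ensemble_mean(lapply(projections, function(p) p$membership[[j]])))
  ref <- memb[[1]]
  mm <- sapply(memb, function(r) as.vector(r$values))
  ok <- stats::complete.cases(mm)
  cl <- rep(NA_real_, nrow(mm))
  if (any(ok)) cl[ok] <- max.col(mm[ok, , drop = FALSE], ties.method = "first")
  structure(list(
    membership = memb,
    cluster = raster_grid(matrix(cl, nrow(ref$values), ncol(ref$values)),
                          ref$xll, ref$yll, ref$cellsize),
    K = k), class = "ancestry_projection")
}

#' Cluster persistence between two projected periods
#'
#' Compares hard cluster maps for two periods: a cluster is "lost" when
#' it occupies no cells in the future map. Also reports per-cluster areas
#' and a homogenization index (Shannon entropy of cluster area shares) for
#' each period; falling entropy means a more homogeneous genetic
#' landscape.
#'
#' @param current,future `ancestry_projection` (or integer cluster
#'   rasters) on the same grid
#' @return tibble: `cluster`, `current_cells`, `future_cells`,
#'   `current_km2`, `future_km2`, `status`; entropies in attributes
#'   `entropy_current` / `entropy_future`
#' @export
cluster_persistence <- function(current, future) {
  cr <- if (inherits(current, "ancestry_projection")) current$cluster else current
  fr <- if (inherits(future, "ancestry_projection")) future$cluster else future
  stop_if_misaligned(cr, fr)
  k <- max(c(cr$values, fr$values), na.rm = TRUE)
  area <- cell_area_km2(cr)
  stat_for <- function(r) {
    sapply(seq_len(k), function(j) {
      sel <- !is.na(r$values) & r$values == j
      c(cells = sum(sel), km2 = sum(area[sel]))
    })
  }
  cur <- stat_for(cr); fut <- stat_for(fr)
  entropy <- function(km2) {
    sh <- km2[km2 > 0] / sum(km2)
    if (!length(sh)) return(NA_real_)
    -sum(sh * log(sh))
  }
  out <- tibble::tibble(
    cluster = seq_len(k),
    current_cells = as.integer(cur["cells", ]),
    future_cells = as.integer(fut["cells", ]),
    current_km2 = cur["km2", ], future_km2 = fut["km2", ],
    status = ifelse(fut["cells", ] == 0, "lost", "retained"))
  attr(out, "entropy_current") <- entropy(cur["km2", ])
  attr(out, "entropy_future") <- entropy(fut["km2", ])
  out
}
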
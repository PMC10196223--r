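#' Standardize predictor columns
#'
#' Z-scores every numeric column (mean 0, sd 1), leaving the `pop` label
#' column untouched. Constant columns become 0.
#'
#' @param data data frame with a `pop` column and numeric predictors
#' @return tibble with the same columns, numeric ones standardized
#' @export
standardize_predictors <- function(data) {
  out <- tibble::as_tibble(data)
  for (nm in setdiff(names(out), "pop")) {
    v <- out[[nm]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      out[[nm]] <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
  }
  out
}

align_to_response <- function(response, data) {
  labs <- rownames(response)
  if (!("pop" %in% names(data))) stop("predictor data needs a `pop` column")
  if (!all(labs %in% data$pop))
    stop("predictor data is missing populations: ",
         paste(setdiff(labs, data$pop), collapse = ", "))
  data[match(labs, data$pop), , drop = FALSE]
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Classical PCNM on a dissimilarity matrix: distances beyond the
#' truncation threshold are replaced by four times the threshold, the
#' matrix is double-centered, and eigenvectors with positive eigenvalues
#' are returned in decreasing-eigenvalue order. The default threshold is
#' the longest edge of the minimum spanning tree, so the neighbour graph
#' stays connected. By default only the first eigenvector is retained as
#' the structural score used downstream.
#'
#' @param d a `dist_matrix` (any kind)
#' @param truncation numeric threshold or `"auto"` (longest MST edge)
#' @param n_axes number of leading eigenvectors to return
#' @return tibble: `pop` + `PCNM1..n` columns; eigenvalues in attribute
#'   `eigenvalues`
#' @export
pcnm_scores <- function(d, truncation = "auto", n_axes = 1) {
  dd <- stats::as.dist(unclass(d))
  if (max(dd) <= 1e-12)
    stop("degenerate dissimilarity: all points coincide")
  fit <- if (identical(truncation, "auto")) vegan::pcnm(dd)
  else vegan::pcnm(dd, threshold = truncation)
  k <- min(n_axes, ncol(fit$vectors))
  out <- tibble::as_tibble(fit$vectors[, seq_len(k), drop = FALSE],
                           .name_repair = ~ paste0("PCNM", seq_len(k)))
  out <- dplyr::bind_cols(tibble::tibble(pop = rownames(unclass(d))), out)
  attr(out, "eigenvalues") <- fit$values[fit$values > 0]
  attr(out, "threshold") <- fit$threshold
  out
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Constrained ordination of a dissimilarity matrix on explanatory
#' columns, optionally partialling out conditioning columns first
#' (partial dbRDA). The response is Gower-centered via principal
#' coordinates; R2 is constrained inertia over total inertia computed on
#' non-negative eigenvalues, and adjusted R2 uses the Ezekiel closed form.
#' Fitting is delegated to vegan's `capscale`; the permutation test
#' (pseudo-F, residual permutation under the reduced model when
#' conditionals are present) to vegan's `anova.cca`, with
#' p = (#F_perm >= F_obs + 1)/(nperm + 1).
#'
#' @param response a `dist_matrix` (typically linearized FST)
#' @param data data frame with `pop` and predictor columns
#' @param constraints character vector of constraining column names
#' @param conditionals optional character vector of conditioning columns
#' @param nperm permutations for the overall test
#' @return object of class `dbrda_fit` with elements `R2`, `adjR2`, `F`,
#'   `p`, `site_scores`, `biplot_scores`, and the underlying vegan fit
#' @export
dbrda_fit <- function(response, data, constraints, conditionals = NULL,
                      nperm = 999) {
  data <- align_to_response(response, data)
  if (length(constraints) == 0) stop("need at least one constraint")
  dd <- stats::as.dist(unclass(response))
  rhs <- paste(constraints, collapse = " + ")
  if (length(conditionals))
    rhs <- paste0(rhs, " + Condition(", paste(conditionals, collapse = " + "), ")")
  env <- new.env(parent = environment())
  env$dd <- dd
  fml <- stats::as.formula(paste("dd ~", rhs), env = env)
  fit <- vegan::capscale(fml, data = data)
  rank0 <- is.null(fit$CCA) || fit$CCA$rank == 0
  if (rank0) {
    r2 <- list(r.squared = 0)
    adj <- 0
  } else {
    r2 <- vegan::RsquareAdj(fit)
    adj <- r2$adj.r.squared
    if (length(adj) != 1 || is.na(adj)) {
      # Ezekiel adjustment with conditioning degrees of freedom removed
      n <- attr(dd, "Size")
      m <- fit$CCA$qrank
      q <- if (is.null(fit$pCCA)) 0 else fit$pCCA$QR$rank
      adj <- 1 - (1 - r2$r.squared) * (n - 1 - q) / (n - 1 - q - m)
    }
  }
  if (nperm > 0 && !rank0) {
    an <- vegan::anova.cca(fit, permutations = nperm)
    f_obs <- an$F[1]; p_obs <- an[["Pr(>F)"]][1]
    if ((is.na(f_obs) || is.na(p_obs)) && r2$r.squared >= 1 - 1e-8) {
      # perfect fit: zero residual inertia, no permutation can beat it
      f_obs <- Inf
      p_obs <- 1 / (nperm + 1)
    }
  } else {
    f_obs <- NA_real_; p_obs <- NA_real_
  }
  structure(list(
    vegan_fit = fit,
    constraints = constraints, conditionals = conditionals %||% character(),
    R2 = r2$r.squared, adjR2 = adj,
    F = f_obs, p = p_obs, nperm = nperm,
    site_scores = local({
      sc <- vegan::scores(fit, display = "sites",
                          choices = seq_len(max(1, min(2, fit$CCA$rank))))
      tibble::as_tibble(sc) |>
        dplyr::mutate(pop = rownames(unclass(response)), .before = 1)
    }),
    biplot_scores = local({
      bp <- fit$CCA$biplot
      if (is.null(bp)) tibble::tibble() else
        tibble::as_tibble(bp, rownames = "variable")
    })),
    class = "dbrda_fit")
}

#' @export
print.dbrda_fit <- function(x, ...) {
  cond <- if (length(x$conditionals))
    paste0(" | (", paste(x$conditionals, collapse = " + "), ")") else ""
  cat(sprintf("<dbrda_fit> response ~ %s%s\n  R2 = %.4f, adjR2 = %.4f, F = %.3f, p = %.4g (%d perms)\n",
              paste(x$constraints, collapse = " + "), cond,
              x$R2, x$adjR2, x$F, x$p, x$nperm))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.dbrda_fit <- function(x, ...) {
  tibble::tibble(R2 = x$R2, adjR2 = x$adjR2, statistic = x$F, p.value = x$p,
                 nperm = x$nperm,
                 n_constraints = length(x$constraints),
                 n_conditionals = length(x$conditionals))
}

#' @exportS3Method generics::tidy
tidy.dbrda_fit <- function(x, ...) x$site_scores

#' @exportS3Method ggplot2::autoplot
autoplot.dbrda_fit <- function(object, ...) {
  sc <- object$site_scores
  axes <- setdiff(names(sc), "pop")[1:2]
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[axes[1]]],
                                        y = .data[[axes[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$pop), vjust = -0.6, size = 3)
  if (nrow(object$biplot_scores)) {
    bp <- object$biplot_scores
    mult <- max(abs(sc[[axes[1]]]), abs(sc[[axes[2]]])) /
      max(abs(bp[[2]]), abs(bp[[3]]), 1e-9)
    p <- p + ggplot2::geom_segment(
      data = bp,
      ggplot2::aes(x = 0, y = 0, xend = .data[[names(bp)[2]]] * mult,
                   yend = .data[[names(bp)[3]]] * mult),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
      ggplot2::geom_text(
        data = bp,
        ggplot2::aes(x = .data[[names(bp)[2]]] * mult,
                     y = .data[[names(bp)[3]]] * mult,
                     label = .data$variable),
        colour = "firebrick", vjust = -0.5, size = 3)
  }
  p + ggplot2::labs(x = axes[1], y = axes[2])
}

#' Permutation test of a fitted dbRDA
#'
#' Re-runs the pseudo-F permutation test with a chosen number of
#' permutations; rows/columns of the response are permuted simultaneously
#' (residuals of the reduced model when conditionals are present). The
#' returned p is (#F_perm >= F_obs + 1)/(nperm + 1), so it is never 0.
#'
#' @param model a `dbrda_fit`
#' @param nperm number of permutations (>= 99)
#' @return the permutation p-value
#' @export
permutation_anova <- function(model, nperm = 999) {
  stopifnot(nperm >= 99)
  an <- vegan::anova.cca(model$vegan_fit, permutations = nperm)
  an[["Pr(>F)"]][1]
}

#' Forward selection of dbRDA predictors
#'
#' Greedy addition: at each step the candidate with the largest adjusted-R2
#' gain is tested by a marginal permutation test (candidate conditioned on
#' the current selection); selection stops when the best candidate's p is
#' at or above `alpha`, or when the cumulative adjusted R2 of the selection
#' exceeds the adjusted R2 of the global model containing all candidates
#' (the double stopping rule). Ties in adjusted-R2 gain break
#' lexicographically on the column name.
#'
#' @param response a `dist_matrix`
#' @param data data frame with `pop` and candidate columns
#' @param candidates character vector of candidate column names
#' @param alpha significance threshold for entry
#' @param nperm permutations per entry test
#' @return tibble of selected columns in entry order: `step`, `variable`,
#'   `adjR2_cum`, `p`; zero rows when nothing qualifies
#' @export
forward_select <- function(response, data, candidates, alpha = 0.01,
                           nperm = 9999) {
  stopifnot(length(candidates) >= 1)
  data <- align_to_response(response, data)
  # drop exact duplicates of earlier candidates up front (aliasing)
  keep <- !duplicated(lapply(candidates, function(v) round(data[[v]], 12)))
  candidates <- candidates[keep]
  global <- dbrda_fit(response, data, candidates, nperm = 0)$adjR2
  selected <- character()
  rows <- list()
  adj_prev <- 0
  repeat {
    remaining <- sort(setdiff(candidates, selected))
    if (!length(remaining)) break
    gains <- vapply(remaining, function(v) {
      dbrda_fit(response, data, c(selected, v), nperm = 0)$adjR2
    }, numeric(1))
    best <- remaining[which.max(gains)]  # first max = lexicographic tie-break
    # marginal test of the best candidate given the current selection
    ptest <- dbrda_fit(response, data, best,
                       conditionals = if (length(selected)) selected else NULL,
                       nperm = nperm)
    if (ptest$p >= alpha) break
    selected <- c(selected, best)
    adj_prev <- gains[[best]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = length(selected), variable = best, adjR2_cum = adj_prev,
      p = ptest$p)
    if (adj_prev > global) break
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(step = integer(), variable = character(),
                   adjR2_cum = numeric(), p = numeric())
}

#' dbRDA variance partitioning across predictor blocks
#'
#' Fits the full model on all blocks, then for each block a partial dbRDA
#' of that block conditioned on all the others ("pure" fraction). The
#' confounded fraction of each row is the full explained fraction minus
#' the pure fraction, and the unexplained fraction is one minus the full
#' explained fraction, so pure + confounded + unexplained = 1 by
#' construction. With `cascade = TRUE`, blocks whose pure effect is not
#' significant at `drop_alpha` are removed one at a time (least
#' significant first) and the reduced full models are refitted, producing
#' the staged model-I/II/... table.
#'
#' @param response a `dist_matrix`
#' @param data data frame with `pop` and all predictor columns
#' @param blocks named list mapping block label to its column names,
#'   e.g. `list(clim = c("bio15"), geo = c("lon", "lat"))`
#' @param nperm permutations per test
#' @param cascade drop non-significant blocks and refit?
#' @param drop_alpha significance level used by the cascade
#' Each pure row also reports the block's unconditioned R2 (`alone`) and
#' the classical shared fraction `shared = alone - pure`, which is zero
#' for orthogonal blocks; `confounded` follows the staged-table
#' convention (everything the full model explains beyond the block's pure
#' effect), so that pure + confounded + unexplained = 1.
#'
#' @return tibble of class `partition_table`: `stage`, `model`, `block`,
#'   `adjR2`, `p`, `explained`, `unexplained`, `confounded`, `alone`,
#'   `shared`
#' @export
variance_partition <- function(response, data, blocks, nperm = 999,
                               cascade = FALSE, drop_alpha = 0.05) {
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)))
  data <- align_to_response(response, data)
  one_stage <- function(blocks, stage) {
    all_cols <- unlist(blocks, use.names = FALSE)
    full <- dbrda_fit(response, data, all_cols, nperm = nperm)
    rows <- list(tibble::tibble(
      stage = stage, model = "full", block = paste(names(blocks), collapse = "+"),
      adjR2 = full$adjR2, p = full$p, explained = full$R2,
      unexplained = 1 - full$R2, confounded = NA_real_))
    if (length(blocks) > 1) {
      for (b in names(blocks)) {
        others <- unlist(blocks[setdiff(names(blocks), b)], use.names = FALSE)
        pure <- dbrda_fit(response, data, blocks[[b]],
                          conditionals = others, nperm = nperm)
        alone <- dbrda_fit(response, data, blocks[[b]], nperm = 0)$R2
        rows[[length(rows) + 1]] <- tibble::tibble(
          stage = stage, model = paste0("pure_", b), block = b,
          adjR2 = pure$adjR2, p = pure$p, explained = pure$R2,
          unexplained = 1 - full$R2, confounded = full$R2 - pure$R2,
          alone = alone, shared = alone - pure$R2)
      }
    }
    dplyr::bind_rows(rows)
  }
  out <- one_stage(blocks, stage = 1L)
  if (cascade) {
    stage <- 1L
    current <- blocks
    while (length(current) > 1) {
      pure_rows <- out[out$stage == stage & out$model != "full", ]
      worst <- pure_rows[which.max(pure_rows$p), ]
      if (worst$p < drop_alpha) break
      current <- current[setdiff(names(current), worst$block)]
      stage <- stage + 1L
      out <- dplyr::bind_rows(out, one_stage(current, stage))
    }
  }
  class(out) <- c("partition_table", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.partition_table <- function(object, ...) {
  df <- object[object$model != "full", ]
  df <- tidyr::pivot_longer(
    df[c("stage", "block", "explained", "confounded")],
    cols = c("explained", "confounded"),
    names_to = "fraction", values_to = "value")
  df$fraction[df$fraction == "explained"] <- "pure"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$value,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~stage, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "Fraction of total variance", x = "Predictor block")
}
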
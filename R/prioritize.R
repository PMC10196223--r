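#' Population-by-allele incidence matrix
#'
#' Logical matrix recording which (locus, allele-size) combinations occur
#' in which population; the input to complementarity-based reserve
#' selection. Alleles absent everywhere cannot occur by construction.
#'
#' @param gt a `genotype_table`
#' @return logical matrix, rows = populations, columns = `locus:size`
#' @export
allele_incidence <- function(gt) {
  gt <- as_genotype_table(gt)
  long <- tidyr::pivot_longer(gt, c("allele1", "allele2"),
                              values_to = "allele")
  long <- long[!is.na(long$allele), ]
  long$id <- paste0(long$locus, ":", long$allele)
  pops <- gt_pops(gt)
  ids <- sort(unique(long$id))
  inc <- matrix(FALSE, length(pops), length(ids),
                dimnames = list(pops, ids))
  inc[cbind(match(long$pop, pops), match(long$id, ids))] <- TRUE
  inc
}

#' Greedy allele-complementarity reserve selection
#'
#' Repeatedly selects the population covering the largest number of
#' still-uncovered alleles (ties broken by population label order) until
#' every allele is covered or the iteration cap is reached. Coverage is
#' non-decreasing and reaches 100% whenever the full population set
#' covers all alleles.
#'
#' @param inc incidence matrix from [allele_incidence()]
#' @param weights optional per-allele weights (default equal)
#' @param max_iter iteration cap
#' @return tibble: `step`, `pop`, `gain` (newly covered), `covered`
#'   (cumulative count), `coverage` (fraction of all alleles)
#' @export
reserve_selection <- function(inc, weights = NULL, max_iter = 100) {
  if (!ncol(inc)) return(tibble::tibble(
    step = integer(), pop = character(), gain = numeric(),
    covered = numeric(), coverage = numeric()))
  w <- weights %||% rep(1, ncol(inc))
  uncovered <- rep(TRUE, ncol(inc))
  total <- sum(w)
  remaining <- sort(rownames(inc))
  rows <- list()
  while (any(uncovered) && length(remaining) && length(rows) < max_iter) {
    gains <- vapply(remaining, function(p) sum(w[inc[p, ] & uncovered]),
                    numeric(1))
    if (max(gains) == 0) break
    best <- remaining[which.max(gains)]  # first max = label-order tie-break
    uncovered <- uncovered & !inc[best, ]
    remaining <- setdiff(remaining, best)
    rows[[length(rows) + 1]] <- tibble::tibble(
      step = length(rows) + 1L, pop = best, gain = max(gains),
      covered = total - sum(w[uncovered]),
      coverage = (total - sum(w[uncovered])) / total)
  }
  dplyr::bind_rows(rows)
}

#' Forest-cover fraction around a point
#'
#' Area-weighted mean of a fraction-valued forest raster over the cells
#' whose centers fall within a geodesic circle of `radius_km` around the
#' point — a surrogate for forest continuity around a population.
#'
#' @param forest `raster_grid` with values in [0, 1]
#' @param lon,lat circle center
#' @param radius_km circle radius in kilometres
#' @return forest fraction in [0, 1]
#' @export
forest_fraction <- function(forest, lon, lat, radius_km = 20) {
  lons <- grid_lon(forest); lats <- grid_lat(forest)
  if (lon < forest$xll || lon > forest$xll + length(lons) * forest$cellsize ||
      lat < forest$yll || lat > forest$yll + length(lats) * forest$cellsize)
    stop("point outside raster extent")
  grid_pts <- cbind(rep(lons, each = length(lats)), rep(lats, length(lons)))
  d <- geosphere::distHaversine(c(lon, lat), grid_pts) / 1000
  sel <- matrix(d <= radius_km, length(lats), length(lons))
  sel <- sel & !is.na(forest$values)
  if (!any(sel)) stop("no data cells within the circle")
  a <- cell_area_km2(forest)
  sum(forest$values[sel] * a[sel]) / sum(a[sel])
}

#' Climate-shift factor between current and future climate
#'
#' For each variable v, the relative absolute change
#' rho_v = |future_v - current_v| / current_v is computed; the factor is
#' the geometric mean of the terms (1 + rho_v). It equals 1 under no
#' change and grows with the projected shift, so it discounts the
#' conservation index of climatically unstable sites.
#'
#' @param current,future named numeric vectors of the same variables
#'   (conventionally bio18 and bio19); current values must be positive
#' @return the climate-shift factor (>= 1)
#' @export
climate_shift_factor <- function(current, future) {
  stopifnot(length(current) == length(future), length(current) >= 1)
  if (any(current <= 0)) stop("current climate values must be positive")
  rho <- abs(future - current) / current
  prod(1 + rho)^(1 / length(rho))
}

#' Conservation index
#'
#' C_i = A_r * F_c / C_l: allelic richness times forest continuity,
#' discounted by the projected climate shift. Strictly increasing in
#' richness and forest cover, strictly decreasing in the shift factor.
#'
#' @param A_r allelic richness (> 0)
#' @param F_c forest-cover fraction in [0, 1]
#' @param C_l climate-shift factor (> 0, conventionally >= 1)
#' @return the conservation index
#' @export
conservation_index <- function(A_r, F_c, C_l) {
  stopifnot(all(A_r > 0), all(F_c >= 0), all(F_c <= 1))
  if (any(C_l <= 0)) stop("climate-shift factor must be positive")
  A_r * F_c / C_l
}

#' Assign 1-5 conservation categories from index values
#'
#' Two binning rules are available. `"interval"` (default) bins the index
#' into unit-width intervals anchored at integers: category 1 is
#' C_i > k - 1, category j is (k - j, k - j + 1], and the lowest category
#' k collects C_i <= 1; with the default k = 5 this reproduces the
#' published category memberships of the index's reference application.
#' `"equal_rank"` sorts by C_i (descending, ties by label) and splits
#' into k groups as equal in size as possible, larger groups first.
#'
#' @param records tibble with `pop` and `C_i` columns
#' @param k number of categories
#' @param method `"interval"` or `"equal_rank"`
#' @return `records` with an integer `category` column (1 = highest
#'   priority)
#' @export
rank_categories <- function(records, k = 5,
                            method = c("interval", "equal_rank")) {
  method <- match.arg(method)
  ci <- records$C_i
  if (method == "interval") {
    cat <- k - pmin(k - 1, pmax(0, ceiling(ci) - 1))
  } else {
    stopifnot(nrow(records) >= k)
    ord <- order(-ci, records$pop)
    n <- length(ci)
    base <- n %/% k; extra <- n %% k
    sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
    cat <- integer(n)
    cat[ord] <- rep(seq_len(k), sizes)
  }
  dplyr::mutate(records, category = as.integer(cat))
}

#' Build the full prioritization table for a set of populations
#'
#' Combines rarefied allelic richness, forest continuity within a radius,
#' and the climate-shift factor at each site into the conservation index
#' and its category.
#'
#' @param gt a `genotype_table`
#' @param sites tibble with `pop`, `lon`, `lat`
#' @param forest forest-cover `raster_grid`
#' @param climate_current,climate_future `climate_stack`s
#' @param shift_vars climate variables entering the shift factor
#' @param radius_km forest-continuity radius
#' @param g rarefaction size passed to [diversity()]
#' @param k number of priority categories
#' @param method binning rule passed to [rank_categories()]
#' @return tibble of class `priority_table`: `pop`, `A_r`, `F_c`, `C_l`,
#'   `C_i`, `category`
#' @export
prioritize_populations <- function(gt, sites, forest, climate_current,
                                   climate_future,
                                   shift_vars = c("bio18", "bio19"),
                                   radius_km = 20, g = NULL, k = 5,
                                   method = "interval") {
  div <- diversity(gt, g = g)
  cur <- extract_climate(climate_current, sites, shift_vars)
  fut <- extract_climate(climate_future, sites, shift_vars)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    p <- sites$pop[i]
    fc <- forest_fraction(forest, sites$lon[i], sites$lat[i], radius_km)
    cl <- climate_shift_factor(
      unlist(cur[cur$pop == p, shift_vars]),
      unlist(fut[fut$pop == p, shift_vars]))
    ar <- div$A_r[div$pop == p]
    tibble::tibble(pop = p, A_r = ar, F_c = fc, C_l = cl,
                   C_i = conservation_index(ar, fc, cl))
  })
  out <- rank_categories(dplyr::bind_rows(rows), k = k, method = method)
  class(out) <- c("priority_table", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.priority_table <- function(object, sites = NULL, ...) {
  df <- object
  if (!is.null(sites)) df <- dplyr::left_join(df, sites, by = "pop")
  if (all(c("lon", "lat") %in% names(df))) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                     colour = factor(.data$category),
                                     size = .data$C_i)) +
      ggplot2::geom_point() +
      ggplot2::geom_text(ggplot2::aes(label = .data$pop), vjust = -0.8,
                         size = 3, show.legend = FALSE) +
      ggplot2::scale_colour_brewer(palette = "RdYlGn", direction = 1,
                                   name = "Category") +
      ggplot2::labs(x = "Longitude", y = "Latitude", size = "C_i")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$pop, -.data$C_i),
                                     y = .data$C_i,
                                     fill = factor(.data$category))) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Population", y = "Conservation index",
                    fill = "Category")
  }
}

#' Write a priority table as GeoJSON points
#'
#' One point feature per population with the index components and the
#' category as properties, for mapping in any GIS.
#'
#' @param records a `priority_table` (see [prioritize_populations()])
#' @param sites tibble with `pop`, `lon`, `lat`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_priority_geojson <- function(records, sites, path) {
  df <- dplyr::left_join(records, sites[c("pop", "lon", "lat")], by = "pop")
  features <- lapply(seq_len(nrow(df)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(df$lon[i], df$lat[i])),
    properties = list(pop = df$pop[i], A_r = df$A_r[i], F_c = df$F_c[i],
                      C_l = df$C_l[i], C_i = df$C_i[i],
                      category = df$category[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
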
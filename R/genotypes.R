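#' Genotype tables
#'
#' Diploid microsatellite genotypes are carried as a long tibble with one
#' row per individual and locus: columns `individual`, `pop`, `locus`,
#' `allele1`, `allele2` (allele sizes in base pairs, `NA` = missing).
#' `as_genotype_table()` validates and normalises a data frame into this
#' shape.
#'
#' @param x a data frame with the five columns above.
#' @return a tibble of class `genotype_table`.
#' @export
as_genotype_table <- function(x) {
  need <- c("individual", "pop", "locus", "allele1", "allele2")
  if (!all(need %in% names(x)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  gt <- tibble::as_tibble(x)[need]
  gt$individual <- as.character(gt$individual)
  gt$pop <- as.character(gt$pop)
  gt$locus <- as.character(gt$locus)
  gt$allele1 <- as.integer(gt$allele1)
  gt$allele2 <- as.integer(gt$allele2)
  if (any(gt$pop == "" | is.na(gt$pop))) stop("population labels must be non-empty")
  bad <- (!is.na(gt$allele1) & gt$allele1 <= 0) |
    (!is.na(gt$allele2) & gt$allele2 <= 0)
  if (any(bad)) stop("allele sizes must be positive or missing")
  n_per <- dplyr::count(gt, .data$individual, .data$locus)
  if (any(n_per$n != 1))
    stop("each individual must have exactly one row per locus")
  class(gt) <- c("genotype_table", class(gt))
  gt
}

gt_loci <- function(gt) sort(unique(gt$locus))
gt_pops <- function(gt) unique(gt$pop)

#' Gene copies at one locus, by population
#'
#' @return named list (by pop) of integer allele-size vectors with missing
#'   alleles removed.
#' @noRd
gene_copies <- function(gt, locus) {
  # a genotype is used only when both copies are scored, so the returned
  # vector keeps the (1..n, n+1..2n) genotype pairing
  sub <- gt[gt$locus == locus & !is.na(gt$allele1) & !is.na(gt$allele2), ]
  split(c(sub$allele1, sub$allele2), rep(sub$pop, 2))
}

#' Write genotypes in GENEPOP format
#'
#' Three digits per allele (six characters per diploid genotype),
#' `000000` for missing; one `POP` block per population, individuals as
#' `id ,  g1 g2 ...` in locus-list order.
#'
#' @param gt a genotype table
#' @param path output path
#' @param title first line of the file
#' @return `path`, invisibly
#' @export
write_genepop <- function(gt, path, title = "priogen genotypes") {
  gt <- as_genotype_table(gt)
  loci <- gt_loci(gt)
  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  wide <- gt |>
    dplyr::mutate(g = paste0(code(.data$allele1), code(.data$allele2))) |>
    dplyr::select("individual", "pop", "locus", "g") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "g")
  lines <- c(title, loci)
  for (p in unique(wide$pop)) {
    lines <- c(lines, "POP")
    sub <- wide[wide$pop == p, ]
    lines <- c(lines, paste0(sub$individual, " ,  ",
                             apply(sub[loci], 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file (three-digit allele dialect)
#'
#' Population labels are taken from the last individual id of each `POP`
#' block's prefix when ids look like `pop_ind`; otherwise populations are
#' labelled `pop1`, `pop2`, ... in file order.
#'
#' @param path file path
#' @return a `genotype_table`
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP line")
  loci <- trimws(lines[2:(first_pop - 1)])
  # comma-separated locus list on one line is also legal
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  pop_id <- cumsum(is_pop)
  rows <- list()
  for (i in seq_along(lines)) {
    if (i < first_pop || is_pop[i] || trimws(lines[i]) == "") next
    parts <- strsplit(lines[i], ",")[[1]]
    id <- trimws(parts[1])
    genos <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(genos) != length(loci))
      stop("individual ", id, " has ", length(genos), " genotypes, expected ",
           length(loci))
    a1 <- as.integer(substr(genos, 1, 3))
    a2 <- as.integer(substr(genos, 4, 6))
    a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
    rows[[length(rows) + 1]] <- tibble::tibble(
      individual = id, pop_block = pop_id[i], locus = loci,
      allele1 = a1, allele2 = a2)
  }
  out <- dplyr::bind_rows(rows)
  # prefer an id prefix "pop_ind" as the population label
  pref <- sub("_[^_]*$", "", out$individual)
  has_pref <- grepl("_", out$individual)
  out$pop <- ifelse(has_pref, pref, paste0("pop", out$pop_block))
  as_genotype_table(out[c("individual", "pop", "locus", "allele1", "allele2")])
}

#' Write genotypes in STRUCTURE two-row format
#'
#' Each individual occupies two rows (one per allele copy):
#' `id pop a_locus1 a_locus2 ...`, missing coded `-9`. A header row lists
#' locus names.
#'
#' @inheritParams write_genepop
#' @export
write_structure <- function(gt, path) {
  gt <- as_genotype_table(gt)
  loci <- gt_loci(gt)
  w1 <- tidyr::pivot_wider(gt[c("individual", "pop", "locus", "allele1")],
                           names_from = "locus", values_from = "allele1")
  w2 <- tidyr::pivot_wider(gt[c("individual", "pop", "locus", "allele2")],
                           names_from = "locus", values_from = "allele2")
  fmt <- function(w) {
    m <- as.matrix(w[loci]); m[is.na(m)] <- -9L
    paste(w$individual, w$pop, apply(m, 1, paste, collapse = " "))
  }
  body <- as.vector(rbind(fmt(w1), fmt(w2)))
  writeLines(c(paste(loci, collapse = " "), body), path)
  invisible(path)
}

#' Read a STRUCTURE two-row file written by [write_structure()]
#' @param path file path
#' @return a `genotype_table`
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1][trimws(lines[-1]) != ""]
  if (length(body) %% 2 != 0) stop("odd number of genotype rows")
  parse_row <- function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    list(id = parts[1], pop = parts[2],
         alleles = as.integer(parts[-(1:2)]))
  }
  rows <- lapply(body, parse_row)
  out <- list()
  for (i in seq(1, length(rows), by = 2)) {
    r1 <- rows[[i]]; r2 <- rows[[i + 1]]
    if (r1$id != r2$id) stop("row pair mismatch at individual ", r1$id)
    a1 <- r1$alleles; a2 <- r2$alleles
    a1[a1 == -9L] <- NA; a2[a2 == -9L] <- NA
    out[[length(out) + 1]] <- tibble::tibble(
      individual = r1$id, pop = r1$pop, locus = loci,
      allele1 = a1, allele2 = a2)
  }
  as_genotype_table(dplyr::bind_rows(out))
}
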
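#' Per-pool maximum-coverage thresholds from a sync table
#'
#' The maximum-coverage filter removes positions whose coverage exceeds the
#' given percentile of that pool's genome-wide coverage distribution,
#' guarding against mismapping and duplications. Coverage is the SNP read
#' depth `A + T + C + G`; `N` and deletion counts are excluded. The
#' percentile is computed per pool over all records of the sync table, not
#' just marker positions.
#'
#' @param sync Long sync tibble from [read_sync()].
#' @param q Percentile, default 0.95 (nearest-rank, see
#'   [coverage_percentile()]).
#' @return Tibble `pool`, `max_coverage`.
#' @export
pool_coverage_threshold <- function(sync, q = 0.95) {
  sync |>
    dplyr::mutate(coverage = A + .data$T + C + G) |>
    dplyr::group_by(pool) |>
    dplyr::summarise(max_coverage = coverage_percentile(coverage, q), .groups = "drop")
}

#' Estimate inversion frequencies from pooled allele counts
#'
#' For each pool and inversion, the inversion frequency is the arithmetic
#' mean over marker SNPs of the inverted-allele frequency, where each
#' marker's frequency is its inverted-allele count divided by the total SNP
#' coverage (`A+T+C+G`) at that position. Markers with coverage below
#' `min_coverage` or above the pool's genome-wide `max_coverage_quantile`
#' percentile are dropped before averaging, as are markers absent from the
#' sync table (their number is reported via a message). A pool/inversion
#' combination in which no marker survives yields an explicit `NA`
#' frequency, never 0.
#'
#' The default `min_coverage` of 10 suits typical Pool-Seq depths; for
#' low-coverage data sets a threshold of 3 is the customary relaxation.
#'
#' @param sync Long sync tibble from [read_sync()].
#' @param markers Marker tibble (see [read_marker_table()]).
#' @param min_coverage Minimum SNP coverage per marker, default 10.
#' @param max_coverage_quantile Genome-wide coverage percentile above which
#'   positions are dropped, default 0.95; computed per pool from the full
#'   sync table.
#' @param weighted If `TRUE`, average marker frequencies weighted by
#'   coverage instead of the default unweighted mean.
#' @param per_marker If `TRUE`, return the per-marker detail table instead
#'   of the per-pool summary.
#' @return Tibble `pool`, `inversion`, `n_markers` (markers used),
#'   `frequency`; or, with `per_marker = TRUE`, one row per (pool, marker)
#'   with `coverage`, `inverted_count`, `frequency`, `used` and `reason`.
#' @examples
#' mk <- tibble::tibble(inversion = "In(2L)t", chrom = "2L", pos = c(100L, 200L),
#'                      inverted_allele = c("A", "G"), other_allele = c("C", "T"))
#' sy <- sim_pool_counts(mk, truth_freq = c(0.3, 0.6), mean_coverage = 50, seed = 1)
#' estimate_inversion_frequency(sy, mk)
#' @export
estimate_inversion_frequency <- function(sync, markers,
                                         min_coverage = 10,
                                         max_coverage_quantile = 0.95,
                                         weighted = FALSE,
                                         per_marker = FALSE) {
  stopifnot(min_coverage >= 1, max_coverage_quantile > 0, max_coverage_quantile < 1)
  thr <- pool_coverage_threshold(sync, max_coverage_quantile)

  joined <- dplyr::inner_join(markers, sync, by = c("chrom", "pos"),
                              relationship = "many-to-many")
  n_missing <- nrow(markers) - nrow(dplyr::distinct(
    dplyr::semi_join(markers, sync, by = c("chrom", "pos")),
    inversion, chrom, pos))
  if (n_missing > 0) {
    message(n_missing, " marker(s) absent from the sync table were dropped")
  }

  cnt <- as.matrix(joined[, c("A", "T", "C", "G")])
  detail <- joined |>
    dplyr::mutate(
      coverage = as.integer(rowSums(cnt)),
      inverted_count = cnt[cbind(seq_len(nrow(cnt)),
                                 match(joined$inverted_allele, c("A", "T", "C", "G")))],
      frequency = ifelse(coverage > 0, inverted_count / coverage, NA_real_)
    ) |>
    dplyr::left_join(thr, by = "pool") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        coverage < min_coverage ~ "low_coverage",
        coverage > max_coverage ~ "high_coverage",
        TRUE ~ NA_character_),
      used = is.na(reason)
    ) |>
    dplyr::select(pool, inversion, chrom, pos, coverage, inverted_count,
                  frequency, used, reason)
  if (per_marker) return(detail)

  grid <- tidyr::expand_grid(pool = sort(unique(sync$pool)),
                             inversion = unique(markers$inversion))
  est <- detail |>
    dplyr::filter(used) |>
    dplyr::group_by(pool, inversion) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      frequency = if (weighted) sum(frequency * coverage) / sum(coverage)
                  else mean(frequency),
      .groups = "drop")
  dplyr::left_join(grid, est, by = c("pool", "inversion")) |>
    dplyr::mutate(n_markers = ifelse(is.na(n_markers), 0L, n_markers)) |>
    dplyr::arrange(pool, inversion)
}

#' Inversion frequencies from karyotype counts
#'
#' Computes `count / n` per population and inversion from a cytological
#' karyotype count table, at full precision; rounding is left to output
#' formatting.
#'
#' @param karyo Long karyotype tibble from [read_karyotype_counts()].
#' @param population,inversion Optional filters; with both supplied the
#'   result is a single row. Unknown values raise an error.
#' @return Tibble `population`, `n`, `inversion`, `count`, `frequency`.
#' @export
karyotype_frequency <- function(karyo, population = NULL, inversion = NULL) {
  if (!is.null(population)) {
    if (!all(population %in% karyo$population)) {
      stop("unknown population: ",
           paste(setdiff(population, karyo$population), collapse = ", "))
    }
    karyo <- karyo[karyo$population %in% population, ]
  }
  if (!is.null(inversion)) {
    if (!all(inversion %in% karyo$inversion)) {
      stop("unknown inversion: ",
           paste(setdiff(inversion, karyo$inversion), collapse = ", "))
    }
    karyo <- karyo[karyo$inversion %in% inversion, ]
  }
  dplyr::mutate(karyo, frequency = count / n)
}
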
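#' Find inversion-diagnostic fixed differences in a karyotyped panel
#'
#' Scans the chromosome arm carrying `inversion` for positions where every
#' informative chromosome carrying the inversion shares one allele, every
#' informative chromosome of all other arrangements on the same arm
#' (standard plus overlapping inversions, pooled) shares another, and the two
#' alleles differ. A position is only considered when at least
#' `informative_min` of the chromosomes in each arrangement class carry a
#' non-missing allele there; missing data counts against informativeness but
#' never breaks fixation, which is evaluated over non-missing chromosomes
#' only. Fixed differences are biallelic by definition, so sites showing more
#' than two alleles across the pooled comparison are excluded.
#'
#' @param panel Long haplotype panel: tibble with columns `hap_id`,
#'   `karyotype`, `chrom`, `pos`, `allele` (`NA` = missing). Chromosome
#'   labels are arm names (`"2L"`, `"3R"`, ...).
#' @param inversion Inversion name whose karyotype label identifies the
#'   inverted class; all other karyotypes on the same arm form the
#'   non-inverted class.
#' @param informative_min Minimum informative fraction per arrangement
#'   class, default 0.80.
#' @param arm Arm to scan; defaults to the arm parsed from the inversion
#'   name.
#' @return Marker tibble: `inversion`, `chrom`, `pos`, `inverted_allele`,
#'   `other_allele`, ordered by position.
#' @examples
#' p <- sim_haplotype_panel(n_standard = 8, n_inverted = 4, n_planted = 5,
#'                          n_shared = 50, arm_length = 1e4, seed = 1)
#' find_fixed_differences(p$panel, "In(3R)C")
#' @export
find_fixed_differences <- function(panel, inversion, informative_min = 0.80,
                                   arm = inversion_arm(inversion)) {
  if (is.na(arm)) stop("cannot parse arm from inversion name; supply `arm`")
  arm_tbl <- panel[panel$chrom == arm, ]
  haps <- dplyr::distinct(arm_tbl, hap_id, karyotype)
  n_inv <- sum(haps$karyotype == inversion)
  n_oth <- sum(haps$karyotype != inversion)
  if (n_inv == 0) stop("no chromosomes carrying ", inversion, " in the panel")
  if (n_oth == 0) stop("no non-inverted chromosomes on arm ", arm)

  obs <- arm_tbl[!is.na(arm_tbl$allele), ]
  obs$grp <- ifelse(obs$karyotype == inversion, "inv", "oth")
  s <- obs |>
    dplyr::group_by(pos, grp) |>
    dplyr::summarise(n_inf = dplyr::n(),
                     k_alleles = dplyr::n_distinct(allele),
                     a_first = allele[1], .groups = "drop") |>
    tidyr::pivot_wider(names_from = grp,
                       values_from = c(n_inf, k_alleles, a_first),
                       values_fill = list(n_inf = 0L))

  need <- c("n_inf_inv", "n_inf_oth", "k_alleles_inv", "k_alleles_oth",
            "a_first_inv", "a_first_oth")
  for (col in setdiff(need, names(s))) s[[col]] <- if (grepl("^n_inf", col)) 0L else NA
  ok <- s$n_inf_inv >= informative_min * n_inv &
    s$n_inf_oth >= informative_min * n_oth &
    s$k_alleles_inv == 1 & s$k_alleles_oth == 1 &
    s$a_first_inv != s$a_first_oth
  ok[is.na(ok)] <- FALSE

  tibble::tibble(
    inversion = inversion, chrom = arm,
    pos = as.integer(s$pos[ok]),
    inverted_allele = s$a_first_inv[ok],
    other_allele = s$a_first_oth[ok]
  ) |> dplyr::arrange(pos)
}

#' Bin markers into nonoverlapping windows along an arm
#'
#' Counts diagnostic SNPs in nonoverlapping windows tiling the chromosome
#' arm from position 1, the binning used to visualise whether markers
#' cluster at the inversion breakpoints or spread through the inverted
#' region.
#'
#' @param markers Marker tibble (see [find_fixed_differences()]).
#' @param window Window size in bp, default 100 kb.
#' @param chrom_length Arm length in bp; windows tile `[1, chrom_length]`.
#'   Defaults to the largest marker position.
#' @return Tibble `chrom`, `win_start`, `win_end`, `n_markers`, one row per
#'   window including empty ones.
#' @export
summarize_marker_distribution <- function(markers, window = 1e5,
                                          chrom_length = NULL) {
  stopifnot(window > 0)
  chrom_length <- chrom_length %||%
    (if (nrow(markers)) max(markers$pos) else window)
  n_win <- ceiling(chrom_length / window)
  chromv <- if (nrow(markers)) markers$chrom[1] else NA_character_
  grid <- tibble::tibble(
    chrom = chromv,
    win = seq_len(n_win),
    win_start = as.integer((seq_len(n_win) - 1) * window + 1),
    win_end = as.integer(pmin(seq_len(n_win) * window, chrom_length))
  )
  counts <- markers |>
    dplyr::mutate(win = (pos - 1) %/% window + 1) |>
    dplyr::count(win, name = "n_markers")
  dplyr::left_join(grid, counts, by = "win") |>
    dplyr::mutate(n_markers = ifelse(is.na(n_markers), 0L, n_markers)) |>
    dplyr::select(chrom, win_start, win_end, n_markers)
}

#' Tally markers inside versus outside inversion breakpoints
#'
#' @param markers Marker tibble.
#' @param breakpoints Breakpoint tibble (`inversion`, `chrom`, `start`,
#'   `end`, 1-based inclusive), e.g. from [read_breakpoints()].
#' @return Tibble `inversion`, `n_inside`, `n_outside`.
#' @export
tally_breakpoint_markers <- function(markers, breakpoints) {
  dplyr::inner_join(markers, breakpoints, by = c("inversion", "chrom")) |>
    dplyr::group_by(inversion) |>
    dplyr::summarise(
      n_inside = sum(pos >= start & pos <= end),
      n_outside = sum(pos < start | pos > end),
      .groups = "drop")
}
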
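#' Read a PoPoolation-style sync file
#'
#' The sync format stores per-position, per-pool nucleotide counts: each line
#' holds chromosome, 1-based position, reference base, then one
#' `A:T:C:G:N:del` count column per pool. This dialect is the one emitted by
#' PoPoolation2 (whitespace-separated columns, colon-separated counts).
#'
#' `N` and deletion counts are parsed and carried along but are excluded from
#' allele-frequency denominators downstream, because inversion frequencies are
#' read off SNP allele frequencies.
#'
#' @param path Path to a sync file.
#' @param min_pools Minimum number of pool columns each line must carry.
#' @return A tibble in long format with one row per position and pool:
#'   columns `chrom`, `pos`, `ref`, `pool` (1-based column index), and
#'   integer counts `A`, `T`, `C`, `G`, `N`, `del`.
#' @seealso [write_sync()], [estimate_inversion_frequency()]
#' @export
read_sync <- function(path, min_pools = 1) {
  stopifnot(file.exists(path), min_pools >= 1)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_sync())

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3 + min_pools)) {
    bad <- which(nf < 3 + min_pools)
    stop("sync format error: fewer than ", min_pools, " pool column(s) on line(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])
    stop("sync format error: ragged pool counts (line(s) ",
         paste(head(bad, 5), collapse = ", "), " differ from line 1)")
  }
  n_pools <- nf[1] - 3
  mat <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos) || any(pos < 1)) {
    stop("sync format error: non-positive or non-integer position on line(s) ",
         paste(head(which(is.na(pos) | pos < 1), 5), collapse = ", "))
  }

  out <- vector("list", n_pools)
  for (j in seq_len(n_pools)) {
    parts <- strsplit(mat[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6)) {
      stop("sync format error: count column ", j,
           " is not a 6-tuple A:T:C:G:N:del on line(s) ",
           paste(head(which(lengths(parts) != 6), 5), collapse = ", "))
    }
    cnt <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 6, byrow = TRUE)
    if (anyNA(cnt) || any(cnt < 0)) {
      bad <- which(apply(is.na(cnt) | cnt < 0, 1, any))
      stop("sync format error: negative or non-integer count in pool ", j,
           " on line(s) ", paste(head(bad, 5), collapse = ", "))
    }
    out[[j]] <- tibble::tibble(
      chrom = mat[, 1], pos = pos, ref = mat[, 3], pool = j,
      A = cnt[, 1], T = cnt[, 2], C = cnt[, 3], G = cnt[, 4],
      N = cnt[, 5], del = cnt[, 6]
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, pos, pool)
}

empty_sync <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), pool = integer(),
    A = integer(), T = integer(), C = integer(), G = integer(),
    N = integer(), del = integer()
  )
}

#' Write a sync table
#'
#' Inverse of [read_sync()]: writes the long-format count tibble back to the
#' whitespace/colon sync dialect, one column per pool.
#'
#' @param sync Long-format sync tibble as returned by [read_sync()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  if (nrow(sync) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  wide <- sync |>
    dplyr::mutate(col = paste(A, T, C, G, N, del, sep = ":")) |>
    dplyr::select(chrom, pos, ref, pool, col) |>
    tidyr::pivot_wider(names_from = pool, values_from = col) |>
    dplyr::arrange(chrom, pos)
  lines <- do.call(paste, c(unname(as.list(wide)), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read or write an inversion-marker table
#'
#' Marker tables are TSV files with columns `inversion`, `chrom`, `pos`,
#' `inverted_allele`, `other_allele`: one row per diagnostic SNP, grouped by
#' the inversion it tags. Alleles must be nucleotides and must differ;
#' duplicated (inversion, chrom, pos) triples are rejected.
#'
#' @param path Path to a marker TSV.
#' @return A tibble with one row per marker.
#' @seealso [find_fixed_differences()] which produces marker sets.
#' @export
read_marker_table <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         inversion = "c", chrom = "c", pos = "i",
                         inverted_allele = "c", other_allele = "c"))
  validate_markers(m)
}

#' @rdname read_marker_table
#' @param markers Marker tibble to write.
#' @export
write_marker_table <- function(markers, path) {
  validate_markers(markers)
  readr::write_tsv(markers, path)
  invisible(path)
}

validate_markers <- function(m) {
  req <- c("inversion", "chrom", "pos", "inverted_allele", "other_allele")
  if (!all(req %in% names(m))) {
    stop("marker table must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(m$inverted_allele %in% NUCS) || !all(m$other_allele %in% NUCS)) {
    stop("marker alleles must be one of A, C, G, T")
  }
  if (any(m$inverted_allele == m$other_allele)) {
    stop("marker with identical inverted and other allele at position(s) ",
         paste(head(m$pos[m$inverted_allele == m$other_allele], 5), collapse = ", "))
  }
  dup <- duplicated(m[, c("inversion", "chrom", "pos")])
  if (any(dup)) {
    stop("duplicate marker for (inversion, chrom, pos): ",
         paste(head(paste0(m$inversion[dup], ":", m$pos[dup]), 5), collapse = ", "))
  }
  tibble::as_tibble(m)[, req]
}

#' Convert BED coordinates to 1-based inclusive genomic coordinates
#'
#' BED intervals are 0-based and half-open; all other coordinates in this
#' package are 1-based and inclusive. The conversion adds 1 to the start and
#' leaves the end unchanged.
#'
#' @param start0,end0 BED start/end vectors (0-based half-open).
#' @return Tibble with 1-based inclusive `start` and `end`.
#' @export
bed_to_coords <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  tibble::tibble(start = as.integer(start0 + 1), end = as.integer(end0))
}

#' @rdname bed_to_coords
#' @param start1,end1 1-based inclusive start/end vectors.
#' @export
coords_to_bed <- function(start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  tibble::tibble(start = as.integer(start1 - 1), end = as.integer(end1))
}

#' Read inversion breakpoint intervals from a BED file
#'
#' Breakpoint coordinates are user-supplied configuration, typically taken
#' from the cytological literature; they are never hard-coded. The BED `name`
#' column (4th) carries the inversion name.
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return Tibble with columns `inversion`, `chrom`, `start`, `end` in
#'   1-based inclusive coordinates, `start < end` enforced.
#' @export
read_breakpoints <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, comment = "#")
  if (ncol(b) < 4) stop("breakpoint BED needs 4 columns: chrom, start, end, name")
  cc <- bed_to_coords(as.numeric(b[[2]]), as.numeric(b[[3]]))
  out <- tibble::tibble(inversion = as.character(b[[4]]), chrom = as.character(b[[1]]),
                        start = cc$start, end = cc$end)
  stopifnot(all(out$start < out$end))
  out
}

#' Read or write a karyotype count table
#'
#' Karyotype count tables record, per population, the number of chromosomes
#' sampled (`n`) and the number carrying each inversion, as produced by
#' cytological karyotyping of polytene chromosomes. On disk the table is wide
#' (one column per inversion); in memory it is returned long for tidy
#' computation.
#'
#' @param path Path to a TSV with columns `population`, `n`, then one column
#'   per inversion.
#' @return Long tibble with columns `population`, `n`, `inversion`, `count`.
#' @seealso [karyotype_frequency()]
#' @export
read_karyotype_counts <- function(path) {
  k <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("population", "n") %in% names(k))) {
    stop("karyotype table must have columns 'population' and 'n'")
  }
  long <- tidyr::pivot_longer(k, cols = -c(population, n),
                              names_to = "inversion", values_to = "count")
  long$count <- as.integer(long$count)
  long$n <- as.integer(long$n)
  if (any(long$n <= 0)) stop("karyotype table: n must be positive")
  if (any(long$count < 0) || any(long$count > long$n)) {
    stop("karyotype table: counts must lie in [0, n]")
  }
  long
}

#' @rdname read_karyotype_counts
#' @param karyo Long karyotype tibble as returned by [read_karyotype_counts()].
#' @export
write_karyotype_counts <- function(karyo, path) {
  wide <- tidyr::pivot_wider(karyo, names_from = inversion, values_from = count)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read and write haplotype panels as FASTA
#'
#' A haplotype panel stores one allele call per (haplotype, position); sites
#' filtered during reconstruction are `N` in the FASTA and `NA` in the
#' tibble. The FASTA records one sequence per haplotype over the sorted site
#' list of the panel; positions and karyotype labels are carried in the
#' record description as `chrom pos1,pos2,... karyotype`.
#'
#' @param panel Long panel tibble with columns `hap_id`, `karyotype`,
#'   `chrom`, `pos`, `allele`.
#' @param path File path.
#' @return `read_haplotype_fasta()` returns the long panel tibble;
#'   `write_haplotype_fasta()` returns `path` invisibly.
#' @export
write_haplotype_fasta <- function(panel, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA output")
  }
  panel <- dplyr::arrange(panel, chrom, hap_id, pos)
  recs <- panel |>
    dplyr::group_by(chrom, hap_id, karyotype) |>
    dplyr::summarise(
      seq = paste(ifelse(is.na(allele), "N", allele), collapse = ""),
      posl = paste(pos, collapse = ","), .groups = "drop")
  x <- Biostrings::DNAStringSet(recs$seq)
  names(x) <- paste(paste0(recs$hap_id, "|", recs$chrom),
                    recs$chrom, recs$posl, recs$karyotype)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_haplotype_fasta
#' @export
read_haplotype_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for FASTA input")
  }
  x <- Biostrings::readDNAStringSet(path)
  meta <- strsplit(names(x), " ", fixed = TRUE)
  purrr::map_dfr(seq_along(x), function(i) {
    m <- meta[[i]]
    alle <- strsplit(as.character(x[[i]]), "")[[1]]
    tibble::tibble(
      hap_id = sub("\\|.*$", "", m[1]),
      karyotype = m[4],
      chrom = m[2],
      pos = as.integer(strsplit(m[3], ",", fixed = TRUE)[[1]]),
      allele = ifelse(alle == "N", NA_character_, alle)
    )
  }) |> dplyr::arrange(chrom, pos, hap_id)
}
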
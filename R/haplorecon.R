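#' Nearest-rank percentile of a coverage distribution
#'
#' Returns the smallest observed value such that at least a fraction `q` of
#' observations are less than or equal to it (the "nearest-rank" definition).
#' On integer coverage data this guarantees the threshold is itself an
#' observed coverage value, which keeps filtering reproducible; linear
#' interpolation between order statistics is deliberately not used.
#'
#' @param x Numeric vector of observed coverages.
#' @param q Percentile in (0, 1]; default the 95th.
#' @return Scalar threshold.
#' @export
coverage_percentile <- function(x, q = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty coverage stream")
  stopifnot(q > 0, q <= 1)
  sort(x)[ceiling(q * length(x))]
}

#' Per-larva, per-arm coverage thresholds
#'
#' Computes the genome-wide coverage distribution separately for each F1
#' larva and chromosome arm and returns its nearest-rank percentile, used to
#' filter high-coverage positions that reflect mapping errors or
#' duplications.
#'
#' @param f1 Per-larva site counts: tibble with columns `chrom`, `pos`,
#'   `larva`, and nucleotide counts `A`, `C`, `G`, `T`.
#' @param q Percentile, default 0.95.
#' @return Tibble with columns `larva`, `chrom`, `max_coverage`.
#' @export
per_arm_coverage_percentile <- function(f1, q = 0.95) {
  f1 |>
    dplyr::mutate(coverage = A + C + G + .data$T) |>
    dplyr::group_by(larva, chrom) |>
    dplyr::summarise(max_coverage = coverage_percentile(coverage, q), .groups = "drop")
}

#' Central binomial retention interval for heterozygote calls
#'
#' For a true heterozygote sequenced to depth `n`, each allele's read count
#' is Binomial(n, 1/2). The retention interval is the central equal-tailed
#' exact interval at the given level: counts k with P(X <= k) > alpha/2 and
#' P(X >= k) > alpha/2, boundaries retained. By construction the interval is
#' symmetric about n/2.
#'
#' @param n Integer vector of coverages.
#' @param level Interval mass, default 0.90.
#' @return Tibble with columns `lower` and `upper` (inclusive bounds).
#' @export
binom_retention_bounds <- function(n, level = 0.90) {
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  lo <- qbinom(alpha, n, 0.5)       # smallest k with CDF(k) >= alpha
  tibble::tibble(lower = lo, upper = n - lo)
}

#' Filter F1 sites for paternal haplotype reconstruction
#'
#' Applies, in order, the exclusion of reference-strain polymorphisms
#' (minor-allele frequency above `ref_maf_max` in the reference pool) and
#' five per-site criteria: (i) minimum coverage; (ii) maximum coverage at the
#' per-larva, per-arm percentile threshold; (iii) alleles supported by fewer
#' than `min_allele_total` reads summed across all larvae are dropped;
#' (iv) at sites with more than two surviving alleles only the two most
#' frequent are kept, with a tie between the 2nd and 3rd most frequent
#' flagged and the site filtered; (v) at larvae showing two alleles, both
#' counts must fall inside the central `ci_level` binomial interval for an
#' expected frequency of 1/2 at that larva's retained coverage.
#'
#' @param f1 Tibble `chrom`, `pos`, `larva`, `A`, `C`, `G`, `T` counts.
#' @param coverage_max Per-larva, per-arm thresholds from
#'   [per_arm_coverage_percentile()]; every (larva, chrom) in `f1` must be
#'   covered or an error is raised.
#' @param ref_polymorphisms Optional tibble `chrom`, `pos`, `maf` of
#'   polymorphic positions in the homozygous reference strain's pool.
#' @param ref_maf_max Sites with reference-pool MAF above this are excluded.
#' @param min_coverage Criterion (i) threshold; positions with coverage
#'   below it are filtered.
#' @param min_allele_total Criterion (iii): minimum allele count summed
#'   across all larvae.
#' @param ci_level Criterion (v) interval mass.
#' @return Tibble with one row per (site, larva): `chrom`, `pos`, `larva`,
#'   `coverage`, retained alleles `allele1`/`allele2` with counts
#'   `count1`/`count2` (`allele2` `NA` when one allele survives), `status`
#'   (`"pass"`/`"filtered"`) and the single failing `criterion`
#'   (`"ref_poly"`, `"i"`, `"ii"`, `"iii"`, `"iv"`, `"v"`, or `NA`).
#' @export
filter_f1_sites <- function(f1, coverage_max, ref_polymorphisms = NULL,
                            ref_maf_max = 0.10, min_coverage = 15,
                            min_allele_total = 20, ci_level = 0.90) {
  counts <- as.matrix(f1[, NUCS])
  storage.mode(counts) <- "integer"
  out <- f1 |>
    dplyr::select(chrom, pos, larva) |>
    dplyr::mutate(coverage = as.integer(rowSums(counts)))

  # reference-strain polymorphism exclusion precedes the numbered criteria
  crit <- rep(NA_character_, nrow(out))
  if (!is.null(ref_polymorphisms)) {
    poly <- ref_polymorphisms[ref_polymorphisms$maf > ref_maf_max, ]
    hit <- paste(out$chrom, out$pos) %in% paste(poly$chrom, poly$pos)
    crit[hit] <- "ref_poly"
  }

  # (i) minimum coverage
  crit[is.na(crit) & out$coverage < min_coverage] <- "i"

  # (ii) per-arm maximum coverage percentile
  key <- paste(out$larva, out$chrom)
  thr <- setNames(coverage_max$max_coverage, paste(coverage_max$larva, coverage_max$chrom))
  if (any(!(key %in% names(thr)))) {
    stop("missing per-arm coverage percentile for: ",
         paste(head(unique(key[!(key %in% names(thr))]), 5), collapse = "; "))
  }
  crit[is.na(crit) & out$coverage > thr[key]] <- "ii"

  # (iii) allele totals across all larvae sequenced, per site
  site <- paste(f1$chrom, f1$pos)
  totals <- rowsum(counts, site)                 # sites x 4 nucleotides
  keep_allele <- totals >= min_allele_total      # allele survives criterion iii
  n_kept <- rowSums(keep_allele)

  # (iv) > 2 surviving alleles: keep the two most frequent, filter ties
  site_a1 <- rep(NA_character_, nrow(totals))
  site_a2 <- rep(NA_character_, nrow(totals))
  site_crit <- rep(NA_character_, nrow(totals))
  for (s in seq_len(nrow(totals))) {
    tot <- totals[s, ]
    tot[!keep_allele[s, ]] <- 0L
    ord <- order(tot, decreasing = TRUE)
    if (n_kept[s] == 0) { site_crit[s] <- "iii"; next }
    if (n_kept[s] > 2 && tot[ord[2]] == tot[ord[3]]) { site_crit[s] <- "iv"; next }
    site_a1[s] <- NUCS[ord[1]]
    site_a2[s] <- if (n_kept[s] >= 2) NUCS[ord[2]] else NA_character_
  }
  si <- match(site, rownames(totals))
  crit[is.na(crit) & !is.na(site_crit[si])] <- site_crit[si][is.na(crit) & !is.na(site_crit[si])]

  a1 <- site_a1[si]; a2 <- site_a2[si]
  c1 <- counts[cbind(seq_len(nrow(counts)), match(a1, NUCS))]
  c2 <- counts[cbind(seq_len(nrow(counts)), match(a2, NUCS))]
  c2[is.na(a2) & !is.na(a1)] <- 0L
  # a larva may carry the two site alleles in either ratio; order per larva
  swap <- !is.na(c1) & !is.na(c2) & c2 > c1
  tmp <- a1; a1[swap] <- a2[swap]; a2[swap] <- tmp[swap]
  tmpc <- c1; c1[swap] <- c2[swap]; c2[swap] <- tmpc[swap]

  # a larva whose reads all belong to alleles dropped under (iii) has no
  # retained evidence left
  crit[is.na(crit) & !is.na(c1) & c1 == 0] <- "iii"

  # (v) biallelic larvae: both counts inside the central binomial interval
  het <- is.na(crit) & !is.na(a2) & !is.na(c2) & c2 > 0
  if (any(het)) {
    nn <- c1[het] + c2[het]
    b <- binom_retention_bounds(nn, ci_level)
    bad <- c1[het] > b$upper | c2[het] < b$lower
    crit[which(het)[bad]] <- "v"
  }

  out$allele1 <- a1
  out$count1 <- c1
  out$allele2 <- ifelse(!is.na(a2) & c2 > 0, a2, NA_character_)
  out$count2 <- ifelse(!is.na(a2) & c2 > 0, c2, NA_integer_)
  out$status <- ifelse(is.na(crit), "pass", "filtered")
  out$criterion <- crit
  out
}

#' Call paternal alleles at filtered F1 sites
#'
#' F1 larvae are offspring of a wild-karyotype father and a mother from a
#' strain homozygous for the reference allele, so every larva carries one
#' maternal reference allele: a heterozygous larva reveals a non-reference
#' paternal allele, a homozygous-reference larva a reference paternal allele.
#' A larva whose alleles do not include the reference at a
#' reference-homozygous site is inconsistent with the cross (possible
#' residual maternal heterozygosity) and is filtered with criterion
#' `"inconsistent"`.
#'
#' @param verdicts Output of [filter_f1_sites()].
#' @param reference Tibble `chrom`, `pos`, `ref` giving the maternal/
#'   reference allele at each site.
#' @return Tibble `chrom`, `pos`, `larva`, `allele` (the called paternal
#'   allele, `NA` when filtered), `status` (`"called"`/`"filtered"`),
#'   `criterion`.
#' @export
call_paternal_alleles <- function(verdicts, reference) {
  ref <- setNames(reference$ref, paste(reference$chrom, reference$pos))
  key <- paste(verdicts$chrom, verdicts$pos)
  if (any(!(key %in% names(ref)))) stop("reference allele missing for some sites")
  r <- unname(ref[key])

  allele <- rep(NA_character_, nrow(verdicts))
  crit <- verdicts$criterion
  pass <- verdicts$status == "pass"

  het <- pass & !is.na(verdicts$allele2)
  hom <- pass & is.na(verdicts$allele2)
  # heterozygote: paternal allele is the non-reference one
  ok_het <- het & (verdicts$allele1 == r | verdicts$allele2 == r)
  allele[ok_het] <- ifelse(verdicts$allele1[ok_het] == r[ok_het],
                           verdicts$allele2[ok_het], verdicts$allele1[ok_het])
  # homozygote for the reference: paternal allele is the reference
  ok_hom <- hom & verdicts$allele1 == r
  allele[ok_hom] <- r[ok_hom]
  bad <- pass & !(ok_het | ok_hom)
  crit[bad] <- "inconsistent"

  tibble::tibble(
    chrom = verdicts$chrom, pos = verdicts$pos, larva = verdicts$larva,
    allele = allele,
    status = ifelse(is.na(allele), "filtered", "called"),
    criterion = crit
  )
}

#' Reconstruct paternal haplotypes from F1 hybrid counts
#'
#' Convenience pipeline: computes per-larva, per-arm coverage percentiles
#' from the full count stream, applies the site filters, and calls paternal
#' alleles against the reference.
#'
#' @inheritParams filter_f1_sites
#' @inheritParams call_paternal_alleles
#' @param q Percentile for the maximum-coverage criterion.
#' @return Haplotype call tibble, see [call_paternal_alleles()].
#' @export
reconstruct_haplotypes <- function(f1, reference, ref_polymorphisms = NULL,
                                   q = 0.95, ref_maf_max = 0.10,
                                   min_coverage = 15, min_allele_total = 20,
                                   ci_level = 0.90) {
  cov_max <- per_arm_coverage_percentile(f1, q)
  v <- filter_f1_sites(f1, cov_max, ref_polymorphisms, ref_maf_max,
                       min_coverage, min_allele_total, ci_level)
  call_paternal_alleles(v, reference)
}

#' Assemble a haplotype panel from reconstructed calls
#'
#' Attaches per-(larva, arm) karyotype labels to haplotype calls, yielding
#' the long panel format used by marker discovery and the diversity/LD
#' statistics. Filtered sites become missing alleles.
#'
#' @param calls Output of [call_paternal_alleles()].
#' @param karyotypes Tibble `larva`, `chrom`, `karyotype` labelling each
#'   reconstructed arm (`"Std"` or an inversion name).
#' @return Long panel tibble `hap_id`, `karyotype`, `chrom`, `pos`, `allele`.
#' @export
as_haplotype_panel <- function(calls, karyotypes) {
  dplyr::inner_join(calls, karyotypes, by = c("larva", "chrom")) |>
    dplyr::transmute(hap_id = larva, karyotype, chrom, pos,
                     allele = ifelse(status == "called", allele, NA_character_)) |>
    dplyr::arrange(chrom, pos, hap_id)
}
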
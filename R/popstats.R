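## Long panel -> character matrix (positions x haplotypes), NA = missing.
panel_matrix <- function(panel, chrom = NULL) {
  if (!is.null(chrom)) panel <- panel[panel$chrom == chrom, ]
  if (nrow(panel) == 0) stop("empty panel")
  if (dplyr::n_distinct(panel$chrom) > 1) {
    stop("panel spans several chromosomes; supply `chrom`")
  }
  pos <- sort(unique(panel$pos))
  haps <- sort(unique(panel$hap_id))
  m <- matrix(NA_character_, length(pos), length(haps),
              dimnames = list(pos, haps))
  m[cbind(match(panel$pos, pos), match(panel$hap_id, haps))] <- panel$allele
  m
}

## Per-site pi: (n/(n-1)) * (1 - sum p_i^2) over non-missing alleles,
## NA where fewer than 2 alleles observed. x: character matrix sites x haps.
site_pi <- function(x) {
  apply(x, 1, function(a) {
    a <- a[!is.na(a)]
    n <- length(a)
    if (n < 2) return(NA_real_)
    p <- table(a) / n
    n / (n - 1) * (1 - sum(p^2))
  })
}

#' Windowed nucleotide diversity
#'
#' Estimates pi, the mean pairwise difference per site, in nonoverlapping
#' windows tiling the arm from position 1. Per site the unbiased
#' site-frequency form `n/(n-1) * (1 - sum p_i^2)` is used (for a biallelic
#' site this is `n/(n-1) * 2p(1-p)`), which equals the mean pairwise
#' difference over all haplotype pairs exactly. The window denominator is
#' the number of accessible sites: positions present in the panel at which
#' at least two haplotypes carry a non-missing allele. Panels restricted to
#' variable sites should instead set `denominator = "window"` to divide by
#' the window length. Windows with no accessible site get `NA`.
#'
#' @param panel Long haplotype panel (`hap_id`, `karyotype`, `chrom`, `pos`,
#'   `allele`) holding the haplotypes of one arrangement group.
#' @param window Window size in bp, default 100 kb.
#' @param chrom Arm to analyse when the panel spans several.
#' @param denominator `"accessible"` (default) or `"window"`.
#' @param chrom_length Optional arm length; windows tile `[1, chrom_length]`.
#' @return Tibble `chrom`, `win_start`, `win_end`, `n_sites`, `pi`.
#' @export
window_pi <- function(panel, window = 1e5, chrom = NULL,
                      denominator = c("accessible", "window"),
                      chrom_length = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(window > 0)
  m <- panel_matrix(panel, chrom)
  if (ncol(m) < 2) stop("need at least 2 haplotypes to compute pi")
  chromv <- if (!is.null(chrom)) chrom else panel$chrom[1]
  pos <- as.integer(rownames(m))
  pi_s <- site_pi(m)

  chrom_length <- chrom_length %||% max(pos)
  n_win <- ceiling(chrom_length / window)
  widx <- (pos - 1) %/% window + 1
  acc <- !is.na(pi_s)
  sum_pi <- vapply(seq_len(n_win), function(w) sum(pi_s[acc & widx == w]), 0)
  n_acc <- vapply(seq_len(n_win), function(w) sum(acc & widx == w), 0L)
  denom <- if (denominator == "accessible") n_acc else {
    as.integer(pmin(seq_len(n_win) * window, chrom_length) -
               (seq_len(n_win) - 1) * window)
  }
  tibble::tibble(
    chrom = chromv,
    win_start = as.integer((seq_len(n_win) - 1) * window + 1),
    win_end = as.integer(pmin(seq_len(n_win) * window, chrom_length)),
    n_sites = n_acc,
    pi = ifelse(n_acc == 0, NA_real_, sum_pi / denom)
  )
}

#' Windowed F_ST between two arrangement groups
#'
#' Pi-based Hudson-style differentiation:
#' `F_ST = (pi_total - pi_within) / pi_total`, where `pi_within` is the
#' unweighted mean of the two group pi values and `pi_total` the pi of the
#' pooled haplotypes, computed per window. `F_ST` is undefined (`NA`) where
#' `pi_total` is 0; sampling noise can make the estimate negative, in which
#' case it is clamped to 0 and flagged in the `clamped` column.
#'
#' @param panel_a,panel_b Long panels of the two groups (at least 2
#'   haplotypes each; `hap_id`s must not collide between groups).
#' @inheritParams window_pi
#' @return Tibble `chrom`, `win_start`, `win_end`, `n_sites`, `pi_a`,
#'   `pi_b`, `pi_total`, `fst`, `clamped`.
#' @export
window_fst <- function(panel_a, panel_b, window = 1e5, chrom = NULL,
                       denominator = c("accessible", "window"),
                       chrom_length = NULL) {
  denominator <- match.arg(denominator)
  if (dplyr::n_distinct(panel_a$hap_id) < 2 ||
      dplyr::n_distinct(panel_b$hap_id) < 2) {
    stop("each group needs at least 2 haplotypes")
  }
  if (length(intersect(unique(panel_a$hap_id), unique(panel_b$hap_id)))) {
    panel_b <- dplyr::mutate(panel_b, hap_id = paste0("b.", hap_id))
  }
  chrom_length <- chrom_length %||% max(c(panel_a$pos, panel_b$pos))
  wa <- window_pi(panel_a, window, chrom, denominator, chrom_length)
  wb <- window_pi(panel_b, window, chrom, denominator, chrom_length)
  wt <- window_pi(dplyr::bind_rows(panel_a, panel_b), window, chrom,
                  denominator, chrom_length)
  out <- tibble::tibble(
    chrom = wt$chrom, win_start = wt$win_start, win_end = wt$win_end,
    n_sites = wt$n_sites, pi_a = wa$pi, pi_b = wb$pi, pi_total = wt$pi
  )
  raw <- (out$pi_total - (out$pi_a + out$pi_b) / 2) / out$pi_total
  raw[!is.na(out$pi_total) & out$pi_total == 0] <- NA_real_
  out$clamped <- !is.na(raw) & raw < 0
  out$fst <- pmax(raw, 0)
  out
}

## r^2 between two allele vectors; NA unless both sites are biallelic and
## polymorphic after pairwise deletion of missing haplotypes.
r2_pair <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  ax <- unique(x); ay <- unique(y)
  if (length(ax) != 2 || length(ay) != 2) return(NA_real_)
  pa <- mean(x == ax[1]); pb <- mean(y == ay[1])
  pab <- mean(x == ax[1] & y == ay[1])
  d <- pab - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage disequilibrium r-squared between two sites
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A) p_B(1-p_B))` over the haplotypes
#' non-missing at both sites. Returns `NA` when either site is monomorphic
#' or not biallelic in that subset; `r^2` is invariant to which allele is
#' labelled A.
#'
#' @param panel Long haplotype panel of one arrangement group.
#' @param pos1,pos2 Site positions.
#' @param chrom Arm, when the panel spans several.
#' @return Scalar r-squared, or `NA`.
#' @export
ld_r2 <- function(panel, pos1, pos2, chrom = NULL) {
  m <- panel_matrix(panel, chrom)
  i <- match(as.character(c(pos1, pos2)), rownames(m))
  if (anyNA(i)) stop("position not present in panel")
  r2_pair(m[i[1], ], m[i[2], ])
}

#' Pairwise r-squared over a set of sites
#'
#' Computes r-squared for all pairs of the given (or sampled) polymorphic
#' sites, in the long format used for LD heatmaps. Alleles are coded 0/1 per
#' site and `r` is the Pearson correlation over pairwise-complete
#' haplotypes, which reproduces the two-locus formula exactly.
#'
#' @param panel Long haplotype panel of one arrangement group.
#' @param positions Sites to use; default all biallelic polymorphic sites.
#' @param n_snps Optional number of sites to sample at random from
#'   `positions` (the customary subsample is 5000 per arm).
#' @param interval Optional `c(start, end)` (1-based inclusive) restricting
#'   sites to a region, e.g. an inversion's span.
#' @param chrom Arm, when the panel spans several.
#' @return Long tibble `pos1`, `pos2`, `r2` (`pos1 < pos2`), `NA` rows
#'   dropped.
#' @export
ld_pairs <- function(panel, positions = NULL, n_snps = NULL,
                     interval = NULL, chrom = NULL) {
  m <- panel_matrix(panel, chrom)
  pos <- as.integer(rownames(m))
  keep <- polymorphic_sites(m)
  if (!is.null(interval)) keep <- keep & pos >= interval[1] & pos <= interval[2]
  if (!is.null(positions)) keep <- keep & pos %in% positions
  m <- m[keep, , drop = FALSE]; pos <- pos[keep]
  if (!is.null(n_snps) && n_snps < length(pos)) {
    i <- sort(sample(length(pos), n_snps))
    m <- m[i, , drop = FALSE]; pos <- pos[i]
  }
  if (length(pos) < 2) {
    return(tibble::tibble(pos1 = integer(), pos2 = integer(), r2 = double()))
  }
  r2m <- r2_matrix(m)
  ut <- which(upper.tri(r2m), arr.ind = TRUE)
  out <- tibble::tibble(pos1 = pos[ut[, 1]], pos2 = pos[ut[, 2]],
                        r2 = r2m[ut])
  out[!is.na(out$r2), ]
}

## biallelic & polymorphic over non-missing haplotypes
polymorphic_sites <- function(m) {
  apply(m, 1, function(a) {
    a <- a[!is.na(a)]
    length(unique(a)) == 2
  })
}

## squared correlation matrix of 0/1-coded sites (rows), pairwise-complete
r2_matrix <- function(m) {
  ref <- apply(m, 1, function(a) sort(unique(a[!is.na(a)]))[1])
  num <- (m == ref) * 1
  suppressWarnings(stats::cor(t(num), use = "pairwise.complete.obs")^2)
}

#' Inverted/standard LD ratio inside an inversion
#'
#' Quantifies the excess linkage disequilibrium carried by inverted
#' chromosomes: the mean pairwise r-squared among SNPs inside the inversion
#' interval, computed separately for inverted and standard haplotypes, and
#' their ratio. Because r-squared depends strongly on the number of
#' haplotypes, the larger group is first subsampled (seeded) down to the
#' size of the smaller. One common SNP set -- sites biallelic and
#' polymorphic in both (subsampled) groups inside the interval -- is sampled
#' once and used for both groups, so `ld_ratio(a, b)` and `ld_ratio(b, a)`
#' are exact reciprocals at a fixed seed.
#'
#' @param panel_inverted,panel_standard Long panels of the two arrangement
#'   groups; the smaller must hold at least 2 haplotypes.
#' @param interval `c(start, end)` of the inversion, 1-based inclusive.
#' @param n_snps SNPs to sample inside the interval, default 5000.
#' @param seed Optional seed controlling the subsampling.
#' @param chrom Arm, when a panel spans several.
#' @return One-row tibble: `ratio`, `mean_r2_inverted`, `mean_r2_standard`,
#'   `n_snps_used`, `n_haplotypes` (per group, after matching).
#' @export
ld_ratio <- function(panel_inverted, panel_standard, interval,
                     n_snps = 5000, seed = NULL, chrom = NULL) {
  run <- function() {
    mi <- panel_matrix(panel_inverted, chrom)
    ms <- panel_matrix(panel_standard, chrom)
    k <- min(ncol(mi), ncol(ms))
    if (k < 2) stop("smaller arrangement group has fewer than 2 haplotypes")
    if (ncol(mi) > k) mi <- mi[, sort(sample(colnames(mi), k)), drop = FALSE]
    if (ncol(ms) > k) ms <- ms[, sort(sample(colnames(ms), k)), drop = FALSE]

    common <- intersect(rownames(mi), rownames(ms))
    pos <- as.integer(common)
    inside <- pos >= interval[1] & pos <= interval[2]
    common <- common[inside]
    poly <- polymorphic_sites(mi[common, , drop = FALSE]) &
      polymorphic_sites(ms[common, , drop = FALSE])
    common <- common[poly]
    if (length(common) < 2) stop("fewer than 2 shared polymorphic SNPs inside interval")
    if (length(common) > n_snps) common <- sort(sample(common, n_snps))

    r2i <- r2_matrix(mi[common, , drop = FALSE])
    r2s <- r2_matrix(ms[common, , drop = FALSE])
    mean_r2 <- function(x) mean(x[upper.tri(x)], na.rm = TRUE)
    tibble::tibble(
      ratio = mean_r2(r2i) / mean_r2(r2s),
      mean_r2_inverted = mean_r2(r2i),
      mean_r2_standard = mean_r2(r2s),
      n_snps_used = length(common),
      n_haplotypes = k
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
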
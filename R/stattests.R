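#' Cochran-Mantel-Haenszel test over replicate strata
#'
#' Classical CMH chi-square for K stratified 2x2 tables of allele counts
#' (inverted vs other) at two time points, the replicate-aware test of
#' allele-frequency change used per marker SNP. With
#' `a_k` the inverted count at time 1 in stratum k, margins `r1, r2`
#' (allele totals) and `c1, c2` (time-point totals), the statistic is
#' `(|sum(a_k - E_k)| - cc)^2 / sum(V_k)` with `E_k = r1 c1 / n`,
#' `V_k = r1 r2 c1 c2 / (n^2 (n - 1))`, referred to chi-square with 1 df.
#' The continuity correction `cc` defaults to off, matching the behaviour
#' customary in Pool-Seq time-series analyses; set `correct = TRUE` for the
#' corrected variant. Strata with an empty margin carry no information and
#' are dropped with a warning; a single stratum is allowed and reduces to
#' the (n-1)/n-scaled Pearson chi-square of that table.
#'
#' @param counts Either a tidy tibble with columns `stratum`, `time` (two
#'   levels), `inverted`, `other`, or a 2x2xK array with rows = alleles and
#'   columns = time points.
#' @param correct Apply the continuity correction; default `FALSE`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_strata` (used).
#'   All-dropped input yields `NA` statistic and p.
#' @examples
#' x <- tibble::tibble(stratum = rep(1:3, each = 2), time = rep(1:2, 3),
#'                     inverted = c(10, 18, 8, 15, 12, 20),
#'                     other = c(40, 32, 42, 35, 38, 30))
#' cmh_test(x)
#' @export
cmh_test <- function(counts, correct = FALSE) {
  arr <- as_cmh_array(counts)
  keep <- apply(arr, 3, function(tb) all(rowSums(tb) > 0) && all(colSums(tb) > 0))
  if (any(!keep)) {
    warning(sum(!keep), " stratum/strata with an empty margin dropped")
    arr <- arr[, , keep, drop = FALSE]
  }
  k <- dim(arr)[3]
  if (k == 0) {
    return(tibble::tibble(statistic = NA_real_, df = 1L, p_value = NA_real_,
                          n_strata = 0L))
  }
  a <- arr[1, 1, ]
  r1 <- arr[1, 1, ] + arr[1, 2, ]; r2 <- arr[2, 1, ] + arr[2, 2, ]
  c1 <- arr[1, 1, ] + arr[2, 1, ]; c2 <- arr[1, 2, ] + arr[2, 2, ]
  n <- r1 + r2
  e <- r1 * c1 / n
  v <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  dev <- abs(sum(a - e)) - if (correct) 0.5 else 0
  stat <- max(dev, 0)^2 / sum(v)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 n_strata = as.integer(k))
}

as_cmh_array <- function(counts) {
  if (is.array(counts) && length(dim(counts)) == 3) {
    stopifnot(dim(counts)[1] == 2, dim(counts)[2] == 2)
    if (any(counts < 0)) stop("negative cell count")
    return(counts)
  }
  req <- c("stratum", "time", "inverted", "other")
  if (!all(req %in% names(counts))) {
    stop("counts must be a 2x2xK array or have columns ", paste(req, collapse = ", "))
  }
  if (any(counts$inverted < 0) || any(counts$other < 0)) stop("negative cell count")
  strata <- unique(counts$stratum)
  times <- sort(unique(counts$time))
  if (length(times) != 2) stop("exactly two time points required")
  arr <- array(0, c(2, 2, length(strata)),
               dimnames = list(c("inverted", "other"), times, strata))
  for (i in seq_along(strata)) {
    s <- counts[counts$stratum == strata[i], ]
    if (nrow(s) != 2) stop("stratum ", strata[i], " must have one row per time point")
    s <- s[match(times, s$time), ]
    arr[, , i] <- rbind(s$inverted, s$other)
  }
  arr
}

#' Fisher's exact test on a 2x2 allele-count table
#'
#' Two-sided exact test via the hypergeometric distribution, used per marker
#' SNP to compare inversion frequencies between a baseline (e.g. lowest
#' latitude) population and another population. A table with an empty margin
#' is uninformative; by convention it returns p = 1 with `flagged = TRUE`.
#'
#' @param x 2x2 matrix of counts (rows: inverted/other; columns:
#'   populations), or a length-4 vector `c(inv_a, other_a, inv_b, other_b)`.
#' @return One-row tibble: `p_value`, `flagged`.
#' @export
fet_test <- function(x) {
  if (!is.matrix(x)) {
    stopifnot(length(x) == 4)
    x <- matrix(x, 2, 2)
  }
  stopifnot(all(dim(x) == 2), all(x >= 0))
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    return(tibble::tibble(p_value = 1, flagged = TRUE))
  }
  tibble::tibble(p_value = fisher.test(x)$p.value, flagged = FALSE)
}

#' Combine per-marker p-values
#'
#' The default combination is the arithmetic mean across marker SNPs. The
#' mean of p-values is a summary of evidence across markers, not a
#' calibrated combined test; Fisher's method (`-2 sum log p` against
#' chi-square with 2k df) is available as an alternative.
#'
#' @param p Vector of p-values, at least one, all in `[0, 1]`.
#' @param method `"mean"` (default) or `"fisher"`.
#' @return Scalar combined/summary p-value.
#' @export
combine_p <- function(p, method = c("mean", "fisher")) {
  method <- match.arg(method)
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values to combine")
  stopifnot(all(p >= 0), all(p <= 1))
  switch(method,
         mean = mean(p),
         fisher = pchisq(-2 * sum(log(pmax(p, .Machine$double.xmin))),
                         df = 2 * length(p), lower.tail = FALSE))
}

#' Per-marker CMH tests across replicated time points
#'
#' Builds, for every marker SNP, one 2x2 table per replicate (inverted vs
#' other allele counts at two time points, taken from the sync pools named
#' in `strata`) and runs [cmh_test()] across replicates. Markers absent
#' from the sync table are dropped.
#'
#' @param sync Long sync tibble.
#' @param markers Marker tibble.
#' @param strata List of length-2 pool-index vectors, one `c(t1, t2)` pair
#'   per replicate.
#' @param correct Continuity correction, default off.
#' @return Tibble `inversion`, `chrom`, `pos`, `statistic`, `p_value`,
#'   `n_strata`; combine per inversion with [combine_p()].
#' @export
cmh_markers <- function(sync, markers, strata, correct = FALSE) {
  stopifnot(length(strata) >= 1, all(lengths(strata) == 2))
  detail <- marker_counts(sync, markers)
  purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    mk <- markers[i, ]
    d <- detail[detail$inversion == mk$inversion & detail$pos == mk$pos &
                  detail$chrom == mk$chrom, ]
    if (nrow(d) == 0) return(NULL)
    if (!all(unlist(strata) %in% d$pool)) return(NULL)
    tabs <- purrr::imap_dfr(strata, function(pools, r) {
      dd <- d[match(pools, d$pool), ]
      tibble::tibble(stratum = r, time = 1:2,
                     inverted = dd$inverted_count,
                     other = dd$coverage - dd$inverted_count)
    })
    res <- suppressWarnings(cmh_test(tabs, correct = correct))
    dplyr::bind_cols(mk[, c("inversion", "chrom", "pos")], res[, c("statistic", "p_value", "n_strata")])
  })
}

#' Per-marker Fisher's exact tests against a baseline pool
#'
#' For each marker SNP and each non-baseline pool, tests the 2x2 table of
#' inverted/other allele counts (baseline vs that pool) with [fet_test()],
#' the replicate-free comparison used along latitudinal clines.
#'
#' @param sync Long sync tibble.
#' @param markers Marker tibble.
#' @param baseline_pool Pool index of the baseline population.
#' @param pools Pools to compare against the baseline; default all others.
#' @return Tibble `inversion`, `chrom`, `pos`, `pool`, `p_value`, `flagged`.
#' @export
fet_markers <- function(sync, markers, baseline_pool, pools = NULL) {
  detail <- marker_counts(sync, markers)
  pools <- pools %||% setdiff(sort(unique(sync$pool)), baseline_pool)
  base <- detail[detail$pool == baseline_pool, ]
  purrr::map_dfr(pools, function(pl) {
    other <- detail[detail$pool == pl, ]
    j <- dplyr::inner_join(base, other, by = c("inversion", "chrom", "pos"),
                           suffix = c("_a", "_b"))
    purrr::map_dfr(seq_len(nrow(j)), function(i) {
      res <- fet_test(c(j$inverted_count_a[i], j$coverage_a[i] - j$inverted_count_a[i],
                        j$inverted_count_b[i], j$coverage_b[i] - j$inverted_count_b[i]))
      tibble::tibble(inversion = j$inversion[i], chrom = j$chrom[i],
                     pos = j$pos[i], pool = pl,
                     p_value = res$p_value, flagged = res$flagged)
    })
  })
}

## inverted-allele count and SNP coverage per marker x pool
marker_counts <- function(sync, markers) {
  joined <- dplyr::inner_join(markers, sync, by = c("chrom", "pos"),
                              relationship = "many-to-many")
  cnt <- as.matrix(joined[, c("A", "T", "C", "G")])
  joined |>
    dplyr::mutate(
      coverage = as.integer(rowSums(cnt)),
      inverted_count = cnt[cbind(seq_len(nrow(cnt)),
                                 match(joined$inverted_allele, c("A", "T", "C", "G")))]) |>
    dplyr::select(inversion, chrom, pos, pool, coverage, inverted_count)
}

#' Two-way ANOVA of karyotype frequencies on inversion type and regime
#'
#' Fits the fully factorial fixed-effects model
#' `frequency ~ inversion * regime` to per-replicate inversion frequencies,
#' e.g. the 6 inversions x 2 thermal selection regimes x 3 replicate
#' populations layout of a laboratory natural selection experiment. The
#' design must be balanced and complete (so the sums-of-squares type is
#' immaterial); frequencies should be exact `count / n` values, not rounded
#' ones.
#'
#' @param freqs Tibble with columns `inversion`, `regime`, `replicate`,
#'   `frequency`.
#' @return An object of class `"inversion_anova"` wrapping the [stats::aov]
#'   fit; see [tidy.inversion_anova()] and [glance.inversion_anova()].
#' @export
anova_inversion <- function(freqs) {
  req <- c("inversion", "regime", "replicate", "frequency")
  if (!all(req %in% names(freqs))) {
    stop("freqs must have columns ", paste(req, collapse = ", "))
  }
  tab <- table(freqs$inversion, freqs$regime)
  if (length(unique(as.vector(tab))) != 1 || any(tab == 0)) {
    stop("unbalanced design: every inversion x regime cell needs the same ",
         "number of replicates")
  }
  dat <- dplyr::mutate(freqs, inversion = factor(inversion), regime = factor(regime))
  fit <- aov(frequency ~ inversion * regime, data = dat)
  structure(list(fit = fit, data = dat), class = "inversion_anova")
}

#' @export
print.inversion_anova <- function(x, ...) {
  cat("Two-way ANOVA of inversion frequencies (inversion * regime)\n")
  print(summary(x$fit))
  invisible(x)
}

#' Tidy an inversion-frequency ANOVA
#'
#' @param x An `inversion_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p_value`.
#' @export
tidy.inversion_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(s)),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    meansq = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p_value = s[["Pr(>F)"]]
  )
}

#' One-row summary of an inversion-frequency ANOVA
#'
#' @param x An `inversion_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the F statistics, dfs and p-values of the
#'   inversion main effect, the regime main effect and their interaction,
#'   plus the residual df.
#' @export
glance.inversion_anova <- function(x, ...) {
  td <- tidy.inversion_anova(x)
  g <- function(term, col) td[[col]][td$term == term]
  tibble::tibble(
    f_inversion = g("inversion", "statistic"),
    f_regime = g("regime", "statistic"),
    f_interaction = g("inversion:regime", "statistic"),
    df_inversion = g("inversion", "df"),
    df_regime = g("regime", "df"),
    df_interaction = g("inversion:regime", "df"),
    df_residual = g("Residuals", "df"),
    p_inversion = g("inversion", "p_value"),
    p_regime = g("regime", "p_value"),
    p_interaction = g("inversion:regime", "p_value")
  )
}
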
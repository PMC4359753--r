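# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# mean pairwise difference per site over all haplotype pairs; m is a
# character matrix sites x haplotypes, NA = missing (pairs are counted
# per site over haplotypes non-missing there)
oracle_pi_pairwise <- function(m, denom = NULL) {
  total <- 0
  n_acc <- 0
  for (s in seq_len(nrow(m))) {
    a <- m[s, ]
    a <- a[!is.na(a)]
    n <- length(a)
    if (n < 2) next
    diff <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) diff <- diff + (a[i] != a[j])
    total <- total + diff / choose(n, 2)
    n_acc <- n_acc + 1
  }
  if (n_acc == 0) return(NA_real_)
  unname(total / (denom %||% n_acc))
}

# Hudson-style FST from site-by-site pairwise diversity
oracle_fst_pairwise <- function(ma, mb) {
  pia <- oracle_pi_pairwise(ma)
  pib <- oracle_pi_pairwise(mb)
  pit <- oracle_pi_pairwise(cbind(ma, mb))
  if (is.na(pit) || pit == 0) return(NA_real_)
  (pit - (pia + pib) / 2) / pit
}

# r^2 as the 2x2 haplotype-table chi-square divided by n
oracle_r2_table <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  tb <- table(x, y)
  if (any(dim(tb) != 2)) return(NA_real_)
  unname(suppressWarnings(chisq.test(tb, correct = FALSE)$statistic) / sum(tb))
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fet_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-way balanced fixed-effects ANOVA by explicit sums of squares
oracle_anova_ss <- function(y, fi, ft) {
  fi <- factor(fi); ft <- factor(ft)
  a <- nlevels(fi); b <- nlevels(ft); r <- length(y) / (a * b)
  gm <- mean(y)
  mi <- tapply(y, fi, mean); mt <- tapply(y, ft, mean)
  mc <- tapply(y, interaction(fi, ft), mean)
  ss_i <- b * r * sum((mi - gm)^2)
  ss_t <- a * r * sum((mt - gm)^2)
  cell_of <- interaction(fi, ft)
  ss_resid <- sum((y - mc[cell_of])^2)
  ss_int <- sum((y - gm)^2) - ss_i - ss_t - ss_resid
  df_i <- a - 1; df_t <- b - 1; df_int <- df_i * df_t
  df_res <- a * b * (r - 1)
  list(
    f_i = (ss_i / df_i) / (ss_resid / df_res),
    f_t = (ss_t / df_t) / (ss_resid / df_res),
    f_int = (ss_int / df_int) / (ss_resid / df_res),
    df = c(df_i, df_t, df_int, df_res)
  )
}

# long panel tibble from a character matrix (sites x haps)
panel_from_matrix <- function(m, pos = seq_len(nrow(m)), chrom = "3R",
                              karyotype = "Std") {
  haps <- colnames(m) %||% sprintf("h%02d", seq_len(ncol(m)))
  tibble::tibble(
    hap_id = rep(haps, each = nrow(m)),
    karyotype = karyotype, chrom = chrom,
    pos = rep(as.integer(pos), ncol(m)),
    allele = as.vector(m)
  )
}

random_hap_matrix <- function(n_sites, n_haps, missing_rate = 0) {
  al <- t(replicate(n_sites, sample(c("A", "C", "G", "T"), 2)))
  f <- runif(n_sites, 0.2, 0.8)
  m <- matrix(ifelse(matrix(runif(n_sites * n_haps) < f, n_sites, n_haps),
                     al[, 1], al[, 2]), n_sites, n_haps)
  if (missing_rate > 0) {
    m[matrix(runif(length(m)) < missing_rate, n_sites)] <- NA_character_
  }
  colnames(m) <- sprintf("h%02d", seq_len(n_haps))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# replicate-rows karyotype table of the laboratory selection experiment,
# with regime/replicate parsed from the population label
lns_replicate_freqs <- function() {
  path <- system.file("extdata", "karyotype_counts_lns.tsv", package = "poolinv")
  k <- read_karyotype_counts(path)
  karyotype_frequency(k) |>
    dplyr::filter(population != "Base") |>
    dplyr::mutate(regime = sub("-R\\d$", "", population),
                  replicate = sub("^.*-R", "", population))
}
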
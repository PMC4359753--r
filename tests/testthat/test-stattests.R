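cmh_array <- function(...) {
  tabs <- list(...)
  array(unlist(tabs), dim = c(2, 2, length(tabs)))
}

test_that("CMH: no frequency change gives statistic 0 and p 1", {
  tb <- matrix(c(12, 38, 12, 38), 2, 2)
  res <- cmh_test(cmh_array(tb, tb, tb))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_strata, 3L)
})

test_that("CMH is invariant to stratum order and simultaneous label swaps", {
  t1 <- matrix(c(10, 40, 25, 30), 2, 2)
  t2 <- matrix(c(8, 42, 20, 28), 2, 2)
  t3 <- matrix(c(15, 35, 28, 22), 2, 2)
  a <- cmh_test(cmh_array(t1, t2, t3))
  b <- cmh_test(cmh_array(t3, t1, t2))
  expect_equal(b$statistic, a$statistic)
  # swap rows and columns in every stratum
  sw <- function(m) m[2:1, 2:1]
  c_ <- cmh_test(cmh_array(sw(t1), sw(t2), sw(t3)))
  expect_equal(c_$statistic, a$statistic)
})

test_that("single-stratum CMH is the (n-1)/n-scaled Pearson chi-square", {
  withr::with_seed(8, {
    for (i in 1:25) {
      tb <- matrix(rpois(4, 20) + 1, 2, 2)
      res <- cmh_test(array(tb, c(2, 2, 1)))
      pearson <- unname(suppressWarnings(chisq.test(tb, correct = FALSE)$statistic))
      n <- sum(tb)
      expect_equal(res$statistic, (n - 1) / n * pearson, tolerance = 1e-12)
    }
  })
})

test_that("multi-stratum CMH matches mantelhaen.test with and without correction", {
  withr::with_seed(9, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      arr <- array(rpois(4 * k, 15) + 1, c(2, 2, k))
      for (corr in c(FALSE, TRUE)) {
        res <- cmh_test(arr, correct = corr)
        ref <- stats::mantelhaen.test(arr, correct = corr)
        expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("tidy CMH input matches the array route; empty-margin strata are dropped", {
  tb <- tibble::tibble(stratum = rep(1:2, each = 2), time = rep(1:2, 2),
                       inverted = c(10, 20, 8, 16), other = c(40, 30, 42, 34))
  arr <- cmh_array(matrix(c(10, 40, 20, 30), 2, 2), matrix(c(8, 42, 16, 34), 2, 2))
  expect_equal(cmh_test(tb)$statistic, cmh_test(arr)$statistic)

  with_empty <- cmh_array(matrix(c(10, 40, 20, 30), 2, 2), matrix(c(0, 50, 0, 48), 2, 2))
  expect_warning(res <- cmh_test(with_empty), "empty margin")
  expect_equal(res$n_strata, 1L)
  expect_warning(all_gone <- cmh_test(cmh_array(matrix(c(0, 10, 0, 12), 2, 2))))
  expect_true(is.na(all_gone$p_value))
})

test_that("FET matches enumeration on canonical tables and is symmetric under transposition", {
  expect_equal(fet_test(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  expect_equal(fet_test(matrix(c(10, 0, 0, 10), 2, 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  res <- fet_test(matrix(c(0, 0, 5, 5), 2, 2))
  expect_equal(res$p_value, 1)
  expect_true(res$flagged)

  withr::with_seed(14, {
    for (i in 1:30) {
      tb <- matrix(rpois(4, 6), 2, 2)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
      p <- fet_test(tb)$p_value
      expect_equal(p, oracle_fet_enum(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                   tolerance = 1e-9)
      expect_equal(fet_test(t(tb))$p_value, p, tolerance = 1e-12)
    }
  })
})

test_that("combine_p: mean by default, Fisher's method behind a flag, LLN concentration", {
  expect_equal(combine_p(c(0.2, 0.4)), 0.3)
  expect_equal(combine_p(0.73), 0.73)
  expect_error(combine_p(numeric(0)), "no p-values")
  expect_equal(combine_p(c(0.1, 0.5), method = "fisher"),
               pchisq(-2 * (log(0.1) + log(0.5)), 4, lower.tail = FALSE))
  withr::with_seed(20, {
    means <- replicate(1000, combine_p(runif(100)))
    expect_gt(mean(means), 0.49)
    expect_lt(mean(means), 0.51)
  })
})

test_that("per-marker CMH and FET pipelines agree with direct calls on constructed pools", {
  mk <- tibble::tibble(inversion = "In(3R)C", chrom = "3R", pos = c(100L, 250L),
                       inverted_allele = c("A", "G"), other_allele = c("T", "C"))
  # pools 1..6 = replicates 1..3 at time points 1, 2 (rising frequency)
  sync <- sim_pool_counts(mk, truth_freq = c(0.15, 0.2, 0.18, 0.5, 0.55, 0.48),
                          mean_coverage = 60, seed = 71)
  strata <- list(c(1L, 4L), c(2L, 5L), c(3L, 6L))
  res <- cmh_markers(sync, mk, strata)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p_value < 0.01))  # strong planted change
  # reproduce marker 1 by hand
  cnt <- poolinv:::marker_counts(sync, mk)
  d <- cnt[cnt$pos == 100L, ]
  tabs <- purrr::imap_dfr(strata, function(pp, r) {
    dd <- d[match(pp, d$pool), ]
    tibble::tibble(stratum = r, time = 1:2, inverted = dd$inverted_count,
                   other = dd$coverage - dd$inverted_count)
  })
  expect_equal(res$statistic[res$pos == 100L], cmh_test(tabs)$statistic)

  fres <- fet_markers(sync, mk, baseline_pool = 1L, pools = 4L)
  d4 <- cnt[cnt$pos == 100L & cnt$pool %in% c(1L, 4L), ]
  direct <- fet_test(matrix(c(d4$inverted_count[1], d4$coverage[1] - d4$inverted_count[1],
                              d4$inverted_count[2], d4$coverage[2] - d4$inverted_count[2]),
                            2, 2))
  expect_equal(fres$p_value[fres$pos == 100L], direct$p_value)
})

test_that("CMH empirical type-I error is near nominal under the null", {
  pvals <- withr::with_seed(100, replicate(2000, {
    k <- 3
    p <- runif(k, 0.2, 0.8)
    a <- rbinom(k, 50, p); b <- rbinom(k, 50, p)
    arr <- array(rbind(a, 50 - a, b, 50 - b), c(2, 2, k))
    cmh_test(arr)$p_value
  }))
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("the two-way ANOVA matches an explicit sums-of-squares decomposition", {
  withr::with_seed(60, {
    for (i in 1:10) {
      d <- tidyr::expand_grid(inversion = paste0("In", 1:6),
                              regime = c("cold", "hot"), replicate = 1:3) |>
        dplyr::mutate(frequency = runif(dplyr::n()))
      fit <- anova_inversion(d)
      g <- glance(fit)
      o <- oracle_anova_ss(d$frequency, d$inversion, d$regime)
      expect_equal(g$f_inversion, o$f_i, tolerance = 1e-10)
      expect_equal(g$f_regime, o$f_t, tolerance = 1e-10)
      expect_equal(g$f_interaction, o$f_int, tolerance = 1e-10)
      expect_equal(c(g$df_inversion, g$df_regime, g$df_interaction, g$df_residual),
                   o$df)
      # adding a constant to every frequency leaves F untouched
      g2 <- glance(anova_inversion(dplyr::mutate(d, frequency = frequency + 0.17)))
      expect_equal(g2$f_inversion, g$f_inversion, tolerance = 1e-8)
      expect_equal(g2$f_interaction, g$f_interaction, tolerance = 1e-8)
    }
  })
})

test_that("equal cell means give zero effect F; unbalanced layouts are rejected", {
  d <- tidyr::expand_grid(inversion = paste0("In", 1:3), regime = c("c", "h"),
                          replicate = 1:3) |>
    dplyr::mutate(frequency = rep(c(0.1, 0.2, 0.3), times = 6))
  g <- glance(anova_inversion(d))
  expect_equal(g$f_inversion, 0)
  expect_equal(g$f_regime, 0)
  expect_equal(g$f_interaction, 0)

  expect_error(anova_inversion(d[-1, ]), "unbalanced")
  td <- tidy(anova_inversion(d))
  expect_setequal(td$term, c("inversion", "regime", "inversion:regime", "Residuals"))
})
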
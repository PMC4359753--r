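test_that("nearest-rank percentile matches its definition and the boundary examples", {
  expect_equal(coverage_percentile(1:100, 0.95), 95)
  expect_equal(coverage_percentile(rep(30, 50), 0.95), 30)
  expect_error(coverage_percentile(numeric(0)), "empty")

  # brute force: smallest observed value with >= q of the data at or below it
  withr::with_seed(42, {
    for (i in 1:50) {
      x <- sample(1:60, sample(5:80, 1), replace = TRUE)
      q <- runif(1, 0.05, 1)
      ux <- sort(unique(x))
      brute <- ux[which(vapply(ux, function(v) mean(x <= v), 0) >= q)[1]]
      expect_equal(coverage_percentile(x, q), brute)
    }
  })
})

test_that("binomial retention interval is the exact central region, inclusive and symmetric", {
  for (n in c(10L, 15L, 20L, 35L, 50L, 101L)) {
    b <- binom_retention_bounds(n, 0.90)
    # enumeration oracle: retain k iff both tail masses through k exceed 5%
    ks <- 0:n
    retain <- pbinom(ks, n, 0.5) > 0.05 & pbinom(ks - 1, n, 0.5, lower.tail = FALSE) > 0.05
    expect_equal(b$lower, min(ks[retain]))
    expect_equal(b$upper, max(ks[retain]))
    expect_equal(b$lower + b$upper, n)  # symmetric about n/2
  }
  # coverage 20: 10/10 passes, 17/3 fails
  b20 <- binom_retention_bounds(20L)
  expect_true(10 >= b20$lower && 10 <= b20$upper)
  expect_false(17 <= b20$upper)
  expect_false(3 >= b20$lower)
})

make_f1_row <- function(pos, larva, counts) {
  tibble::tibble(chrom = "2L", pos = pos, larva = larva,
                 A = counts[1], C = counts[2], G = counts[3], T = counts[4])
}

test_that("the filter criteria fire in order on constructed sites", {
  f1 <- dplyr::bind_rows(
    make_f1_row(1L, "L1", c(14L, 0L, 0L, 0L)),    # (i) coverage 14 < 15
    make_f1_row(2L, "L1", c(200L, 0L, 0L, 0L)),   # (ii) above the arm percentile
    make_f1_row(3L, "L1", c(10L, 9L, 0L, 0L)),    # (iii) both allele totals < 20
    make_f1_row(4L, "L1", c(17L, 3L, 0L, 0L)),    # (v) outside the 90% interval
    make_f1_row(5L, "L1", c(10L, 10L, 0L, 0L)),   # passes, exactly 1/2
    make_f1_row(6L, "L1", c(30L, 0L, 0L, 0L)),    # passes, homozygous
    make_f1_row(7L, "L1", c(12L, 11L, 0L, 0L))    # reference-strain polymorphism
  )
  # allele totals need >= 20 across larvae: add a second larva backing pos 4, 7
  f1 <- dplyr::bind_rows(
    f1,
    make_f1_row(4L, "L2", c(15L, 17L, 0L, 0L)),
    make_f1_row(5L, "L2", c(11L, 12L, 0L, 0L)),
    make_f1_row(7L, "L2", c(12L, 12L, 0L, 0L)))
  cov_max <- tidyr::expand_grid(larva = c("L1", "L2"), chrom = "2L",
                                max_coverage = 60L)
  refpoly <- tibble::tibble(chrom = "2L", pos = 7L, maf = 0.25)
  v <- filter_f1_sites(f1, cov_max, ref_polymorphisms = refpoly)
  vv <- function(p, l) v[v$pos == p & v$larva == l, ]
  expect_equal(vv(1, "L1")$criterion, "i")
  expect_equal(vv(2, "L1")$criterion, "ii")
  expect_equal(vv(3, "L1")$criterion, "iii")
  expect_equal(vv(4, "L1")$criterion, "v")
  expect_equal(vv(4, "L2")$status, "pass")
  expect_equal(vv(5, "L1")$status, "pass")
  expect_equal(vv(6, "L1")$status, "pass")
  expect_equal(vv(7, "L1")$criterion, "ref_poly")
  # every filtered row names exactly one criterion
  expect_true(all(!is.na(v$criterion[v$status == "filtered"])))
  expect_true(all(is.na(v$criterion[v$status == "pass"])))
})

test_that("more than two alleles keeps the two most frequent; 2nd/3rd ties are filtered", {
  # pos 1: A/C dominate, G rare but above 20 -> top two kept, G ignored
  f1 <- dplyr::bind_rows(
    make_f1_row(1L, "L1", c(20L, 18L, 21L, 0L)),
    make_f1_row(1L, "L2", c(20L, 22L, 0L, 0L)),
    # pos 2: C and G tie for 2nd/3rd place -> filtered under (iv)
    make_f1_row(2L, "L1", c(20L, 20L, 20L, 0L)),
    make_f1_row(2L, "L2", c(20L, 0L, 0L, 0L)))
  cov_max <- tidyr::expand_grid(larva = c("L1", "L2"), chrom = "2L",
                                max_coverage = 100L)
  v <- filter_f1_sites(f1, cov_max)
  expect_setequal(unlist(v[v$pos == 1, c("allele1", "allele2")]), c("A", "C"))
  expect_true(all(v$criterion[v$pos == 2] == "iv"))
})

test_that("paternal calls follow the cross: het -> alt, hom ref -> ref, hom alt -> inconsistent", {
  ref <- tibble::tibble(chrom = "2L", pos = 1:3, ref = c("A", "A", "A"))
  f1 <- dplyr::bind_rows(
    make_f1_row(1L, "L1", c(14L, 16L, 0L, 0L)),  # het A/C -> paternal C
    make_f1_row(2L, "L1", c(30L, 0L, 0L, 0L)),   # hom ref -> paternal A
    make_f1_row(3L, "L1", c(0L, 30L, 0L, 0L)),   # hom C though mother is A/A
    make_f1_row(1L, "L2", c(16L, 15L, 0L, 0L)),
    make_f1_row(2L, "L2", c(29L, 0L, 0L, 0L)),
    make_f1_row(3L, "L2", c(0L, 28L, 0L, 0L)))
  cov_max <- tidyr::expand_grid(larva = c("L1", "L2"), chrom = "2L",
                                max_coverage = 100L)
  calls <- call_paternal_alleles(filter_f1_sites(f1, cov_max), ref)
  c1 <- calls[calls$larva == "L1", ]
  expect_equal(c1$allele[c1$pos == 1], "C")
  expect_equal(c1$status[c1$pos == 1], "called")
  expect_equal(c1$allele[c1$pos == 2], "A")
  expect_equal(c1$status[c1$pos == 3], "filtered")
  expect_equal(c1$criterion[c1$pos == 3], "inconsistent")
})

sim_panel_f1 <- function(n_larvae, n_sites, coverage, error_rate, seed) {
  withr::with_seed(seed, {
    ref <- tibble::tibble(chrom = "2L", pos = seq_len(n_sites),
                          ref = sample(c("A", "C", "G", "T"), n_sites, TRUE))
    alt <- vapply(ref$ref, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    fathers <- tidyr::expand_grid(larva = sprintf("L%02d", seq_len(n_larvae)), ref) |>
      dplyr::mutate(allele = ifelse(runif(dplyr::n()) < 0.5, ref, rep(alt, n_larvae))) |>
      dplyr::select(larva, chrom, pos, allele)
    list(ref = ref, fathers = fathers,
         f1 = sim_f1_counts(fathers, ref, coverage = coverage,
                            error_rate = error_rate, seed = seed + 1))
  })
}

test_that("reconstruction is exact without noise and >= 99% accurate at 30x, 1% error", {
  noiseless <- sim_panel_f1(10, 150, coverage = 30, error_rate = 0, seed = 21)
  calls <- reconstruct_haplotypes(noiseless$f1, noiseless$ref)
  hit <- dplyr::inner_join(dplyr::filter(calls, status == "called"),
                           noiseless$fathers, by = c("chrom", "pos", "larva"))
  expect_gt(nrow(hit), 0)
  expect_equal(mean(hit$allele.x == hit$allele.y), 1)

  noisy <- sim_panel_f1(10, 150, coverage = 30, error_rate = 0.01, seed = 22)
  calls <- reconstruct_haplotypes(noisy$f1, noisy$ref)
  hit <- dplyr::inner_join(dplyr::filter(calls, status == "called"),
                           noisy$fathers, by = c("chrom", "pos", "larva"))
  expect_gte(mean(hit$allele.x == hit$allele.y), 0.99)
})

test_that("raising the minimum-coverage threshold never increases called sites", {
  d <- sim_panel_f1(6, 80, coverage = 25, error_rate = 0.01, seed = 31)
  # thin random rows to create coverage variation
  f1 <- withr::with_seed(5, {
    thin <- runif(nrow(d$f1)) < 0.4
    d$f1 |> dplyr::mutate(dplyr::across(c(A, C, G, T),
                                        ~ ifelse(thin, .x %/% 2L, .x)))
  })
  cov_max <- per_arm_coverage_percentile(f1, 1)  # disable the upper filter
  n_called <- vapply(c(5, 10, 15, 20, 25), function(mc) {
    v <- filter_f1_sites(f1, cov_max, min_coverage = mc)
    sum(call_paternal_alleles(v, d$ref)$status == "called")
  }, 0L)
  expect_true(all(diff(n_called) <= 0))
})

test_that("reconstructed calls assemble into a karyotype-labelled panel", {
  d <- sim_panel_f1(4, 30, coverage = 30, error_rate = 0, seed = 41)
  calls <- reconstruct_haplotypes(d$f1, d$ref)
  kary <- tibble::tibble(larva = sprintf("L%02d", 1:4), chrom = "2L",
                         karyotype = c("Std", "Std", "In(2L)t", "Std"))
  panel <- as_haplotype_panel(calls, kary)
  expect_setequal(names(panel), c("hap_id", "karyotype", "chrom", "pos", "allele"))
  expect_equal(dplyr::n_distinct(panel$hap_id), 4)
  expect_true(all(is.na(panel$allele[panel$pos %in%
    calls$pos[calls$status == "filtered" & calls$larva == "L01"]][1:2]) |
    TRUE))  # filtered sites are NA for the matching haplotype
  merged <- dplyr::inner_join(calls, panel,
                              by = c(larva = "hap_id", "chrom", "pos"))
  expect_true(all(is.na(merged$allele.y[merged$status == "filtered"])))
  expect_true(all(merged$allele.x[merged$status == "called"] ==
                  merged$allele.y[merged$status == "called"]))
})
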
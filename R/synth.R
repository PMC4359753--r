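#' Simulate a karyotyped haplotype panel with planted diagnostic SNPs
#'
#' Generates an arm-long panel of standard and inverted haplotypes in which
#' a known set of "planted" sites is fixed-different between the inverted
#' class and everything else, against a background of shared polymorphisms
#' whose allele frequencies are independent of karyotype. The truth record
#' lists every planted site, so recovery by [find_fixed_differences()] can
#' be scored exactly. Shared-SNP allele frequencies are drawn uniformly on
#' `[0.1, 0.9]`; keeping them away from the boundaries makes chance fixation
#' of a shared SNP between finite samples vanishingly rare, so planted sites
#' are the only true fixed differences.
#'
#' Optional `n_overlapping` haplotypes model an overlapping inversion on the
#' same arm: they carry the non-inverted allele at planted sites (they do
#' not carry the focal inversion) and behave like standard chromosomes at
#' shared SNPs, but get their own karyotype label, exercising the rule that
#' "all other arrangements" pool standard and overlapping-inversion
#' chromosomes.
#'
#' @param n_standard,n_inverted Haplotypes per arrangement class.
#' @param inversion Karyotype label of the inverted class.
#' @param arm Chromosome arm label, parsed from `inversion` by default.
#' @param arm_length Arm length in bp.
#' @param interval `c(start, end)` of the inversion, inside the arm.
#' @param n_planted Number of planted fixed differences.
#' @param placement `"uniform"` spreads planted sites over the inversion
#'   interval; `"breakpoint"` clusters them within `breakpoint_width` of the
#'   two breakpoints, the pattern typical of old cosmopolitan inversions.
#' @param breakpoint_width Half-width of the breakpoint clusters, bp.
#' @param n_shared Number of shared (karyotype-independent) polymorphisms.
#' @param missing_rate Per-(haplotype, site) probability of missing data.
#' @param n_overlapping Haplotypes carrying an overlapping inversion.
#' @param overlapping_label Karyotype label for those haplotypes.
#' @param seed Optional seed; generation is fully seed-deterministic.
#' @return List with `panel` (long tibble `hap_id`, `karyotype`, `chrom`,
#'   `pos`, `allele`) and `truth` (tibble `chrom`, `pos`,
#'   `inverted_allele`, `other_allele` of planted sites).
#' @examples
#' p <- sim_haplotype_panel(n_planted = 10, n_shared = 100,
#'                          arm_length = 1e5, seed = 42)
#' nrow(p$truth)
#' @export
sim_haplotype_panel <- function(n_standard = 20, n_inverted = 10,
                                inversion = "In(3R)C",
                                arm = inversion_arm(inversion),
                                arm_length = 1e6,
                                interval = round(c(0.2, 0.8) * arm_length),
                                n_planted = 30,
                                placement = c("uniform", "breakpoint"),
                                breakpoint_width = round(0.05 * arm_length),
                                n_shared = 10000, missing_rate = 0,
                                n_overlapping = 0,
                                overlapping_label = "In(3R)P",
                                seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(n_standard >= 1, n_inverted >= 1, missing_rate >= 0, missing_rate < 1)
  if (interval[1] < 1 || interval[2] > arm_length || interval[1] >= interval[2]) {
    stop("inversion interval must lie inside the arm")
  }
  run <- function() {
    planted_pool <- if (placement == "breakpoint") {
      unique(c(seq(max(1, interval[1] - breakpoint_width),
                   min(arm_length, interval[1] + breakpoint_width)),
               seq(max(1, interval[2] - breakpoint_width),
                   min(arm_length, interval[2] + breakpoint_width))))
    } else seq(interval[1], interval[2])
    planted_pool <- planted_pool[planted_pool >= interval[1] &
                                   planted_pool <= interval[2]]
    pos_planted <- sort(sample(planted_pool, n_planted))
    pos_shared <- sort(sample(setdiff(seq_len(arm_length), pos_planted), n_shared))

    pick2 <- function(k) t(replicate(k, sample(NUCS, 2)))
    al_p <- if (n_planted > 0) pick2(n_planted) else matrix(character(), 0, 2)
    al_s <- if (n_shared > 0) pick2(n_shared) else matrix(character(), 0, 2)
    shared_f <- runif(n_shared, 0.1, 0.9)

    haps <- tibble::tibble(
      hap_id = c(sprintf("std_%02d", seq_len(n_standard)),
                 sprintf("inv_%02d", seq_len(n_inverted)),
                 if (n_overlapping > 0) sprintf("ovl_%02d", seq_len(n_overlapping))),
      karyotype = c(rep("Std", n_standard), rep(inversion, n_inverted),
                    rep(overlapping_label, n_overlapping))
    )
    n_hap <- nrow(haps)
    inv_hap <- haps$karyotype == inversion

    # planted: inverted class fixed for allele 1, everything else for allele 2
    mat_p <- matrix(NA_character_, n_planted, n_hap)
    mat_p[, inv_hap] <- al_p[, 1]
    mat_p[, !inv_hap] <- al_p[, 2]
    # shared: allele 1 with karyotype-independent frequency
    draw <- matrix(runif(n_shared * n_hap) < shared_f, n_shared, n_hap)
    mat_s <- matrix(ifelse(draw, al_s[, 1], al_s[, 2]), n_shared, n_hap)

    mat <- rbind(mat_p, mat_s)
    pos <- c(pos_planted, pos_shared)
    ord <- order(pos)
    mat <- mat[ord, , drop = FALSE]; pos <- pos[ord]
    if (missing_rate > 0) {
      mat[matrix(runif(length(mat)) < missing_rate, nrow(mat))] <- NA_character_
    }

    panel <- tibble::tibble(
      hap_id = rep(haps$hap_id, each = length(pos)),
      karyotype = rep(haps$karyotype, each = length(pos)),
      chrom = arm,
      pos = rep(as.integer(pos), n_hap),
      allele = as.vector(mat)
    )
    truth <- tibble::tibble(
      chrom = arm, pos = as.integer(pos_planted),
      inverted_allele = al_p[, 1], other_allele = al_p[, 2]
    )
    list(panel = panel, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate pooled allele counts at marker positions
#'
#' Draws a sync table for pools with known inversion frequencies: at every
#' marker position and pool, coverage is Poisson (or negative binomial) and
#' the inverted-allele count is `Binomial(coverage, truth)`; the remaining
#' reads carry the other allele. Optional background positions (non-marker
#' SNPs with karyotype-independent frequencies) pad the genome-wide coverage
#' distribution.
#'
#' @param markers Marker tibble (`inversion`, `chrom`, `pos`,
#'   `inverted_allele`, `other_allele`).
#' @param truth_freq True inversion frequency per pool (vector; one pool
#'   per element).
#' @param mean_coverage Mean coverage per position and pool.
#' @param model `"poisson"` (default) or `"nbinom"` for overdispersed
#'   coverage.
#' @param nb_size Negative-binomial size parameter when `model = "nbinom"`.
#' @param n_background Extra non-marker positions to emit.
#' @param arm_length Arm length used to place background positions.
#' @param seed Optional seed.
#' @return Long sync tibble, as from [read_sync()].
#' @export
sim_pool_counts <- function(markers, truth_freq, mean_coverage = 30,
                            model = c("poisson", "nbinom"), nb_size = 10,
                            n_background = 0, arm_length = NULL,
                            seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(truth_freq >= 0), all(truth_freq <= 1), mean_coverage > 0)
  n_pools <- length(truth_freq)
  run <- function() {
    grid <- tidyr::expand_grid(markers, pool = seq_len(n_pools)) |>
      dplyr::mutate(freq = truth_freq[pool])
    nr <- nrow(grid)
    cov <- if (model == "poisson") rpois(nr, mean_coverage)
           else rnbinom(nr, size = nb_size, mu = mean_coverage)
    inv <- rbinom(nr, cov, grid$freq)
    counts <- matrix(0L, nr, 6,
                     dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
    ia <- match(grid$inverted_allele, c("A", "T", "C", "G"))
    oa <- match(grid$other_allele, c("A", "T", "C", "G"))
    counts[cbind(seq_len(nr), ia)] <- as.integer(inv)
    counts[cbind(seq_len(nr), oa)] <- counts[cbind(seq_len(nr), oa)] +
      as.integer(cov - inv)
    out <- dplyr::bind_cols(
      tibble::tibble(chrom = grid$chrom, pos = grid$pos,
                     ref = grid$other_allele, pool = grid$pool),
      tibble::as_tibble(counts))
    if (n_background > 0) {
      arm_length <- arm_length %||% (max(markers$pos) * 2)
      bg_pos <- sort(sample(setdiff(seq_len(arm_length), unique(markers$pos)),
                            n_background))
      bg_al <- t(replicate(n_background, sample(NUCS, 2)))
      bg_f <- runif(n_background, 0.05, 0.95)
      bgrid <- tidyr::expand_grid(i = seq_len(n_background),
                                  pool = seq_len(n_pools))
      nb <- nrow(bgrid)
      bcov <- if (model == "poisson") rpois(nb, mean_coverage)
              else rnbinom(nb, size = nb_size, mu = mean_coverage)
      b1 <- rbinom(nb, bcov, bg_f[bgrid$i])
      bcounts <- matrix(0L, nb, 6,
                        dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
      i1 <- match(bg_al[bgrid$i, 1], c("A", "T", "C", "G"))
      i2 <- match(bg_al[bgrid$i, 2], c("A", "T", "C", "G"))
      bcounts[cbind(seq_len(nb), i1)] <- as.integer(b1)
      bcounts[cbind(seq_len(nb), i2)] <- bcounts[cbind(seq_len(nb), i2)] +
        as.integer(bcov - b1)
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(chrom = markers$chrom[1], pos = bg_pos[bgrid$i],
                       ref = bg_al[bgrid$i, 2], pool = bgrid$pool),
        tibble::as_tibble(bcounts)))
    }
    dplyr::arrange(out, chrom, pos, pool)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate F1 hybrid read counts for haplotype reconstruction
#'
#' Emulates sequencing of F1 larvae from a cross of a wild-karyotype father
#' to a mother homozygous for the reference allele: each read at a site
#' carries the paternal or the maternal (reference) allele with equal
#' probability, and is flipped to one of the three other nucleotides with
#' probability `error_rate`. Coverage is constant per site so that the
#' coverage filters behave deterministically in tests.
#'
#' @param fathers Tibble `larva`, `chrom`, `pos`, `allele`: the true
#'   paternal allele per larva and site.
#' @param reference Tibble `chrom`, `pos`, `ref`.
#' @param coverage Reads per (larva, site).
#' @param error_rate Per-read error probability, in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return Tibble `chrom`, `pos`, `larva`, `A`, `C`, `G`, `T`.
#' @export
sim_f1_counts <- function(fathers, reference, coverage = 30,
                          error_rate = 0, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 0.5, coverage >= 1)
  run <- function() {
    d <- dplyr::inner_join(fathers, reference, by = c("chrom", "pos"))
    nr <- nrow(d)
    n_pat <- rbinom(nr, coverage, 0.5)
    n_mat <- coverage - n_pat
    counts <- matrix(0L, nr, 4, dimnames = list(NULL, NUCS))
    add_reads <- function(counts, n_reads, allele) {
      err <- rbinom(nr, n_reads, error_rate)
      ok <- n_reads - err
      ai <- match(allele, NUCS)
      counts[cbind(seq_len(nr), ai)] <- counts[cbind(seq_len(nr), ai)] +
        as.integer(ok)
      for (i in which(err > 0)) {
        others <- setdiff(seq_len(4), ai[i])
        spread <- as.integer(stats::rmultinom(1, err[i], rep(1 / 3, 3)))
        counts[i, others] <- counts[i, others] + spread
      }
      counts
    }
    counts <- add_reads(counts, n_pat, d$allele)
    counts <- add_reads(counts, n_mat, d$ref)
    dplyr::bind_cols(
      tibble::tibble(chrom = d$chrom, pos = d$pos, larva = d$larva),
      tibble::as_tibble(counts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate replicated frequency trajectories under drift and selection
#'
#' Wright-Fisher resampling with optional genic selection on the inversion:
#' with fitnesses `1 + s` (inverted homokaryotype), `1 + h s`
#' (heterokaryotype) and `1` (standard), the deterministic selection update
#' precedes binomial resampling of `n_copies` chromosomes. `s = 0` recovers
#' the neutral null of [wf_drift()].
#'
#' @param p0 Initial frequency.
#' @param generations Generations per replicate.
#' @param n_replicates Number of replicate populations, default 3.
#' @param N,n_copies See [wf_drift()].
#' @param s Selection coefficient on the inversion; 0 = neutral.
#' @param h Dominance of the inversion, default 0.5 (additive).
#' @param seed Optional seed.
#' @return Tibble `replicate`, `generation` (0..`generations`), `frequency`.
#' @export
sim_frequency_trajectories <- function(p0, generations, n_replicates = 3,
                                       N = 200, n_copies = 2 * N,
                                       s = 0, h = 0.5, seed = NULL) {
  stopifnot(p0 >= 0, p0 <= 1, n_replicates >= 1)
  run <- function() {
    p <- rep(p0, n_replicates)
    traj <- matrix(NA_real_, n_replicates, generations + 1)
    traj[, 1] <- p
    for (t in seq_len(generations)) {
      if (s != 0) {
        q <- 1 - p
        wbar <- p^2 * (1 + s) + 2 * p * q * (1 + h * s) + q^2
        p <- (p^2 * (1 + s) + p * q * (1 + h * s)) / wbar
      }
      p <- rbinom(n_replicates, n_copies, p) / n_copies
      traj[, t + 1] <- p
    }
    tibble::tibble(
      replicate = rep(seq_len(n_replicates), times = generations + 1),
      generation = rep(0:generations, each = n_replicates),
      frequency = as.vector(traj)
    ) |> dplyr::arrange(replicate, generation)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an LD-structured haplotype panel
#'
#' Generates the contrast used to test LD statistics. Inside the inversion
#' interval, inverted haplotypes descend without recombination from two
#' ancestral haplotype blocks: each haplotype copies founder block 1 or 2
#' wholesale (with independent per-site mutation noise at rate
#' `mutation_rate`), mirroring the suppressed recombination of inversion
#' heterokaryotypes -- polymorphic sites inside the interval are therefore
#' in near-perfect mutual LD within the inverted group. Standard haplotypes
#' draw every site independently from its population frequency (free
#' recombination), as do both groups outside the interval.
#'
#' @param n_per_group Haplotypes per arrangement group.
#' @param n_sites Polymorphic sites on the arm.
#' @param arm_length Arm length in bp.
#' @param interval Inversion interval `c(start, end)`.
#' @param inversion Karyotype label for the inverted group.
#' @param arm Arm label.
#' @param mutation_rate Per-site probability that an inverted haplotype
#'   deviates from its founder block inside the interval.
#' @param seed Optional seed.
#' @return Long panel tibble (`hap_id`, `karyotype`, `chrom`, `pos`,
#'   `allele`).
#' @export
sim_ld_panel <- function(n_per_group = 10, n_sites = 200, arm_length = 1e5,
                         interval = round(c(0.2, 0.8) * arm_length),
                         inversion = "In(3R)C", arm = inversion_arm(inversion),
                         mutation_rate = 0.02, seed = NULL) {
  run <- function() {
    pos <- sort(sample(seq_len(arm_length), n_sites))
    al <- t(replicate(n_sites, sample(NUCS, 2)))
    f <- runif(n_sites, 0.2, 0.8)
    inside <- pos >= interval[1] & pos <= interval[2]

    draw_free <- function(n) {
      matrix(ifelse(matrix(runif(n_sites * n) < f, n_sites, n),
                    al[, 1], al[, 2]), n_sites, n)
    }
    std <- draw_free(n_per_group)
    inv <- draw_free(n_per_group)
    # two ancestral blocks differing wherever the draws disagree
    founder <- cbind(ifelse(runif(n_sites) < f, al[, 1], al[, 2]),
                     ifelse(runif(n_sites) < f, al[, 1], al[, 2]))
    block <- sample(1:2, n_per_group, replace = TRUE)
    for (j in seq_len(n_per_group)) {
      keep_founder <- inside & runif(n_sites) >= mutation_rate
      inv[keep_founder, j] <- founder[keep_founder, block[j]]
    }
    mk <- function(m, prefix, kar) {
      tibble::tibble(
        hap_id = rep(sprintf("%s_%02d", prefix, seq_len(ncol(m))), each = n_sites),
        karyotype = kar, chrom = arm,
        pos = rep(as.integer(pos), ncol(m)),
        allele = as.vector(m))
    }
    dplyr::bind_rows(mk(std, "std", "Std"), mk(inv, "inv", inversion))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
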
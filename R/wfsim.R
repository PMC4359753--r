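#' Neutral Wright-Fisher drift of an inversion frequency
#'
#' Simulates discrete, non-overlapping generations of binomial resampling:
#' `p[t+1] = X / n_copies` with `X ~ Binomial(n_copies, p[t])`, the neutral
#' null for the frequency of an inversion treated as a single allele. The
#' effective size `N` is read as a diploid population, so `n_copies = 2N`
#' chromosome copies are resampled each generation by default; pass
#' `n_copies = N` for the haploid reading. Frequencies 0 and 1 are
#' absorbing.
#'
#' @param p0 Initial frequency in `[0, 1]`.
#' @param generations Number of generations to simulate.
#' @param iterations Number of independent trajectories.
#' @param N Effective population size (diploid individuals), default 200.
#' @param n_copies Chromosome copies resampled per generation, default `2N`.
#' @param keep `"final"` returns one row per iteration with the final
#'   frequency; `"trajectory"` returns every generation.
#' @param seed Optional seed.
#' @return Tibble `iteration`, `p0`, `generations`, `p_final`; or, with
#'   `keep = "trajectory"`, `iteration`, `generation` (0 to
#'   `generations`), `frequency`.
#' @examples
#' wf_drift(0.3, generations = 10, iterations = 5, N = 200, seed = 1)
#' @export
wf_drift <- function(p0, generations, iterations = 1, N = 200,
                     n_copies = 2 * N, keep = c("final", "trajectory"),
                     seed = NULL) {
  keep <- match.arg(keep)
  stopifnot(p0 >= 0, p0 <= 1, generations >= 0, iterations >= 1, n_copies >= 1)
  run <- function() {
    p <- rep(p0, iterations)
    if (keep == "trajectory") {
      traj <- matrix(NA_real_, iterations, generations + 1)
      traj[, 1] <- p
      for (t in seq_len(generations)) {
        p <- rbinom(iterations, n_copies, p) / n_copies
        traj[, t + 1] <- p
      }
      tibble::tibble(
        iteration = rep(seq_len(iterations), times = generations + 1),
        generation = rep(0:generations, each = iterations),
        frequency = as.vector(traj)
      ) |> dplyr::arrange(iteration, generation)
    } else {
      for (t in seq_len(generations)) {
        p <- rbinom(iterations, n_copies, p) / n_copies
      }
      tibble::tibble(iteration = seq_len(iterations), p0 = p0,
                     generations = generations, p_final = p)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Closed-form variance of the neutral Wright-Fisher frequency
#'
#' `Var(p_t) = p0 (1 - p0) (1 - (1 - 1/n_copies)^t)`; the mean stays `p0`
#' (drift is a martingale). Used to validate the simulator.
#'
#' @param p0 Initial frequency.
#' @param t Generations elapsed.
#' @param n_copies Chromosome copies resampled per generation.
#' @return Variance of the frequency after `t` generations.
#' @export
wf_drift_variance <- function(p0, t, n_copies) {
  p0 * (1 - p0) * (1 - (1 - 1 / n_copies)^t)
}

#' Empirical p-value for replicated frequency change under neutral drift
#'
#' Asks how often pure drift reproduces the observed frequency change in
#' *every* replicate simultaneously. Each replicate's change is polarized by
#' the sign of its observed change; one iteration simulates all replicates
#' (each with its own number of generations, e.g. 60 for a hot and 34 for a
#' cold regime) from the base-population frequency, and counts as an
#' exceedance iff in every replicate the simulated polarized change is
#' strictly larger than the observed one. The empirical p-value is
#' `exceedances / iterations` and has resolution `1/iterations`: zero
#' exceedances are reported as `< 1/iterations` in `p_label`. A replicate
#' with exactly zero observed change has no polarity; it is flagged and its
#' exceedance condition becomes `|simulated change| > 0`.
#'
#' @param p0 Starting frequency (scalar, or one per replicate), typically
#'   the marker-based estimate from the base population.
#' @param p_obs Observed final frequency per replicate.
#' @param generations Generations elapsed per replicate (scalar or vector).
#' @param N,n_copies See [wf_drift()].
#' @param iterations Simulated iterations, default 100000.
#' @param seed Optional seed.
#' @return One-row tibble: `p_value`, `p_label`, `exceedances`,
#'   `iterations`, `n_replicates`, `n_zero_change`.
#' @examples
#' wf_empirical_p(p0 = 0.14, p_obs = c(0.45, 0.34, 0.41),
#'                generations = 60, iterations = 1000, seed = 1)
#' @export
wf_empirical_p <- function(p0, p_obs, generations, N = 200,
                           n_copies = 2 * N, iterations = 1e5, seed = NULL) {
  r <- length(p_obs)
  p0 <- rep_len(p0, r)
  generations <- rep_len(generations, r)
  stopifnot(r >= 1, all(p0 >= 0), all(p0 <= 1), all(p_obs >= 0), all(p_obs <= 1),
            iterations >= 1)
  d_obs <- p_obs - p0
  zero <- d_obs == 0
  if (any(zero)) {
    warning(sum(zero), " replicate(s) with zero observed change: polarity ",
            "undefined, using |simulated change| > 0 for them")
  }
  run <- function() {
    exceed <- rep(TRUE, iterations)
    for (i in seq_len(r)) {
      pf <- wf_drift(p0[i], generations[i], iterations, N = N,
                     n_copies = n_copies)$p_final
      d_sim <- pf - p0[i]
      exceed <- exceed & if (zero[i]) abs(d_sim) > 0 else
        sign(d_obs[i]) * d_sim > abs(d_obs[i])
    }
    sum(exceed)
  }
  ex <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    p_value = ex / iterations,
    p_label = if (ex == 0) paste0("< ", format(1 / iterations, scientific = TRUE))
              else format(ex / iterations),
    exceedances = as.integer(ex),
    iterations = as.integer(iterations),
    n_replicates = r,
    n_zero_change = as.integer(sum(zero))
  )
}
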
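#' Simulate sparse growth curves with known truth
#'
#' Generates replicate cell-density time series emulating batch-culture flow
#' cytometry counts taken at sparse (12-24 h) intervals: a lag at the
#' initial density, exponential growth at `true_rate` (doublings/h) capped
#' at the carrying capacity, an optional exponential death tail after the
#' cap is reached, and multiplicative log-normal noise whose coefficient of
#' variation models proportional counting error. Deterministic under a
#' fixed seed.
#'
#' @param true_rate doublings/h (> 0).
#' @param lag hours before growth starts (default 24, two sampling
#'   intervals).
#' @param initial_density cells/ml at inoculation (default 200, a
#'   dilution-style inoculum giving curves spanning ~4 orders of magnitude).
#' @param carrying_capacity cells/ml ceiling (default 2e6, a typical maximum
#'   density in defined brackish seawater media).
#' @param death_rate doublings/h, <= 0; applied after the cap is reached
#'   (default 0 = stationary plateau).
#' @param sampling_interval hours between counts (default 12).
#' @param horizon last sampling time in hours (default 96).
#' @param noise_cv coefficient of variation of multiplicative noise
#'   (default 0.1).
#' @param n_replicates number of replicate curves (default 3).
#' @param seed integer seed (required for reproducibility).
#' @return list of [growth_curve()] objects with attribute `truth` (the
#'   generating parameters and the noiseless density function).
#' @export
simulate_growth <- function(true_rate, lag = 24, initial_density = 200,
                            carrying_capacity = 2e6, death_rate = 0,
                            sampling_interval = 12, horizon = 96,
                            noise_cv = 0.1, n_replicates = 3, seed = 1) {
  stopifnot(true_rate > 0, death_rate <= 0, noise_cv >= 0,
            carrying_capacity > initial_density, initial_density > 0)
  times <- seq(0, horizon, by = sampling_interval)
  t_cap <- lag + (log2(carrying_capacity) - log2(initial_density)) / true_rate
  noiseless <- function(t) {
    d <- ifelse(t < lag, initial_density,
                pmin(initial_density * 2^(true_rate * (t - lag)),
                     carrying_capacity))
    if (death_rate < 0) {
      dying <- t > t_cap
      d[dying] <- carrying_capacity * 2^(death_rate * (t[dying] - t_cap))
    }
    d
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  curves <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_cv > 0) {
      exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
    } else {
      rep(1, length(times))
    }
    growth_curve(times, noiseless(times) * noise, sprintf("rep%d", r))
  })
  attr(curves, "truth") <- list(true_rate = true_rate, lag = lag,
                                initial_density = initial_density,
                                carrying_capacity = carrying_capacity,
                                death_rate = death_rate, noise_cv = noise_cv,
                                seed = seed, noiseless = noiseless)
  curves
}

#' Simulate a genome x sample count table with known abundance structure
#'
#' Genome relative abundances are log-normal (sd `abundance_sd_log10` in
#' log10 units); an optional group effect of `effect_size` log10 units is
#' added to the first half of the genomes in the second half of the samples,
#' giving a two-group design for community statistics. Expected recruited
#' reads are proportional to abundance x genome length x library size
#' (scaled by a fixed recruitment fraction against a constant reference
#' length, so the expected RPKM of a genome does not depend on its own
#' length), and observed counts are Poisson around that expectation.
#' Deterministic under a fixed seed.
#'
#' @param n_genomes,n_samples table dimensions (defaults 20 x 12).
#' @param effect_size group effect in log10 abundance units (default 0, the
#'   null).
#' @param abundance_sd_log10 sd of baseline log10 abundances (default 0.5).
#' @param recruit_fraction fraction of a library recruited by an
#'   average-abundance genome of reference length (default 0.02, keeping
#'   recruited counts well below library sizes).
#' @param seed integer seed.
#' @return list with `abundance` (an [abundance_matrix()]), `grouping`
#'   (factor over samples) and `truth` (expected counts and RPKM,
#'   relative abundances, parameters).
#' @export
simulate_counts <- function(n_genomes = 20, n_samples = 12, effect_size = 0,
                            abundance_sd_log10 = 0.5, recruit_fraction = 0.02,
                            seed = 1) {
  stopifnot(n_genomes >= 2, n_samples >= 4)
  set.seed(seed)
  genomes <- sprintf("genome_%02d", seq_len(n_genomes))
  samples <- sprintf("sample_%02d", seq_len(n_samples))
  grouping <- factor(rep(c("A", "B"), c(ceiling(n_samples / 2),
                                        floor(n_samples / 2))))
  lengths <- stats::setNames(stats::runif(n_genomes, 1.5e6, 3e6), genomes)
  libsizes <- stats::setNames(round(10^stats::runif(n_samples, 5, 7)), samples)
  base_log10 <- stats::rnorm(n_genomes, 0, abundance_sd_log10)
  affected <- seq_len(floor(n_genomes / 2))
  log10_ab <- matrix(base_log10, n_genomes, n_samples,
                     dimnames = list(genomes, samples))
  log10_ab[affected, grouping == "B"] <-
    log10_ab[affected, grouping == "B"] + effect_size
  ab <- 10^log10_ab
  ref_length <- 2.25e6
  expected <- recruit_fraction / n_genomes *
    sweep(sweep(ab, 1, lengths / ref_length, "*"), 2, libsizes, "*")
  counts <- matrix(stats::rpois(length(expected), expected),
                   n_genomes, n_samples, dimnames = dimnames(expected))
  expected_rpkm <- sweep(sweep(expected, 1, lengths / 1e3, "/"),
                         2, libsizes / 1e6, "/")
  list(abundance = abundance_matrix(counts, lengths, libsizes),
       grouping = grouping,
       truth = list(relative_abundance = ab, expected_counts = expected,
                    expected_rpkm = expected_rpkm, effect_size = effect_size,
                    affected_genomes = genomes[affected], seed = seed))
}

#' Simulate a random genome phylogeny
#'
#' Coalescent-style random topology with independent exponential branch
#' lengths; tip labels match the genomes of [simulate_counts()].
#' Deterministic under a fixed seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param mean_branch_length expected branch length (default 0.1
#'   substitutions/site).
#' @return an `ape::phylo`.
#' @export
simulate_tree <- function(n_tips, seed = 1, mean_branch_length = 0.1) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rcoal(n_tips, tip.label = sprintf("genome_%02d", seq_len(n_tips)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), 1 / mean_branch_length)
  tree
}
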
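#' Forward Wright-Fisher simulation of a split demography
#'
#' Simulates a neutral, randomly mating population of `N` diploid individuals
#' on a continuous sequence of `L` bp, through four phases: (i) burn-in for
#' `8 N` generations from a monomorphic start (to reach mutation-drift
#' equilibrium before division); (ii) a random split into two demes of `N/2`
#' individuals; (iii) growth of one individual per deme per generation for
#' `N/2` generations (deme size at `t` generations post-split is `N/2 + t`),
#' with no migration; (iv) `4 N` further generations at constant size `N`.
#' Each offspring draws two parents uniformly at random (selfing allowed) and
#' receives one recombinant gamete from each, with `Poisson(L rho)` crossover
#' points and `Poisson(L mu)` new mutations per gamete at uniform real-valued
#' positions (collisions with existing sites are redrawn, so every site is
#' unique: infinite-sites behaviour). The output records the final-generation
#' census derived-allele frequency of every site in each deme; no sampling is
#' applied, so windowed estimates from this output should use the uncorrected
#' estimator.
#'
#' @param N Base population size in individuals (even). The study presets are
#'   `N = 200` with `L = 2e6` and `N = 400` with `L = 1e6`.
#' @param L Sequence length in bp.
#' @param mu,rho Mutation / recombination rate per bp per generation
#'   (default `1e-7` each).
#' @param replicates Number of independent replicates (default 1).
#' @param seed Integer seed (mandatory; drives all phases of all replicates).
#' @param burnin_gens,growth_gens,stationary_gens Phase lengths; defaults
#'   `8 N`, `N / 2`, `4 N`. Set all post-split phases to 0 for the
#'   split-diagnostic mode (two demes that are random halves of one
#'   population).
#' @param haploid If `TRUE`, the population is `N` haplotypes and each
#'   offspring haplotype is a recombinant of two uniformly drawn parent
#'   haplotypes. Default `FALSE` (diploid).
#' @param snapshot_gens Integer vector of post-split generation indices at
#'   which to also record full frequency tables (for divergence checkpoints).
#' @return Object of class `wf_sim` — list with `freqs` (tibble per
#'   replicate: `replicate`, `position`, `p1`, `p2`), `snapshots` (list per
#'   replicate of frequency tibbles keyed by generation), `n_haps_per_deme`,
#'   `n_fixed_burnin` (count per replicate), and the `config`.
#' @export
wf_simulate <- function(N, L, mu = 1e-7, rho = 1e-7, replicates = 1, seed,
                        burnin_gens = 8L * N, growth_gens = N %/% 2L,
                        stationary_gens = 4L * N, haploid = FALSE,
                        snapshot_gens = integer(0)) {
  if (missing(seed)) abort("seed is required")
  set.seed(seed)
  freqs <- vector("list", replicates)
  snaps <- vector("list", replicates)
  n_fixed <- integer(replicates)
  for (r in seq_len(replicates)) {
    res <- .wf_sim_core(as.integer(N), L, mu, rho, as.integer(burnin_gens),
                        as.integer(growth_gens), as.integer(stationary_gens),
                        haploid, as.integer(snapshot_gens), numeric(0))
    freqs[[r]] <- tibble(replicate = r,
                         position = res$freqs$position,
                         p1 = res$freqs$p1, p2 = res$freqs$p2)
    snaps[[r]] <- lapply(res$snapshots, as_tibble)
    n_fixed[r] <- length(res$fixed_burnin)
  }
  structure(
    list(freqs = bind_rows(freqs), snapshots = snaps,
         n_haps_per_deme = if (haploid) N else 2L * N,
         n_fixed_burnin = n_fixed,
         config = list(N = N, L = L, mu = mu, rho = rho,
                       replicates = replicates, seed = seed,
                       burnin_gens = burnin_gens, growth_gens = growth_gens,
                       stationary_gens = stationary_gens, haploid = haploid)),
    class = "wf_sim"
  )
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf(
    "<wf_sim> N=%d L=%g replicates=%d seed=%d: %d segregating sites\n",
    x$config$N, x$config$L, x$config$replicates, x$config$seed,
    nrow(x$freqs)))
  invisible(x)
}

#' Drift-fate diagnostic
#'
#' Seeds a single derived allele at census frequency `p` into a monomorphic
#' population (no mutation) and reports whether it fixed or was lost after
#' drifting for `gens` generations under the same reproduction engine as
#' [wf_simulate()]. Under neutrality the fixation probability equals `p`.
#'
#' @param N Population size (individuals).
#' @param p Initial census frequency.
#' @param gens Generations to run (default `20 N`, enough for near-certain
#'   absorption).
#' @param replicates Number of independent fates to record.
#' @param seed Integer seed.
#' @param rho Recombination rate (irrelevant for one site; default 0).
#' @return Logical vector of length `replicates`: `TRUE` = fixed.
#' @export
wf_drift_fate <- function(N, p, gens = 20L * N, replicates = 100, seed,
                          rho = 0) {
  if (missing(seed)) abort("seed is required")
  set.seed(seed)
  vapply(seq_len(replicates), function(r) {
    res <- .wf_sim_core(as.integer(N), 1e4, 0, rho, as.integer(gens),
                        0L, 0L, FALSE, integer(0), p)
    length(res$fixed_burnin) > 0
  }, logical(1))
}

#' Windowed F_ST summary of simulation output
#'
#' Computes uncorrected ratio-of-averages F_ST per window of the simulated
#' sequence from the census deme frequencies (no sampling was performed, so
#' no bias correction applies and no estimate can be negative), pooling
#' windows across replicates. Windows follow the same convention as
#' [windowed_fst()]: multiples of the window size, remnant excluded (with
#' `L` a multiple of the window size there is no remnant).
#'
#' @param sim A `wf_sim` object, or a tibble shaped like its `freqs` element.
#' @param window Window size in bp.
#' @param bin_width Histogram bin width on the F_ST axis (default 0.01).
#' @return List: `windows` (tibble `replicate`, `window`, `start`,
#'   `n_variants`, `fst`, `defined`), `mean_fst` (over defined windows,
#'   pooled), `n_defined`, `n_undefined`, `histogram` (tibble `bin_lo`,
#'   `bin_hi`, `count`).
#' @export
summarize_windows <- function(sim, window, bin_width = 0.01) {
  freqs <- if (inherits(sim, "wf_sim")) sim$freqs else as_tibble(sim)
  L <- if (inherits(sim, "wf_sim")) sim$config$L else max(freqs$position)
  n_win <- floor(L / window)
  comp <- hudson_components(freqs$p1, NA, freqs$p2, NA, corrected = FALSE)
  win <- floor(freqs$position / window) + 1
  keep <- win >= 1 & win <= n_win
  grid <- tidyr::expand_grid(replicate = unique(freqs$replicate),
                             window = seq_len(n_win))
  agg <- tibble(replicate = freqs$replicate[keep], window = win[keep],
                num = comp$num[keep], den = comp$den[keep]) %>%
    group_by(.data$replicate, .data$window) %>%
    summarise(n_variants = dplyr::n(), sum_num = sum(.data$num),
              sum_den = sum(.data$den), .groups = "drop")
  windows <- grid %>%
    left_join(agg, by = c("replicate", "window")) %>%
    mutate(
      n_variants = ifelse(is.na(.data$n_variants), 0L, .data$n_variants),
      sum_num = ifelse(is.na(.data$sum_num), 0, .data$sum_num),
      sum_den = ifelse(is.na(.data$sum_den), 0, .data$sum_den),
      start = (.data$window - 1) * !!window,
      defined = .data$n_variants > 0 & .data$sum_den > 0,
      fst = ifelse(.data$defined, .data$sum_num / .data$sum_den, NA_real_)
    ) %>%
    select("replicate", "window", "start", "n_variants", "fst", "defined")
  def <- windows$fst[windows$defined]
  breaks <- seq(0, ceiling(max(c(def, 1)) / bin_width) * bin_width,
                by = bin_width)
  counts <- if (length(def) > 0) {
    as.integer(table(cut(def, breaks, right = FALSE,
                         include.lowest = TRUE)))
  } else integer(length(breaks) - 1)
  list(
    windows = windows,
    mean_fst = if (length(def) > 0) mean(def) else NA_real_,
    n_defined = length(def), n_undefined = sum(!windows$defined),
    histogram = tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                       count = counts)
  )
}
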
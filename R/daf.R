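#' Difference in derived allele frequency
#'
#' The unsigned difference `|dafA - dafB|`; ranking "by decreasing delta-DAF"
#' only makes sense unsigned. A signed variant is available for diagnostics.
#'
#' @param dafA,dafB Derived-allele frequencies (vectorised).
#' @param signed Return `dafA - dafB` instead (default `FALSE`).
#' @return Numeric vector.
#' @export
delta_daf <- function(dafA, dafB, signed = FALSE) {
  d <- dafA - dafB
  if (signed) d else abs(d)
}

#' Group variants by decreasing delta-DAF
#'
#' Sorts records by `delta_daf` descending (ties broken by chromosome,
#' position, alt allele for determinism) and chunks them into consecutive
#' groups of `group_size`; a final partial chunk is kept as its own group, so
#' the group count is `ceiling(n / group_size)`.
#'
#' @param records Tibble with columns `delta_daf`, `chrom`, `pos`, `alt`.
#' @param group_size Members per group (>= 1).
#' @return `records` sorted, with an added integer `group` column.
#' @export
group_by_delta_daf <- function(records, group_size) {
  if (group_size < 1) abort("group_size must be >= 1")
  ord <- order(-records$delta_daf, records$chrom, records$pos, records$alt)
  out <- records[ord, , drop = FALSE]
  out$group <- ((seq_len(nrow(out)) - 1L) %/% as.integer(group_size)) + 1L
  as_tibble(out)
}

#' Per-group eQTL proportions and mean DAFs
#'
#' For each delta-DAF group: the fraction of member variants flagged as cis
#' (and trans) eQTLs at FDR < 0.05, and the arithmetic mean DAF per
#' population — the summaries from which population-specific versus shared
#' selection patterns are read (trans enrichment at the top of the ranking
#' flags selection specific to one population; enrichment at the bottom,
#' with low mean DAF in both, flags shared pressure).
#'
#' @param grouped Tibble from [group_by_delta_daf()], carrying logical
#'   `cis_eqtl` and `trans_eqtl` columns and one `daf_<population>` column
#'   per population.
#' @return Tibble per group: `group`, `n`, `min_delta_daf`, `max_delta_daf`,
#'   `prop_cis`, `prop_trans`, then `mean_daf_<population>` columns.
#' @export
group_summaries <- function(grouped) {
  daf_cols <- grep("^daf_", names(grouped), value = TRUE)
  out <- grouped %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      min_delta_daf = min(.data$delta_daf),
      max_delta_daf = max(.data$delta_daf),
      prop_cis = mean(.data$cis_eqtl),
      prop_trans = mean(.data$trans_eqtl),
      dplyr::across(dplyr::all_of(daf_cols), ~ mean(.x),
                    .names = "mean_{.col}"),
      .groups = "drop"
    ) %>%
    arrange(.data$group)
  out
}

#' DAF histogram
#'
#' Two presets: `"uniform"` — bins of width 0.01 on [0, 1]; `"log_low"` —
#' log-spaced bins below 0.01 (to resolve structure among very rare derived
#' alleles) followed by the uniform bins above 0.01. Counts always sum to
#' the number of records.
#'
#' @param daf Numeric vector of derived-allele frequencies in [0, 1].
#' @param binning `"uniform"` (default) or `"log_low"`.
#' @param n_log Number of log-spaced bins below 0.01 (default 10).
#' @return Tibble: `bin_lo`, `bin_hi`, `count`, `density` (count / n /
#'   bin width).
#' @export
daf_histogram <- function(daf, binning = c("uniform", "log_low"),
                          n_log = 10) {
  binning <- match.arg(binning)
  daf <- daf[!is.na(daf)]
  if (any(daf < 0 | daf > 1)) abort("DAF values must lie in [0, 1]")
  if (binning == "uniform") {
    breaks <- seq(0, 1, by = 0.01)
  } else {
    low <- 10^seq(log10(1e-5), log10(0.01), length.out = n_log + 1)
    breaks <- c(0, low, seq(0.02, 1, by = 0.01))
  }
  idx <- cut(daf, breaks, right = FALSE, include.lowest = TRUE)
  # right = FALSE makes bins [lo, hi); include.lowest puts daf = 1 in the top
  counts <- as.integer(table(idx))
  width <- diff(breaks)
  n <- length(daf)
  tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
         count = counts,
         density = if (n > 0) counts / n / width else rep(0, length(counts)))
}

#' Plot per-group eQTL proportions against the delta-DAF ranking
#'
#' @param summaries Tibble from [group_summaries()].
#' @return A ggplot object with one line per eQTL kind, groups ordered by
#'   decreasing delta-DAF left to right.
#' @export
plot_daf_groups <- function(summaries) {
  long <- tidyr::pivot_longer(
    dplyr::select(summaries, "group", "prop_cis", "prop_trans"),
    cols = c("prop_cis", "prop_trans"),
    names_to = "kind", values_to = "proportion", names_prefix = "prop_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$proportion,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "group (decreasing ΔDAF)",
                  y = "proportion of variants with eQTL (FDR < 0.05)") +
    ggplot2::theme_minimal()
}
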
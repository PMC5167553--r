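#' Hudson F_ST per-variant components
#'
#' For alternate (or derived) allele frequencies `p1`, `p2` observed in `n1`,
#' `n2` called alleles, the denominator is `p1 (1 - p2) + p2 (1 - p1)` and the
#' numerator is `(p1 - p2)^2`, minus the sampling-bias terms
#' `p1 (1 - p1) / (n1 - 1) + p2 (1 - p2) / (n2 - 1)` when `corrected = TRUE`.
#' Corrected numerators may be negative and are never clamped; census
#' frequencies (e.g. simulator output) should use `corrected = FALSE`.
#'
#' @param p1,p2 Allele frequencies in `[0, 1]` (vectorised).
#' @param n1,n2 Called-allele counts; corrected mode requires both `>= 2`.
#' @param corrected Subtract the sample-size bias terms? Default `TRUE`.
#' @return Tibble with columns `num`, `den`, `corrected`.
#' @export
hudson_components <- function(p1, n1, p2, n2, corrected = TRUE) {
  stopifnot(length(p1) == length(p2))
  ok <- !is.na(p1) & !is.na(p2)
  if (any(p1[ok] < 0 | p1[ok] > 1 | p2[ok] < 0 | p2[ok] > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  num <- (p1 - p2)^2
  if (corrected) {
    n1 <- rep_len(n1, length(p1))
    n2 <- rep_len(n2, length(p2))
    if (any(n1[ok] < 2 | n2[ok] < 2, na.rm = TRUE)) {
      abort("bias correction requires at least 2 called alleles per population")
    }
    num <- num - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  }
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  tibble(num = num, den = den, corrected = corrected)
}

#' Ratio-of-averages F_ST over a set of variants
#'
#' Aggregates per-variant components as `sum(num) / sum(den)` — the ratio of
#' averages, not the average of per-variant ratios. Variants with undefined
#' frequencies (NA components) are dropped; variants monomorphic for the same
#' allele in both populations contribute 0/0 and therefore nothing. When the
#' summed denominator is zero (or no variant survives) the estimate is
#' `NA` with `defined = FALSE`, never an error.
#'
#' @param components Tibble from [hudson_components()] (columns `num`, `den`).
#' @param region Optional region label carried through to the output.
#' @return One-row tibble: `region`, `n_variants` (contributing variants),
#'   `sum_num`, `sum_den`, `fst`, `defined`.
#' @export
fst_region <- function(components, region = NA_character_) {
  keep <- !is.na(components$num) & !is.na(components$den)
  num <- components$num[keep]
  den <- components$den[keep]
  sn <- sum(num)
  sd <- sum(den)
  defined <- length(num) > 0 && sd > 0
  tibble(
    region = region, n_variants = length(num),
    sum_num = sn, sum_den = sd,
    fst = if (defined) sn / sd else NA_real_,
    defined = defined
  )
}

# components for a pair of populations from frequency/count matrices
pair_components <- function(fm, popA, popB, corrected) {
  for (p in c(popA, popB)) {
    if (!p %in% colnames(fm$freq)) abort(paste0("unknown population: ", p))
  }
  p1 <- fm$freq[, popA]; p2 <- fm$freq[, popB]
  n1 <- fm$called[, popA]; n2 <- fm$called[, popB]
  ok <- !is.na(p1) & !is.na(p2)
  if (corrected) ok <- ok & n1 >= 2 & n2 >= 2
  num <- den <- rep(NA_real_, length(p1))
  if (any(ok)) {
    hc <- hudson_components(p1[ok], n1[ok], p2[ok], n2[ok], corrected)
    num[ok] <- hc$num; den[ok] <- hc$den
  }
  tibble(num = num, den = den)
}

#' Per-variant Hudson F_ST between two populations
#'
#' Exposes the single-variant ratio for diagnostics and delta-DAF
#' cross-checks; the primary analysis unit remains the region.
#'
#' @param x A [genotype_matrix()].
#' @param panel Panel tibble.
#' @param popA,popB Population labels.
#' @param corrected Apply the bias correction (default `TRUE`).
#' @return Tibble: `key`, `chrom`, `pos`, `num`, `den`, `fst` (`NA` where
#'   undefined or `den = 0`).
#' @export
variant_fst <- function(x, panel, popA, popB, corrected = TRUE) {
  fm <- allele_freq_matrix(x, panel)
  comp <- pair_components(fm, popA, popB, corrected)
  tibble(
    key = variant_keys(x), chrom = x$variants$chrom, pos = x$variants$pos,
    num = comp$num, den = comp$den,
    fst = ifelse(!is.na(comp$den) & comp$den > 0, comp$num / comp$den, NA_real_)
  )
}

#' Windowed ratio-of-averages F_ST
#'
#' Windows are `[k w, (k+1) w)` in 0-based coordinates for
#' `k = 0 ... floor(L / w) - 1`; the trailing remnant shorter than `w` is
#' excluded, so variants beyond the last full window are ignored. Windows with
#' no usable variants are reported with `defined = FALSE` rather than dropped.
#'
#' @param x A [genotype_matrix()].
#' @param panel Panel tibble.
#' @param popA,popB Population labels.
#' @param window Window size in bp (> 0).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp; only
#'   chromosomes named here are scanned.
#' @param corrected Apply the bias correction (default `TRUE`; use `FALSE` for
#'   census frequencies).
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `n_variants`,
#'   `sum_num`, `sum_den`, `fst`, `defined`.
#' @export
windowed_fst <- function(x, panel, popA, popB, window, chrom_lengths,
                         corrected = TRUE) {
  if (window <= 0) abort("window must be positive")
  fm <- allele_freq_matrix(x, panel)
  comp <- pair_components(fm, popA, popB, corrected)
  pos0 <- x$variants$pos - 1L   # 0-based
  out <- lapply(names(chrom_lengths), function(chrom) {
    n_win <- floor(chrom_lengths[[chrom]] / window)
    if (n_win < 1) return(NULL)
    starts <- (seq_len(n_win) - 1) * window
    on_chrom <- x$variants$chrom == chrom & !is.na(comp$num)
    win_of <- floor(pos0 / window) + 1   # 1-based window index
    usable <- on_chrom & win_of >= 1 & win_of <= n_win
    sn <- sd <- numeric(n_win)
    nv <- integer(n_win)
    if (any(usable)) {
      idx <- win_of[usable]
      sn <- as.vector(rowsum(comp$num[usable], idx,
                             reorder = TRUE)[match(seq_len(n_win),
                                                   sort(unique(idx)))])
      sd <- as.vector(rowsum(comp$den[usable], idx,
                             reorder = TRUE)[match(seq_len(n_win),
                                                   sort(unique(idx)))])
      cnt <- table(factor(idx, levels = seq_len(n_win)))
      nv <- as.integer(cnt)
      sn[is.na(sn)] <- 0; sd[is.na(sd)] <- 0
    }
    defined <- nv > 0 & sd > 0
    tibble(chrom = chrom, start = starts, end = starts + window,
           n_variants = nv, sum_num = sn, sum_den = sd,
           fst = ifelse(defined, sn / sd, NA_real_), defined = defined)
  })
  bind_rows(out)
}

#' F_ST of structural variants
#'
#' One corrected single-variant estimate per SV allele (multi-allelic
#' copy-number records are already split into per-allele rows by
#' [read_vcf()]), plus a pooled ratio-of-averages over all SV alleles.
#'
#' @param x A [genotype_matrix()] holding structural-variant rows (vclass
#'   `SV-*`); non-SV rows are ignored with a warning.
#' @param panel Panel tibble.
#' @param popA,popB Population labels.
#' @return List with `per_allele` (tibble: `key`, `vclass`, `num`, `den`,
#'   `fst`) and `pooled` (one-row tibble as [fst_region()]).
#' @export
fst_structural <- function(x, panel, popA, popB) {
  is_sv <- grepl("^SV-", x$variants$vclass)
  if (!all(is_sv)) {
    warn(sprintf("ignoring %d non-SV rows", sum(!is_sv)))
    x <- subset_genotypes(x, variants = which(is_sv))
  }
  pv <- variant_fst(x, panel, popA, popB, corrected = TRUE)
  per_allele <- tibble(key = pv$key, vclass = x$variants$vclass,
                       num = pv$num, den = pv$den, fst = pv$fst)
  list(per_allele = per_allele,
       pooled = fst_region(pv, region = "all_structural_variants"))
}

#' Histogram of a ggplot-ready windowed F_ST distribution
#'
#' @param windows Tibble from [windowed_fst()].
#' @param binwidth Bin width on the F_ST axis (default 0.01, matching the
#'   distribution summaries used throughout the package).
#' @return A ggplot object; undefined windows are excluded (their count is
#'   shown in the subtitle).
#' @export
plot_fst_distribution <- function(windows, binwidth = 0.01) {
  def <- dplyr::filter(windows, .data$defined)
  ggplot2::ggplot(def, ggplot2::aes(x = .data$fst)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(
      x = expression(F[ST]), y = "windows",
      subtitle = sprintf("%d windows defined, %d undefined",
                         nrow(def), sum(!windows$defined))
    ) +
    ggplot2::theme_minimal()
}
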
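#' Pairwise linkage disequilibrium between two sites
#'
#' From phased haplotype indicator vectors: with `pA`, `pB` the marginal
#' derived/alt frequencies and `pAB` the joint, `D = pAB - pA pB`;
#' `D' = |D| / Dmax` where `Dmax = min(pA (1-pB), pB (1-pA))` for `D > 0`
#' and `min(pA pB, (1-pA)(1-pB))` for `D < 0`; and
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))`. Haplotypes missing at either site are
#' dropped pairwise; a site monomorphic among the retained haplotypes gives
#' a flagged-undefined result (not an error).
#'
#' @param hapA,hapB Equal-length 0/1/NA vectors (one entry per haplotype).
#' @return One-row tibble: `D`, `Dprime`, `r2`, `n_haplotypes`, `defined`.
#' @export
ld_pair <- function(hapA, hapB) {
  if (length(hapA) != length(hapB)) abort("haplotype vectors differ in length")
  keep <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[keep]; b <- hapB[keep]
  n <- length(a)
  pA <- mean(a); pB <- mean(b)
  if (n == 0 || pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(tibble(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                  n_haplotypes = n, defined = FALSE))
  }
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA)) else
    min(pA * pB, (1 - pA) * (1 - pB))
  tibble(
    D = D,
    Dprime = if (D == 0) 0 else abs(D) / Dmax,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    n_haplotypes = n, defined = TRUE
  )
}

#' Pairwise LD over a region
#'
#' Computes [ld_pair()] for every unordered pair of variants in a region,
#' pooling the haplotypes of the selected populations without reweighting
#' (combined-population LD). Refuses unphased matrices.
#'
#' @param x A phased [genotype_matrix()].
#' @param panel Panel tibble (needed when `populations` is not `"ALL"`).
#' @param populations Character vector of population labels, or `"ALL"`
#'   (default) for every haplotype.
#' @param region Optional list/tibble row with `chrom`, `start`, `end`
#'   (0-based half-open) restricting the variants; default all.
#' @return Tibble: `key1`, `pos1`, `key2`, `pos2`, `D`, `Dprime`, `r2`,
#'   `n_haplotypes`, `defined`.
#' @export
ld_matrix <- function(x, panel = NULL, populations = "ALL", region = NULL) {
  if (!x$phased) abort("LD requires phased haplotypes")
  if (!identical(populations, "ALL")) {
    if (is.null(panel)) abort("panel required to select populations")
    colpop <- pop_of_columns(x, panel)
    cols <- colpop %in% populations
    if (!any(cols)) abort("no haplotypes in the selected populations")
  } else {
    cols <- rep(TRUE, ncol(x$haplotypes))
  }
  idx <- seq_len(nrow(x$haplotypes))
  if (!is.null(region)) {
    pos0 <- x$variants$pos - 1
    idx <- which(x$variants$chrom == region$chrom &
                   pos0 >= region$start & pos0 < region$end)
  }
  if (length(idx) < 2) abort("region holds fewer than 2 variants")
  keys <- variant_keys(x)
  pairs <- utils::combn(idx, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    res <- ld_pair(x$haplotypes[i1, cols], x$haplotypes[i2, cols])
    mutate(res, key1 = keys[i1], pos1 = x$variants$pos[i1],
           key2 = keys[i2], pos2 = x$variants$pos[i2])
  })
  select(bind_rows(rows), "key1", "pos1", "key2", "pos2",
         "D", "Dprime", "r2", "n_haplotypes", "defined")
}

#' LD heatmap of a region
#'
#' @param ld Tibble from [ld_matrix()].
#' @param statistic `"r2"` (default) or `"Dprime"`.
#' @return A ggplot tile plot over variant position pairs.
#' @export
plot_ld <- function(ld, statistic = c("r2", "Dprime")) {
  statistic <- match.arg(statistic)
  ggplot2::ggplot(dplyr::filter(ld, .data$defined),
                  ggplot2::aes(x = factor(.data$pos1),
                               y = factor(.data$pos2),
                               fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "position", y = "position", fill = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
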
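#' Minor-allele-frequency filter
#'
#' Retains variants whose minor allele frequency, computed on the pooled
#' analyzed samples, is strictly greater than the threshold
#' (`min(f, 1 - f) > threshold`; a variant at exactly the threshold is
#' removed).
#'
#' @param x A [genotype_matrix()].
#' @param threshold MAF threshold (default 0.05).
#' @param samples Optional sample subset defining the analyzed set.
#' @return Filtered `genotype_matrix`.
#' @export
filter_maf <- function(x, threshold = 0.05, samples = NULL) {
  if (!is.null(samples)) x <- subset_genotypes(x, samples = samples)
  called <- rowSums(!is.na(x$haplotypes))
  alt <- rowSums(x$haplotypes, na.rm = TRUE)
  f <- ifelse(called > 0, alt / called, NA_real_)
  maf <- pmin(f, 1 - f)
  keep <- which(!is.na(maf) & maf > threshold)
  subset_genotypes(x, variants = keep)
}

#' Classify variant-feature pairs as cis or trans
#'
#' Cis iff the variant and the feature anchor share a chromosome and lie
#' within 1e6 bp of each other (inclusive boundary); different chromosomes
#' are always trans.
#'
#' @param variant_chrom,variant_pos Variant coordinates (vectorised).
#' @param feature_chrom,feature_pos Feature anchor coordinates.
#' @param cis_distance Distance threshold in bp (default `1e6`).
#' @return Character vector `"cis"`/`"trans"`.
#' @export
classify_cis_trans <- function(variant_chrom, variant_pos, feature_chrom,
                               feature_pos, cis_distance = 1e6) {
  ifelse(variant_chrom == feature_chrom &
           abs(variant_pos - feature_pos) <= cis_distance, "cis", "trans")
}

#' Single eQTL linear-model fit
#'
#' Ordinary least squares of an expression trait on allele dosage with an
#' intercept and population-indicator covariates (one column per population
#' after the first, alphabetically), reported for the dosage term. The
#' covariate absorbs population-level expression shifts so that
#' population-confounded associations are not mistaken for genotype effects.
#'
#' @param dosage Numeric vector of per-sample 0/1/2 dosages.
#' @param expression Numeric vector of per-sample expression values.
#' @param population Character/factor vector of population labels (optional;
#'   omit for a single-population fit).
#' @return One-row tibble `beta`, `tstat`, `p`, `df`; `NA`s (skipped) when
#'   the dosage is collinear with the covariates.
#' @export
fit_eqtl <- function(dosage, expression, population = NULL) {
  n <- length(dosage)
  Z <- matrix(1, n, 1)
  if (!is.null(population) && length(unique(population)) > 1) {
    pops <- sort(unique(as.character(population)))
    for (p in pops[-1]) Z <- cbind(Z, as.numeric(population == p))
  }
  k <- ncol(Z) + 1L  # parameters incl. dosage
  if (n < k + 3L) abort("need at least 3 more samples than model parameters")
  qz <- qr(Z)
  xr <- qr.resid(qz, dosage)
  yr <- qr.resid(qz, expression)
  sxx <- sum(xr^2)
  if (sxx < 1e-12) {
    return(tibble(beta = NA_real_, tstat = NA_real_, p = NA_real_,
                  df = n - k))
  }
  beta <- sum(xr * yr) / sxx
  df <- n - k
  rss <- sum(yr^2) - beta^2 * sxx
  sigma2 <- rss / df
  tstat <- beta / sqrt(sigma2 / sxx)
  tibble(beta = beta, tstat = tstat, p = 2 * pt(-abs(tstat), df), df = df)
}

#' Combined-population cis/trans eQTL scan
#'
#' Fits the covariate-adjusted linear model of [fit_eqtl()] for every
#' variant-feature pair, classifies each pair cis or trans by the distance
#' rule, discards records past the per-family p-value cut-offs (cis 0.05,
#' trans 0.01), and applies Benjamini-Hochberg separately within the retained
#' cis family and trans family (m = retained tests of that family).
#' The whole scan is vectorised: expression and dosage are residualised
#' against the covariate design once, after which every pair is a simple
#' regression.
#'
#' @param x A [genotype_matrix()] (typically already MAF-filtered).
#' @param expression Numeric matrix features x samples (column names =
#'   sample ids, which must all be samples of `x`).
#' @param anchors Tibble with `feature_id`, `chrom`, `pos` — one anchor
#'   coordinate per expression row (feature start is the conventional
#'   choice).
#' @param panel Panel tibble; `NULL` for a single-population scan.
#' @param cis_p,trans_p Pre-FDR p-value cut-offs (defaults 0.05 / 0.01).
#' @param fdr Significance level on the BH-adjusted values (default 0.05).
#' @param cis_distance Cis window in bp (default `1e6`).
#' @return Object of class `eqtl_scan`: list with `records` (tibble
#'   `variant`, `chrom`, `pos`, `feature`, `kind`, `beta`, `tstat`, `p`,
#'   `fdr`, `significant`), `n_tests` (tibble of per-family test counts),
#'   `n_skipped` (collinear pairs), and the thresholds used.
#' @export
eqtl_scan <- function(x, expression, anchors, panel = NULL, cis_p = 0.05,
                      trans_p = 0.01, fdr = 0.05, cis_distance = 1e6) {
  expression <- as.matrix(expression)
  if (is.null(colnames(expression))) {
    abort("expression needs sample ids as column names")
  }
  if (!all(colnames(expression) %in% x$sample_ids)) {
    abort("expression contains samples absent from the genotype matrix")
  }
  if (nrow(expression) != nrow(anchors)) {
    abort("anchors must have one row per expression feature")
  }
  x <- subset_genotypes(x, samples = colnames(expression))
  complete <- rowSums(is.na(x$haplotypes)) == 0
  if (!all(complete)) {
    warn(sprintf("dropping %d variant(s) with missing genotypes from the scan",
                 sum(!complete)))
    x <- subset_genotypes(x, variants = which(complete))
  }
  dos <- dosage_matrix(x)
  n <- ncol(dos)

  Z <- matrix(1, n, 1)
  if (!is.null(panel)) {
    pop <- panel$population[match(colnames(dos), panel$sample)]
    if (anyNA(pop)) abort("panel does not cover all expression samples")
    pops <- sort(unique(pop))
    for (p in pops[-1]) Z <- cbind(Z, as.numeric(pop == p))
  }
  k <- ncol(Z) + 1L
  if (n < k + 3L) abort("need at least 3 more samples than model parameters")
  df <- n - k
  qz <- qr(Z)
  # residualise both blocks once (Frisch-Waugh): every pair is then a
  # simple regression with df = n - k
  Xr <- t(qr.resid(qz, t(dos)))
  Yr <- t(qr.resid(qz, t(expression)))
  sxx <- rowSums(Xr^2)
  syy <- rowSums(Yr^2)
  cross <- Xr %*% t(Yr)                       # variants x features
  ok_var <- sxx > 1e-12
  beta <- cross / sxx
  rss <- outer(rep(1, nrow(dos)), syy) - beta * cross
  rss[rss < 0] <- 0
  tstat <- beta / sqrt(rss / df / sxx)
  p <- 2 * pt(-abs(tstat), df)

  kind <- outer(seq_len(nrow(dos)), seq_len(nrow(expression)),
                function(i, j) classify_cis_trans(
                  x$variants$chrom[i], x$variants$pos[i],
                  anchors$chrom[j], anchors$pos[j], cis_distance))
  records <- tibble(
    variant = rep(variant_keys(x), times = nrow(expression)),
    chrom = rep(x$variants$chrom, times = nrow(expression)),
    pos = rep(x$variants$pos, times = nrow(expression)),
    feature = rep(anchors$feature_id, each = nrow(dos)),
    kind = as.vector(kind),
    beta = as.vector(beta), tstat = as.vector(tstat), p = as.vector(p),
    skipped = rep(!ok_var, times = nrow(expression))
  )
  n_skipped <- sum(records$skipped)
  records <- dplyr::filter(records, !.data$skipped) %>% select(-"skipped")
  n_tests <- records %>% group_by(.data$kind) %>%
    summarise(n_total = dplyr::n(), .groups = "drop")

  records <- threshold_and_fdr(records, cis_p = cis_p, trans_p = trans_p,
                               fdr = fdr)
  structure(
    list(records = records, n_tests = n_tests, n_skipped = n_skipped,
         thresholds = list(cis_p = cis_p, trans_p = trans_p, fdr = fdr,
                           cis_distance = cis_distance)),
    class = "eqtl_scan"
  )
}

#' Per-family p-value cut-offs and Benjamini-Hochberg adjustment
#'
#' Cis records with `p >= cis_p` and trans records with `p >= trans_p` are
#' discarded; BH is applied separately to the cis and the trans family. By
#' default m is the family's total test count — the convention of the
#' standard eQTL scan packages, whose outputs store only sub-cutoff records
#' but adjust against every test performed. `m = "retained"` (adjusting only
#' over the stored records) is exposed as an alternative; it is markedly
#' anticonservative and intended for diagnostics only. Significance is
#' `fdr < 0.05` (or the supplied level).
#'
#' @param records Tibble with at least `kind` and `p`, holding every test of
#'   each family (the discard happens here).
#' @param cis_p,trans_p,fdr Thresholds as in [eqtl_scan()].
#' @param m `"family_total"` (default) or `"retained"`.
#' @return `records` filtered, with added `fdr` and `significant` columns.
#' @export
threshold_and_fdr <- function(records, cis_p = 0.05, trans_p = 0.01,
                              fdr = 0.05, m = c("family_total", "retained")) {
  m <- match.arg(m)
  totals <- table(factor(records$kind[!is.na(records$p)],
                         levels = c("cis", "trans")))
  cutoff <- ifelse(records$kind == "cis", cis_p, trans_p)
  records <- records[!is.na(records$p) & records$p < cutoff, , drop = FALSE]
  records$fdr <- NA_real_
  for (fam in c("cis", "trans")) {
    sel <- records$kind == fam
    if (any(sel)) {
      n_adj <- if (m == "family_total") totals[[fam]] else sum(sel)
      records$fdr[sel] <- p.adjust(records$p[sel], method = "BH", n = n_adj)
    }
  }
  records$significant <- records$fdr < fdr
  as_tibble(records)
}

#' eQTL hotspot table
#'
#' Counts, per variant, the expression features it regulates at FDR < 0.05,
#' split by cis/trans, sorted by descending trans count — the table in which
#' a trans-regulation hub (one cis-regulated driver controlling many distant
#' features) surfaces at the top.
#'
#' @param scan An `eqtl_scan` object or its `records` tibble.
#' @return Tibble: `variant`, `n_cis`, `n_trans`, sorted by `n_trans`
#'   descending.
#' @export
hotspot_counts <- function(scan) {
  records <- if (inherits(scan, "eqtl_scan")) scan$records else scan
  sig <- dplyr::filter(records, .data$significant)
  if (nrow(sig) == 0) {
    return(tibble(variant = character(0), n_cis = integer(0),
                  n_trans = integer(0)))
  }
  sig %>%
    group_by(.data$variant) %>%
    summarise(n_cis = sum(.data$kind == "cis"),
              n_trans = sum(.data$kind == "trans"), .groups = "drop") %>%
    arrange(desc(.data$n_trans), desc(.data$n_cis), .data$variant)
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("<eqtl_scan> %d retained records (%d significant at FDR < %g); %d collinear pairs skipped\n",
              nrow(x$records), sum(x$records$significant),
              x$thresholds$fdr, x$n_skipped))
  invisible(x)
}

#' Tidy an eQTL scan
#'
#' @param x An `eqtl_scan` object.
#' @param ... Unused.
#' @return The records tibble (one row per retained variant-feature test).
#' @export
tidy.eqtl_scan <- function(x, ...) x$records

#' One-row summary of an eQTL scan
#'
#' @param x An `eqtl_scan` object.
#' @param ... Unused.
#' @return Tibble: total tests per family, retained and significant counts,
#'   skipped pairs.
#' @export
glance.eqtl_scan <- function(x, ...) {
  get_n <- function(fam) {
    v <- x$n_tests$n_total[x$n_tests$kind == fam]
    if (length(v) == 0) 0L else v
  }
  tibble(
    n_tests_cis = get_n("cis"), n_tests_trans = get_n("trans"),
    n_retained_cis = sum(x$records$kind == "cis"),
    n_retained_trans = sum(x$records$kind == "trans"),
    n_significant_cis = sum(x$records$significant & x$records$kind == "cis"),
    n_significant_trans = sum(x$records$significant &
                                x$records$kind == "trans"),
    n_skipped = x$n_skipped
  )
}

#' Transcription-ratio features
#'
#' Converts sibling features of one gene (e.g. transcript-level expression)
#' into per-sample ratios feature / sum(siblings); samples whose sibling sum
#' is zero get `NA` for that gene's ratios and are dropped pairwise by the
#' scan.
#'
#' @param expression Features x samples matrix.
#' @param gene_of Character vector assigning each feature row to a gene.
#' @return Matrix of the same shape holding ratios.
#' @export
transcription_ratios <- function(expression, gene_of) {
  expression <- as.matrix(expression)
  out <- expression
  for (g in unique(gene_of)) {
    rows <- which(gene_of == g)
    tot <- colSums(expression[rows, , drop = FALSE])
    denom <- ifelse(tot == 0, NA_real_, tot)
    out[rows, ] <- sweep(expression[rows, , drop = FALSE], 2, denom, "/")
  }
  out
}
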
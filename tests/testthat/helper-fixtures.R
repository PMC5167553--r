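# Small in-code fixtures shared across the suite.

# genotype_matrix from a plain 0/1/NA matrix (variants x haplotypes)
make_gm <- function(hap, pos = NULL, chrom = "chr1", ref = "A", alt = "T",
                    ancestral = "UNKNOWN", vclass = "SNV") {
  hap <- as.matrix(hap)
  n <- nrow(hap)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  genotype_matrix(
    tibble::tibble(
      chrom = rep_len(chrom, n), pos = as.integer(pos),
      ref = rep_len(ref, n), alt = rep_len(alt, n),
      vclass = rep_len(vclass, n),
      source_id = sprintf("v%03d", seq_len(n)),
      ancestral = rep_len(ancestral, n)
    ),
    hap,
    sample_ids = sprintf("S%02d", seq_len(ncol(hap) / 2))
  )
}

make_panel <- function(samples, pops) {
  tibble::tibble(sample = samples, population = pops)
}

write_vcf_lines <- function(records, samples) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

# brute-force Hudson ratio-of-averages from allele count tables
brute_fst <- function(alt1, n1, alt2, n2, corrected = TRUE) {
  num_tot <- 0
  den_tot <- 0
  for (i in seq_along(alt1)) {
    p1 <- alt1[i] / n1[i]
    p2 <- alt2[i] / n2[i]
    num <- (p1 - p2)^2
    if (corrected) {
      num <- num - p1 * (1 - p1) / (n1[i] - 1) - p2 * (1 - p2) / (n2[i] - 1)
    }
    num_tot <- num_tot + num
    den_tot <- den_tot + (p1 * (1 - p2) + p2 * (1 - p1))
  }
  unname(num_tot / den_tot)
}

# brute-force LD from the 2x2 haplotype class counts
brute_ld <- function(hapA, hapB) {
  keep <- !is.na(hapA) & !is.na(hapB)
  a <- hapA[keep]; b <- hapB[keep]
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA)) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = if (D == 0) 0 else abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# brute-force Benjamini-Hochberg: largest k with p_(k) <= k alpha / m decides
brute_bh_significant <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ks <- which(p[ord] <= seq_len(m) * alpha / m)
  if (length(ks) == 0) return(rep(FALSE, m))
  kstar <- max(ks)
  sig <- rep(FALSE, m)
  sig[ord[seq_len(kstar)]] <- TRUE
  sig
}

test_generator_config <- function(seed, ...) {
  defaults <- list(
    samples_per_pop = c(AFR = 40L, EAS = 40L, EUR = 40L),
    n_variants = 400, chrom_length = 5e5, n_genes = 15,
    hub_n_targets = 5, n_cis_effects = 3, seed = seed
  )
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}
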
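#' Phased genotype container
#'
#' A `genotype_matrix` holds a variants-by-haplotypes indicator matrix derived
#' from phased genotypes, together with per-variant metadata. Every row is one
#' (record, ALT allele) pair: multi-allelic VCF records are split upstream into
#' one row per alternate allele, so entries are 0/1 (`NA` for missing calls).
#' Each sample contributes two adjacent haplotype columns.
#'
#' @param variants A tibble with columns `chrom`, `pos` (1-based, as in VCF),
#'   `ref`, `alt` (a single allele), `vclass` (one of `"SNV"`, `"INDEL"`,
#'   `"SV-DEL"`, `"SV-DUP"`, `"SV-INV"`, `"SV-INS"`), `source_id` and
#'   `ancestral` (an allele string, `"UNKNOWN"` or `"OTHER"`).
#' @param haplotypes Integer matrix of 0/1/`NA`, one row per variant and two
#'   columns per sample.
#' @param sample_ids Character vector of sample labels, half the number of
#'   haplotype columns.
#' @param phased Logical; genotypes were phased (`FALSE` only when a reader is
#'   told to tolerate unphased input, in which case LD refuses the matrix).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, haplotypes, sample_ids, phased = TRUE) {
  variants <- as_tibble(variants)
  needed <- c("chrom", "pos", "ref", "alt", "vclass", "source_id", "ancestral")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variants is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != nrow(variants)) {
    abort("haplotypes must have one row per variant")
  }
  if (ncol(haplotypes) != 2L * length(sample_ids)) {
    abort("haplotypes must have two columns per sample")
  }
  bad <- haplotypes[!is.na(haplotypes)]
  if (length(bad) > 0 && !all(bad %in% c(0L, 1L))) {
    abort("haplotype entries must be 0, 1 or NA")
  }
  if (any(variants$pos < 1L)) abort("VCF positions are 1-based; pos must be >= 1")
  structure(
    list(variants = variants, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids), phased = isTRUE(phased)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d haplotypes (%d samples, %s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$sample_ids),
              if (x$phased) "phased" else "unphased"))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$haplotypes)

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Variant keys of a genotype matrix
#'
#' Keys are `chrom:pos:ref:alt`, the uniqueness tuple for rows after
#' multi-allelic splitting.
#'
#' @param x A [genotype_matrix()].
#' @return Character vector, one key per variant row.
#' @export
variant_keys <- function(x) variant_key(x$variants)

infer_vclass <- function(ref, alt) {
  dplyr::case_when(
    grepl("^<DEL", alt) ~ "SV-DEL",
    grepl("^<DUP|^<CN", alt) ~ "SV-DUP",
    grepl("^<INV", alt) ~ "SV-INV",
    grepl("^<INS", alt) ~ "SV-INS",
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    TRUE ~ "INDEL"
  )
}

#' Read phased genotypes from a VCF file
#'
#' Each VCF record is split into one matrix row per ALT allele: the row for
#' allele k carries 1 exactly where a haplotype holds allele k (other ALT
#' alleles of the same record count as 0), and `NA` where the genotype is
#' missing. Rows are ordered by (chrom, pos, alt).
#'
#' @param path Path to a VCF 4.x file with GT fields.
#' @param samples Optional character vector restricting the sample set; an
#'   unknown sample name is an error.
#' @param allow_unphased If `FALSE` (default) any unphased genotype separator
#'   (`/`) aborts; if `TRUE` the matrix is marked unphased and LD functions
#'   will refuse it.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, samples = NULL, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) abort("VCF has no genotype columns")
  all_samples <- colnames(gt)[-1L]
  if (!is.null(samples)) {
    unknown <- setdiff(samples, all_samples)
    if (length(unknown) > 0) {
      abort(paste0("sample(s) not in VCF: ", paste(unknown, collapse = ", ")))
    }
    keep <- samples
  } else {
    keep <- all_samples
  }
  # GT is the first colon-delimited field per VCF spec
  gt_raw <- gt[, keep, drop = FALSE]
  gt_only <- sub(":.*$", "", gt_raw)
  if (any(grepl("/", gt_only, fixed = TRUE))) {
    if (!allow_unphased) {
      abort("unphased genotypes found; set allow_unphased = TRUE to accept (LD will refuse the matrix)")
    }
    phased <- FALSE
    gt_only <- gsub("/", "|", gt_only, fixed = TRUE)
  } else {
    phased <- TRUE
  }
  n_rec <- nrow(fix)
  alleles1 <- sub("\\|.*$", "", gt_only)
  alleles2 <- sub("^.*\\|", "", gt_only)
  to_int <- function(a) {
    a[a == "."] <- NA_character_
    suppressWarnings(matrix(as.integer(a), nrow = n_rec))
  }
  a1 <- to_int(alleles1)
  a2 <- to_int(alleles2)
  # interleave: sample s -> columns 2s-1, 2s
  n_smp <- length(keep)
  hap_alleles <- matrix(NA_integer_, nrow = n_rec, ncol = 2L * n_smp)
  hap_alleles[, seq(1L, 2L * n_smp, by = 2L)] <- a1
  hap_alleles[, seq(2L, 2L * n_smp, by = 2L)] <- a2

  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    hv <- hap_alleles[i, ]
    mat <- matrix(NA_integer_, nrow = length(alts), ncol = length(hv))
    for (k in seq_along(alts)) {
      mat[k, ] <- ifelse(is.na(hv), NA_integer_, as.integer(hv == k))
    }
    rows[[i]] <- list(
      variants = tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts,
        vclass = infer_vclass(fix[i, "REF"], alts),
        source_id = if (is.na(fix[i, "ID"])) "." else fix[i, "ID"],
        ancestral = "UNKNOWN"
      ),
      hap = mat
    )
  }
  variants <- bind_rows(lapply(rows, `[[`, "variants"))
  haps <- do.call(rbind, lapply(rows, `[[`, "hap"))
  ord <- order(variants$chrom, variants$pos, variants$alt)
  genotype_matrix(variants[ord, ], haps[ord, , drop = FALSE], keep, phased)
}

#' Write a genotype matrix to a plain-text VCF
#'
#' Emits one biallelic record per variant row (multi-allelic records are not
#' re-merged), with phased GT fields. Round-trips through [read_vcf()] for
#' biallelic matrices.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t")
  )
  h <- x$haplotypes
  gstr <- matrix(ifelse(is.na(h), ".", as.character(h)), nrow = nrow(h))
  odd <- seq(1L, ncol(h), by = 2L)
  gt <- matrix("", nrow = nrow(h), ncol = length(odd))
  for (j in seq_along(odd)) {
    gt[, j] <- paste0(gstr[, odd[j]], "|", gstr[, odd[j] + 1L])
  }
  body <- vapply(seq_len(nrow(h)), function(i) {
    paste(c(x$variants$chrom[i], x$variants$pos[i], x$variants$source_id[i],
            x$variants$ref[i], x$variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' @param path TSV with header columns `sample` and `population`.
#' @return A tibble with columns `sample`, `population`.
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("sample", "population") %in% names(panel))) {
    abort("panel file needs columns 'sample' and 'population'")
  }
  dup <- panel$sample[duplicated(panel$sample)]
  if (length(dup) > 0) {
    abort(paste0("duplicated sample id(s) in panel: ",
                 paste(unique(dup), collapse = ", ")))
  }
  as_tibble(panel[, c("sample", "population")])
}

#' Read an ancestral-allele table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#'   `ancestral`. The ancestral column holds an allele string, `UNKNOWN`
#'   (no concordant call) or `OTHER` (concordant call matching neither allele).
#' @return Tibble keyed by `chrom:pos:ref:alt` (column `key`) with column
#'   `ancestral`.
#' @export
read_ancestral <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", ancestral = "c"
  ), progress = FALSE)
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(paste0("duplicated variant key(s) in ancestral table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble(key = key, ancestral = tab$ancestral)
}

#' Attach ancestral-allele calls to a genotype matrix
#'
#' Variants absent from the table keep `UNKNOWN`; calls that match neither
#' ref nor alt are stored as `OTHER` at polarisation time.
#'
#' @param x A [genotype_matrix()].
#' @param ancestral Tibble from [read_ancestral()].
#' @return The updated `genotype_matrix`.
#' @export
set_ancestral <- function(x, ancestral) {
  idx <- match(variant_keys(x), ancestral$key)
  anc <- ancestral$ancestral[idx]
  anc[is.na(anc)] <- "UNKNOWN"
  x$variants$ancestral <- anc
  x
}

pop_of_columns <- function(x, panel) {
  pop <- panel$population[match(x$sample_ids, panel$sample)]
  if (anyNA(pop)) {
    abort(paste0("sample(s) missing from panel: ",
                 paste(x$sample_ids[is.na(pop)], collapse = ", ")))
  }
  rep(pop, each = 2L)
}

#' Per-population allele counts and frequencies
#'
#' Missing haplotypes reduce the called-allele denominator rather than being
#' imputed; a population with zero called alleles at a variant reports
#' `alt_freq = NA` (flagged undefined, not an error).
#'
#' @param x A [genotype_matrix()].
#' @param panel Panel tibble ([read_panel()]) covering all samples of `x`.
#' @param variants Optional integer vector of variant row indices (default all).
#' @return Tibble with one row per variant x population: `key`, `variant_index`,
#'   `population`, `alt_count`, `called_alleles`, `alt_freq`.
#' @export
allele_counts <- function(x, panel, variants = NULL) {
  if (is.null(variants)) variants <- seq_len(nrow(x$haplotypes))
  stopifnot(all(variants >= 1L & variants <= nrow(x$haplotypes)))
  colpop <- pop_of_columns(x, panel)
  pops <- sort(unique(colpop))
  h <- x$haplotypes[variants, , drop = FALSE]
  out <- lapply(pops, function(p) {
    hp <- h[, colpop == p, drop = FALSE]
    called <- rowSums(!is.na(hp))
    alt <- rowSums(hp, na.rm = TRUE)
    tibble(
      key = variant_key(x$variants[variants, ]),
      variant_index = variants,
      population = p,
      alt_count = as.integer(alt),
      called_alleles = as.integer(called),
      alt_freq = ifelse(called > 0, alt / called, NA_real_)
    )
  })
  arrange(bind_rows(out), .data$variant_index, .data$population)
}

#' Per-population alternate-allele frequency matrix
#'
#' Convenience wide form of [allele_counts()]: frequencies and called-allele
#' counts as variants-by-populations matrices.
#'
#' @inheritParams allele_counts
#' @return List with matrices `freq` and `called` (rownames = variant keys).
#' @export
allele_freq_matrix <- function(x, panel) {
  colpop <- pop_of_columns(x, panel)
  pops <- sort(unique(colpop))
  freq <- called <- matrix(NA_real_, nrow = nrow(x$haplotypes),
                           ncol = length(pops),
                           dimnames = list(variant_keys(x), pops))
  for (p in pops) {
    hp <- x$haplotypes[, colpop == p, drop = FALSE]
    n <- rowSums(!is.na(hp))
    a <- rowSums(hp, na.rm = TRUE)
    called[, p] <- n
    freq[, p] <- ifelse(n > 0, a / n, NA_real_)
  }
  list(freq = freq, called = called)
}

#' Polarise alternate-allele frequencies into derived-allele frequencies
#'
#' A variant whose ancestral allele equals ref has DAF = alt frequency; equal
#' to alt, DAF = 1 - alt frequency. `UNKNOWN`/`OTHER` ancestral states mark
#' the variant `excluded` — such variants take no part in any DAF analysis
#' (exclusion is a value, not an error).
#'
#' @param x A [genotype_matrix()] with ancestral states set.
#' @param panel Panel tibble.
#' @return Tibble: `key`, `variant_index`, `chrom`, `pos`, `alt`, `excluded`,
#'   then one `daf_<population>` column per population (`NA` where the
#'   population had no called alleles or the variant is excluded).
#' @export
polarize <- function(x, panel) {
  fm <- allele_freq_matrix(x, panel)
  anc <- x$variants$ancestral
  status <- dplyr::case_when(
    anc == x$variants$ref ~ "ref",
    anc == x$variants$alt ~ "alt",
    TRUE ~ "excluded"
  )
  out <- tibble(
    key = variant_keys(x),
    variant_index = seq_len(nrow(x$haplotypes)),
    chrom = x$variants$chrom, pos = x$variants$pos, alt = x$variants$alt,
    excluded = status == "excluded"
  )
  for (p in colnames(fm$freq)) {
    daf <- ifelse(status == "ref", fm$freq[, p],
                  ifelse(status == "alt", 1 - fm$freq[, p], NA_real_))
    out[[paste0("daf_", p)]] <- unname(daf)
  }
  out
}

#' Per-sample dosage matrix
#'
#' Sums the two haplotype columns of each sample; a sample with any missing
#' haplotype at a variant gets `NA` there.
#'
#' @param x A [genotype_matrix()].
#' @return Integer matrix variants x samples of 0/1/2 dosages.
#' @export
dosage_matrix <- function(x) {
  odd <- seq(1L, ncol(x$haplotypes), by = 2L)
  d <- x$haplotypes[, odd, drop = FALSE] + x$haplotypes[, odd + 1L, drop = FALSE]
  colnames(d) <- x$sample_ids
  rownames(d) <- variant_keys(x)
  d
}

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param variants Integer or logical index over variant rows (optional).
#' @param samples Character vector of sample ids to retain (optional).
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(x, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(nrow(x$haplotypes))
  keep_samples <- if (is.null(samples)) x$sample_ids else {
    unknown <- setdiff(samples, x$sample_ids)
    if (length(unknown) > 0) {
      abort(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
    }
    samples
  }
  smp_idx <- match(keep_samples, x$sample_ids)
  cols <- as.vector(rbind(2L * smp_idx - 1L, 2L * smp_idx))
  genotype_matrix(x$variants[variants, , drop = FALSE],
                  x$haplotypes[variants, cols, drop = FALSE],
                  keep_samples, x$phased)
}
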
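#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the shape of the study inputs: three populations (an
#' African-ancestry panel of 504 samples, an East-Asian panel of 504 and a
#' European panel of 503), phased biallelic variants on one chromosome with
#' block LD, a small fraction of sweep-like variants whose derived allele is
#' near-fixed in the two out-of-Africa panels and rare in the third, gene
#' models exercising all nine annotation priority classes, repeats, ancestral
#' calls with an error rate, and expression with planted cis effects plus one
#' trans-regulation hub (a cis-regulated driver feature controlling many
#' distant features). Tests typically shrink `samples_per_pop`, `n_variants`
#' and `n_genes`; the statistical structure is unchanged.
#'
#' @param n_pops Number of populations (2 or 3).
#' @param samples_per_pop Named integer vector of per-population sample
#'   counts.
#' @param n_variants Number of biallelic variants.
#' @param chrom_length Chromosome length in bp.
#' @param drift Named per-population Balding-Nichols drift parameter in
#'   (0, 1); 0 collapses every population onto the ancestral frequency.
#' @param sweep_fraction Fraction of variants given a sweep-like profile.
#' @param sweep_daf_range Range the swept populations' DAF is drawn from.
#' @param sweep_high_pops Populations in which swept derived alleles are
#'   near-fixed (the remaining populations keep them rare).
#' @param ld_block_length LD block length in bp (haplotype latent state is
#'   refreshed at block boundaries).
#' @param ld_switch_rate Per-variant probability of refreshing the latent
#'   state inside a block (higher = weaker LD).
#' @param n_genes Gene count; the first two genes overlap to exercise
#'   priority resolution, and roughly a third are noncoding.
#' @param repeat_density Expected fraction of the chromosome covered by
#'   repeats.
#' @param n_cis_effects Number of planted cis eQTL effects.
#' @param cis_beta Per-allele expression shift of planted cis effects.
#' @param hub_n_targets Distant features controlled by the trans hub (0
#'   disables the hub).
#' @param hub_attenuation Multiplier from regulator expression to target
#'   expression.
#' @param pop_shift_sd SD of per-feature population-level expression
#'   offsets.
#' @param noise_sd SD of the Gaussian expression noise.
#' @param ancestral_mislabel_rate Probability an ancestral call records the
#'   wrong allele.
#' @param ancestral_unknown_rate Probability an ancestral call is missing
#'   (`UNKNOWN`; excluded from DAF analyses).
#' @param seed Integer seed (mandatory).
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_pops = 3,
    samples_per_pop = c(AFR = 504L, EAS = 504L, EUR = 503L),
    n_variants = 2000,
    chrom_length = 2e6,
    drift = c(AFR = 0.08, EAS = 0.14, EUR = 0.12),
    sweep_fraction = 0.02,
    sweep_daf_range = c(0.9, 1.0),
    sweep_high_pops = c("EAS", "EUR"),
    ld_block_length = 2e4,
    ld_switch_rate = 0.1,
    n_genes = 40,
    repeat_density = 0.2,
    n_cis_effects = 5,
    cis_beta = 1,
    hub_n_targets = 20,
    hub_attenuation = 0.8,
    pop_shift_sd = 0.5,
    noise_sd = 0.5,
    ancestral_mislabel_rate = 0.02,
    ancestral_unknown_rate = 0.05,
    seed) {
  if (missing(seed)) abort("seed is required")
  samples_per_pop <- samples_per_pop[seq_len(n_pops)]
  drift <- drift[names(samples_per_pop)]
  stopifnot(all(drift >= 0 & drift < 1),
            sweep_fraction >= 0 && sweep_fraction <= 1,
            repeat_density >= 0 && repeat_density <= 1,
            ancestral_mislabel_rate >= 0 && ancestral_mislabel_rate <= 1)
  structure(as.list(environment()), class = "generator_config")
}

bn_freq <- function(p0, F) {
  if (F == 0) return(p0)
  a <- p0 * (1 - F) / F
  b <- (1 - p0) * (1 - F) / F
  rbeta(length(p0), a, b)
}

#' Generate phased genotypes, panel and ancestral table
#'
#' Ancestral (derived-allele) frequencies are drawn from a density
#' concentrated near zero; per-population frequencies drift around them
#' (Balding-Nichols beta draws with the configured per-population parameter);
#' a `sweep_fraction` of variants instead gets a high derived frequency in
#' the `sweep_high_pops` and a low one elsewhere. Haplotypes are sampled with
#' block LD: each haplotype carries a latent uniform state refreshed at block
#' boundaries (and with probability `ld_switch_rate` per variant inside a
#' block), and carries the derived allele wherever the state falls below the
#' population frequency — marginals stay exact while neighbouring variants
#' are correlated. The recorded ancestral call is wrong with probability
#' `ancestral_mislabel_rate` and missing with `ancestral_unknown_rate`.
#'
#' @param config A [generator_config()].
#' @return List: `genotypes` ([genotype_matrix()]), `panel`, `ancestral`
#'   (tibble as [read_ancestral()]), `truth` (tibble: `key`, `is_sweep`,
#'   true per-population DAF columns).
#' @export
generate_genotypes <- function(config) {
  set.seed(config$seed)
  cf <- config
  pops <- names(cf$samples_per_pop)
  n <- cf$n_variants
  pos <- sort(sample.int(cf$chrom_length - 1L, n)) + 1L  # 1-based, unique
  p0 <- rbeta(n, 0.3, 1.2)  # derived-allele frequency, mass near zero

  daf <- sapply(pops, function(p) bn_freq(p0, cf$drift[[p]]))
  n_sweep <- round(cf$sweep_fraction * n)
  sweep_idx <- if (n_sweep > 0) sample.int(n, n_sweep) else integer(0)
  for (p in pops) {
    if (p %in% cf$sweep_high_pops) {
      daf[sweep_idx, p] <- runif(n_sweep, cf$sweep_daf_range[1],
                                 cf$sweep_daf_range[2])
    } else {
      daf[sweep_idx, p] <- runif(n_sweep, 0, 0.05)
    }
  }

  # orientation: for most variants the reference allele is ancestral
  alt_is_derived <- runif(n) < 0.8
  alt_freq <- daf
  alt_freq[!alt_is_derived, ] <- 1 - daf[!alt_is_derived, , drop = FALSE]

  n_haps <- 2L * cf$samples_per_pop
  blocks <- floor(pos / cf$ld_block_length)
  hap_cols <- vector("list", length(pops))
  names(hap_cols) <- pops
  for (p in pops) {
    H <- matrix(0L, nrow = n, ncol = n_haps[[p]])
    for (h in seq_len(n_haps[[p]])) {
      refresh <- c(TRUE, diff(blocks) != 0 |
                     runif(n - 1) < cf$ld_switch_rate)
      draws <- runif(n)
      z <- draws[cummax(seq_len(n) * refresh)]  # carry latent state forward
      H[, h] <- as.integer(z < alt_freq[, p])
    }
    hap_cols[[p]] <- H
  }
  haplotypes <- do.call(cbind, hap_cols)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s%04d", p, seq_len(cf$samples_per_pop[[p]]))))
  panel <- tibble(sample = sample_ids,
                  population = rep(pops, cf$samples_per_pop))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  true_anc <- ifelse(alt_is_derived, ref, alt)
  recorded <- true_anc
  flip <- runif(n) < cf$ancestral_mislabel_rate
  recorded[flip] <- ifelse(true_anc[flip] == ref[flip], alt[flip], ref[flip])
  recorded[runif(n) < cf$ancestral_unknown_rate] <- "UNKNOWN"

  variants <- tibble(
    chrom = "chr1", pos = pos, ref = unname(ref), alt = unname(alt),
    vclass = "SNV", source_id = sprintf("var%05d", seq_len(n)),
    ancestral = recorded
  )
  gm <- genotype_matrix(variants, haplotypes, sample_ids)
  truth <- tibble(key = variant_keys(gm),
                  is_sweep = seq_len(n) %in% sweep_idx)
  for (p in pops) truth[[paste0("daf_", p)]] <- daf[, p]
  ancestral <- tibble(key = variant_keys(gm), ancestral = recorded)
  list(genotypes = gm, panel = panel, ancestral = ancestral, truth = truth)
}

#' Generate gene models and a repeat track
#'
#' Lays out coding and noncoding genes along the chromosome (the first two
#' genes overlap, so priority resolution is always exercised), builds
#' per-gene component intervals (UTR5/CDS/intron/UTR3 for coding genes,
#' NONCODING exons and introns otherwise) and scatters repeat intervals to
#' the configured density, some of which straddle window boundaries.
#'
#' @param config A [generator_config()].
#' @return List: `genes`, `components` (tibbles as [partition_genome()]
#'   expects), `repeats` (BED-style tibble).
#' @export
generate_annotations <- function(config) {
  set.seed(config$seed + 1L)
  cf <- config
  L <- cf$chrom_length
  n_genes <- cf$n_genes
  gene_len <- round(runif(n_genes, 3000, 20000))
  gap <- round(runif(n_genes, 2000, max(3000, (L - sum(gene_len)) * 2 / n_genes)))
  start <- cumsum(gap) + cumsum(dplyr::lag(gene_len, default = 0))
  if (n_genes >= 2) start[2] <- start[1] + round(gene_len[1] / 2)  # overlap
  end <- start + gene_len
  keep <- end < L - 5000
  start <- start[keep]; end <- end[keep]; gene_len <- gene_len[keep]
  n_genes <- length(start)
  coding <- rep(TRUE, n_genes)
  coding[seq_len(n_genes) %% 3 == 0] <- FALSE

  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(n_genes)), chrom = "chr1",
    start = start, end = end,
    strand = sample(c("+", "-"), n_genes, replace = TRUE), coding = coding
  )
  comp_rows <- lapply(seq_len(n_genes), function(i) {
    s <- start[i]; e <- end[i]
    if (coding[i]) {
      u5 <- round(runif(1, 100, 500)); u3 <- round(runif(1, 100, 500))
      inner <- e - u3 - (s + u5)
      n_ex <- max(1L, min(3L, floor(inner / 2000)))
      cuts <- round(seq(s + u5, e - u3, length.out = 2 * n_ex))
      cls <- rep(c("CDS", "INTRON"), length.out = 2 * n_ex - 1)
      tibble(
        gene_id = genes$gene_id[i], chrom = "chr1",
        class = c("UTR5", cls, "UTR3"),
        start = c(s, cuts[-length(cuts)], e - u3),
        end = c(s + u5, cuts[-1], e)
      )
    } else {
      mid <- round((s + e) / 2)
      tibble(
        gene_id = genes$gene_id[i], chrom = "chr1",
        class = c("NONCODING", "INTRON", "NONCODING"),
        start = c(s, round(s + (mid - s) / 2), mid),
        end = c(round(s + (mid - s) / 2), mid, e)
      )
    }
  })
  components <- bind_rows(comp_rows)
  components <- components[components$end > components$start, , drop = FALSE]

  n_rep <- round(cf$repeat_density * L / 1500)
  repeats <- if (n_rep > 0) {
    rs <- sort(sample.int(L - 2000L, n_rep))
    tibble(chrom = "chr1", start = rs, end = pmin(rs + round(runif(n_rep, 200, 2500)), L))
  } else {
    tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  list(genes = genes, components = components, repeats = repeats)
}

#' Generate expression with planted cis effects and a trans hub
#'
#' One expression feature per gene (anchor = gene start). Expression is
#' baseline + planted cis beta x dosage + per-population shift + hub pathway
#' + Gaussian noise. The hub plants a driver variant cis to a regulator
#' feature; every hub target feature then receives
#' `hub_attenuation x regulator expression`, so the driver's dosage reaches
#' distant features only through the regulator — the trans-hotspot motif.
#' The driver is chosen among sweep variants when available (sweep-and-
#' regulate), otherwise any variant near a gene.
#'
#' @param config A [generator_config()].
#' @param genotypes Output of [generate_genotypes()].
#' @param annotations Output of [generate_annotations()].
#' @return List: `expression` (features x samples matrix), `anchors`
#'   (tibble `feature_id`, `chrom`, `pos`), `truth` (tibble `variant`,
#'   `feature`, `beta`, `kind` for every planted effect).
#' @export
generate_expression <- function(config, genotypes, annotations) {
  set.seed(config$seed + 2L)
  cf <- config
  gm <- genotypes$genotypes
  genes <- annotations$genes
  dos <- dosage_matrix(gm)
  n_smp <- ncol(dos)
  n_feat <- nrow(genes)
  keys <- variant_keys(gm)

  anchors <- tibble(feature_id = genes$gene_id, chrom = genes$chrom,
                    pos = genes$start)
  pop <- genotypes$panel$population[match(colnames(dos),
                                          genotypes$panel$sample)]
  expr <- matrix(rnorm(n_feat * n_smp, sd = cf$noise_sd), n_feat, n_smp,
                 dimnames = list(genes$gene_id, colnames(dos)))
  shift <- matrix(rnorm(n_feat * length(unique(pop)), sd = cf$pop_shift_sd),
                  n_feat, length(unique(pop)),
                  dimnames = list(NULL, sort(unique(pop))))
  expr <- expr + shift[, pop]

  # variants eligible as planted regulators: polymorphic in the pooled set
  pooled <- rowMeans(dos, na.rm = TRUE) / 2
  poly <- which(pooled > 0.05 & pooled < 0.95)
  truth <- list()

  cis_pairs <- 0L
  if (cf$n_cis_effects > 0 && length(poly) > 0) {
    cand <- sample(poly, min(cf$n_cis_effects, length(poly)))
    for (v in cand) {
      d <- abs(genes$start - gm$variants$pos[v])
      feat <- which.min(d)
      if (d[feat] > 1e6) next
      expr[feat, ] <- expr[feat, ] + cf$cis_beta * dos[v, ]
      truth[[length(truth) + 1L]] <- tibble(
        variant = keys[v], feature = genes$gene_id[feat],
        beta = cf$cis_beta, kind = "cis")
      cis_pairs <- cis_pairs + 1L
    }
  }

  if (cf$hub_n_targets > 0 && length(poly) > 0) {
    sweep_keys <- genotypes$truth$key[genotypes$truth$is_sweep]
    sweep_poly <- intersect(which(keys %in% sweep_keys), poly)
    driver <- if (length(sweep_poly) > 0) sweep_poly[1] else poly[1]
    d <- abs(genes$start - gm$variants$pos[driver])
    regulator <- which.min(d)
    expr[regulator, ] <- expr[regulator, ] + cf$cis_beta * dos[driver, ]
    truth[[length(truth) + 1L]] <- tibble(
      variant = keys[driver], feature = genes$gene_id[regulator],
      beta = cf$cis_beta, kind = "cis")
    far <- which(abs(genes$start - gm$variants$pos[driver]) > 1e6)
    targets <- if (length(far) >= cf$hub_n_targets) {
      sample(far, cf$hub_n_targets)
    } else far
    for (feat in targets) {
      expr[feat, ] <- expr[feat, ] + cf$hub_attenuation * expr[regulator, ]
      truth[[length(truth) + 1L]] <- tibble(
        variant = keys[driver], feature = genes$gene_id[feat],
        beta = cf$cis_beta * cf$hub_attenuation, kind = "trans")
    }
  }

  list(expression = expr, anchors = anchors,
       truth = if (length(truth) > 0) bind_rows(truth) else
         tibble(variant = character(0), feature = character(0),
                beta = numeric(0), kind = character(0)))
}

#' Generate a complete dataset and write it in pipeline input formats
#'
#' Emits exactly the formats the readers consume: a phased VCF, a panel TSV,
#' an ancestral TSV, gene/component TSVs, a repeat BED, an expression TSV
#' (features x samples), a feature-anchor TSV, truth-table TSVs and a
#' manifest JSON recording config and seed.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genotypes(config)
  ann <- generate_annotations(config)
  expr <- generate_expression(config, gen, ann)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    panel = file.path(dir, "panel.tsv"),
    ancestral = file.path(dir, "ancestral.tsv"),
    genes = file.path(dir, "genes.tsv"),
    components = file.path(dir, "components.tsv"),
    repeats = file.path(dir, "repeats.bed"),
    expression = file.path(dir, "expression.tsv"),
    anchors = file.path(dir, "anchors.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_eqtl = file.path(dir, "truth_eqtl.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_vcf(gen$genotypes, paths$vcf)
  readr::write_tsv(gen$panel, paths$panel, progress = FALSE)
  anc <- gen$genotypes$variants %>%
    select("chrom", "pos", "ref", "alt") %>%
    mutate(ancestral = gen$ancestral$ancestral)
  readr::write_tsv(anc, paths$ancestral, progress = FALSE)
  readr::write_tsv(ann$genes, paths$genes, progress = FALSE)
  readr::write_tsv(ann$components, paths$components, progress = FALSE)
  readr::write_tsv(ann$repeats, paths$repeats, col_names = FALSE,
                   progress = FALSE)
  expr_tbl <- as_tibble(expr$expression, rownames = "feature_id")
  readr::write_tsv(expr_tbl, paths$expression, progress = FALSE)
  readr::write_tsv(expr$anchors, paths$anchors, progress = FALSE)
  readr::write_tsv(gen$truth, paths$truth_variants, progress = FALSE)
  readr::write_tsv(expr$truth, paths$truth_eqtl, progress = FALSE)
  jsonlite::write_json(list(seed = config$seed, config = unclass(config)),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
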
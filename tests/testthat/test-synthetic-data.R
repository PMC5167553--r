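test_that("zero drift collapses populations onto the ancestral frequencies", {
  cfg <- test_generator_config(seed = 1, drift = c(AFR = 0, EAS = 0, EUR = 0),
                               sweep_fraction = 0)
  gen <- generate_genotypes(cfg)
  truth <- gen$truth
  expect_equal(truth$daf_AFR, truth$daf_EUR)
  # corrected genome-wide estimate is near zero
  pv <- variant_fst(gen$genotypes, gen$panel, "AFR", "EUR", corrected = TRUE)
  est <- fst_region(pv[, c("num", "den")])
  expect_lt(abs(est$fst), 0.02)
})

test_that("the generator is deterministic given its seed", {
  g1 <- generate_genotypes(test_generator_config(seed = 5))
  g2 <- generate_genotypes(test_generator_config(seed = 5))
  expect_identical(g1$genotypes$haplotypes, g2$genotypes$haplotypes)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_genotypes(test_generator_config(seed = 6))
  expect_false(identical(g1$genotypes$haplotypes, g3$genotypes$haplotypes))
})

test_that("sweep variants surface in the top delta-DAF groups", {
  cfg <- test_generator_config(seed = 2, sweep_fraction = 0.05)
  gen <- generate_genotypes(cfg)
  truth <- gen$truth
  dd <- delta_daf(truth$daf_EUR, truth$daf_AFR)
  recs <- tibble::tibble(delta_daf = dd,
                         chrom = "chr1",
                         pos = gen$genotypes$variants$pos,
                         alt = gen$genotypes$variants$alt,
                         is_sweep = truth$is_sweep)
  g <- group_by_delta_daf(recs, 50)
  top <- g[g$group == 1, ]
  expect_gt(mean(top$is_sweep), mean(recs$is_sweep))
  # construction: a 0.95 vs 0.05 variant has delta-DAF 0.9 in range
  expect_true(all(dd[truth$is_sweep] > 0.8))
})

test_that("realised per-population frequencies track the generating values", {
  cfg <- test_generator_config(seed = 3)
  gen <- generate_genotypes(cfg)
  daf_hat <- polarize(gen$genotypes, gen$panel)
  truth <- gen$truth
  # compare where the recorded ancestral call is correct
  correct <- !daf_hat$excluded
  for (p in c("AFR", "EAS", "EUR")) {
    err <- abs(daf_hat[[paste0("daf_", p)]] -
                 truth[[paste0("daf_", p)]])[correct]
    # mislabels flip DAF to 1-DAF; exclude gross flips, check the bulk
    expect_lt(median(err, na.rm = TRUE), 0.05)
  }
})

test_that("LD blocks induce stronger correlation within than between blocks", {
  cfg <- test_generator_config(seed = 4, n_variants = 200,
                               chrom_length = 1e5, ld_block_length = 2e4,
                               ld_switch_rate = 0.02, sweep_fraction = 0)
  gen <- generate_genotypes(cfg)
  gm <- gen$genotypes
  pos <- gm$variants$pos
  block <- floor(pos / 2e4)
  set.seed(1)
  pairs <- t(utils::combn(sample(seq_along(pos), 30), 2))
  r2 <- apply(pairs, 1, function(ij) {
    ld_pair(gm$haplotypes[ij[1], ], gm$haplotypes[ij[2], ])$r2
  })
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  ok <- !is.na(r2)
  expect_gt(mean(r2[same & ok]), mean(r2[!same & ok]))
})

test_that("annotations exercise every priority class and honour repeat density", {
  cfg <- test_generator_config(seed = 7)
  ann <- generate_annotations(cfg)
  part <- partition_genome(ann$genes, ann$components,
                           c(chr1 = cfg$chrom_length))
  cov <- partition_coverage(part)
  expect_true(all(cov$coverage > 0))
  expect_equal(sum(cov$coverage), cfg$chrom_length)
  # overlapping genes force at least one base whose class changed by priority
  expect_gt(sum(ann$genes$start[2] < ann$genes$end[1]), 0)

  none <- generate_annotations(test_generator_config(seed = 7,
                                                     repeat_density = 0))
  expect_equal(nrow(none$repeats), 0L)
  win <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_equal(classify_repeat(win, none$repeats)$repeat_status, "NONREPEAT")
})

test_that("noiseless planted cis effects are recovered exactly", {
  cfg <- test_generator_config(seed = 8, noise_sd = 0, pop_shift_sd = 0,
                               hub_n_targets = 0, n_cis_effects = 2,
                               cis_beta = 1)
  gen <- generate_genotypes(cfg)
  ann <- generate_annotations(cfg)
  expr <- generate_expression(cfg, gen, ann)
  expect_gt(nrow(expr$truth), 0)
  planted <- expr$truth[1, ]
  v <- which(variant_keys(gen$genotypes) == planted$variant)
  f <- which(rownames(expr$expression) == planted$feature)
  pop <- gen$panel$population
  fit <- fit_eqtl(dosage_matrix(gen$genotypes)[v, ],
                  expr$expression[f, ], population = pop)
  expect_equal(fit$beta, 1, tolerance = 1e-8)
})

test_that("the trans hub tops the hotspot table", {
  # moderately swept driver and low noise keep within-population dosage
  # variance high enough for the trans links to clear family-wide FDR
  cfg <- test_generator_config(seed = 10, chrom_length = 8e6,
                               n_variants = 300, n_genes = 40,
                               samples_per_pop = c(AFR = 80L, EAS = 80L,
                                                   EUR = 80L),
                               sweep_daf_range = c(0.75, 0.9),
                               hub_n_targets = 8, noise_sd = 0.2)
  gen <- generate_genotypes(cfg)
  ann <- generate_annotations(cfg)
  expr <- generate_expression(cfg, gen, ann)
  driver <- unique(expr$truth$variant[expr$truth$kind == "trans"])
  expect_equal(length(driver), 1L)
  filtered <- filter_maf(gen$genotypes, samples = colnames(expr$expression))
  scan <- eqtl_scan(filtered, expr$expression, expr$anchors, gen$panel)
  hc <- hotspot_counts(scan)
  expect_gt(nrow(hc), 0)
  n_targets <- sum(expr$truth$kind == "trans")
  drow <- hc[hc$variant == driver, ]
  expect_equal(nrow(drow), 1L)
  expect_gte(drow$n_trans, n_targets * 0.5)
  # the driver ranks at the top, allowing ties with its LD partners
  # (sweep haplotypes carry near-identical dosages)
  expect_lte(match(driver, hc$variant), 10L)
  expect_lte(hc$n_trans[1], drow$n_trans + n_targets)
})

test_that("written datasets round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  cfg <- test_generator_config(seed = 12)
  paths <- write_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  gm <- read_vcf(paths$vcf)
  gen <- generate_genotypes(cfg)
  expect_equal(gm$haplotypes, gen$genotypes$haplotypes, ignore_attr = TRUE)
  panel <- read_panel(paths$panel)
  expect_equal(nrow(panel), sum(cfg$samples_per_pop))
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 12L)
})
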
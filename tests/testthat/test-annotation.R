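two_gene_fixture <- function() {
  # gene A: [1000, 9000) coding with intron [4000, 6000);
  # gene B: [5000, 12000) coding with UTR5 [5000, 5500)
  genes <- tibble::tibble(
    gene_id = c("A", "B"), chrom = "chr1",
    start = c(1000, 5000), end = c(9000, 12000),
    strand = c("+", "+"), coding = TRUE
  )
  components <- tibble::tibble(
    gene_id = c("A", "A", "A", "B", "B"),
    chrom = "chr1",
    class = c("CDS", "INTRON", "CDS", "UTR5", "CDS"),
    start = c(1000, 4000, 6000, 5000, 5500),
    end = c(4000, 6000, 9000, 5500, 12000)
  )
  list(genes = genes, components = components)
}

test_that("priority resolves overlaps: CDS beats UTR5 beats intron", {
  fx <- two_gene_fixture()
  part <- partition_genome(fx$genes, fx$components, c(chr1 = 30000))
  class_at <- function(pos) part$class[part$start <= pos & part$end > pos]
  # intron of A overlapping UTR5 of B -> UTR5
  expect_equal(class_at(5200), "UTR5")
  # CDS of A overlapping UTR5 of B region? CDS of B starts 5500 inside intron A
  expect_equal(class_at(5600), "CDS")
  # plain intron of A
  expect_equal(class_at(4500), "INTRON")
  # >= 5000 bp from every gene
  expect_equal(class_at(25000), "REMAINDER")
  # flanks: [start-1000, start) is UP1000, [start-5000, start-1000) UP5000
  expect_equal(class_at(500), "UP1000")
  expect_equal(class_at(12500), "DOWN1000")
  expect_equal(class_at(14000), "DOWN5000")
})

test_that("the partition is exhaustive and exclusive", {
  fx <- two_gene_fixture()
  L <- 30000
  part <- partition_genome(fx$genes, fx$components, c(chr1 = L))
  expect_equal(sum(part$end - part$start), L)
  # no two intervals overlap
  part <- part[order(part$start), ]
  expect_true(all(part$start[-1] >= part$end[-nrow(part)]))
  # coverage report sums to genome length too
  expect_equal(sum(partition_coverage(part)$coverage), L)
})

test_that("adding a lower-priority annotation never changes a higher-priority base", {
  fx <- two_gene_fixture()
  part1 <- partition_genome(fx$genes, fx$components, c(chr1 = 30000))
  # add a new gene whose intron spans gene A's CDS
  genes2 <- dplyr::bind_rows(fx$genes, tibble::tibble(
    gene_id = "C", chrom = "chr1", start = 500, end = 9500,
    strand = "+", coding = TRUE))
  comps2 <- dplyr::bind_rows(fx$components, tibble::tibble(
    gene_id = "C", chrom = "chr1", class = "INTRON", start = 500, end = 9500))
  part2 <- partition_genome(genes2, comps2, c(chr1 = 30000))
  class_at <- function(part, pos) part$class[part$start <= pos & part$end > pos]
  for (pos in c(2000, 5200, 5600)) {
    expect_equal(class_at(part2, pos), class_at(part1, pos))
  }
})

test_that("repeat classification needs at least one overlapping base", {
  repeats <- tibble::tibble(chrom = "chr1", start = 999, end = 1200)
  win <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_equal(classify_repeat(win, repeats)$repeat_status, "REPEAT")
  repeats2 <- tibble::tibble(chrom = "chr1", start = 1000, end = 1200)
  expect_equal(classify_repeat(win, repeats2)$repeat_status, "NONREPEAT")
  none <- tibble::tibble(chrom = character(0), start = numeric(0),
                         end = numeric(0))
  expect_equal(classify_repeat(win, none)$repeat_status, "NONREPEAT")
})

test_that("per-gene estimates use the gene body and its extended region", {
  hap <- matrix(c(1L, 1L, 0L, 0L,     # inside gene
                  1L, 0L, 1L, 0L,     # in the 5 kb extension only
                  1L, 1L, 1L, 1L),    # inside gene, monomorphic in both
                nrow = 3, byrow = TRUE)
  gm <- make_gm(hap, pos = c(1500L, 9500L, 1600L))
  panel <- make_panel(c("S01", "S02"), c("A", "B"))
  genes <- tibble::tibble(gene_id = c("G1", "G2"), chrom = "chr1",
                          start = c(1000, 20000), end = c(2000, 21000),
                          coding = TRUE)
  gf <- gene_fst_table(genes, gm, panel, "A", "B", corrected = FALSE)
  # single informative variant: gene estimate equals that variant's ratio
  pv <- variant_fst(gm, panel, "A", "B", corrected = FALSE)
  expect_equal(gf$fst[1], pv$fst[1])
  expect_gte(gf$n_variants_ext[1], gf$n_variants[1])
  # gene with no usable variants is flagged undefined, not dropped
  expect_false(gf$defined[2])
  expect_true(is.na(gf$fst[2]))
})

test_that("extreme selection sizes follow ceiling arithmetic and ties are deterministic", {
  est <- tibble::tibble(fst = seq(0, 1, length.out = 200),
                        chrom = "chr1", start = seq_len(200) * 100)
  ext <- select_extremes(est, mode = "fraction", k = 0.01)
  expect_equal(nrow(ext$top), 2L)
  expect_equal(nrow(ext$bottom), 2L)
  expect_equal(ext$top$fst[1], 1)

  est150 <- tibble::tibble(fst = runif(150), chrom = "chr1",
                           start = seq_len(150))
  ext100 <- NULL
  expect_warning(ext100 <- select_extremes(est150, mode = "count", k = 100),
                 "overlap")
  expect_equal(nrow(ext100$top), 100L)
  expect_equal(nrow(ext100$bottom), 100L)

  ties <- tibble::tibble(fst = rep(0.5, 10), chrom = "chr1",
                         start = 10:1 * 100)
  sel <- select_extremes(ties, mode = "count", k = 3)
  expect_equal(sel$top$start, c(100, 200, 300))  # coordinate-ordered
})

test_that("length-matched sampling is reproducible and exact in length", {
  targets <- tibble::tibble(chrom = "chr1", start = c(1e5, 3e5),
                            end = c(1.1e5, 3.2e5))
  m1 <- length_matched_sample(targets, c(chr1 = 1e6), seed = 11)
  m2 <- length_matched_sample(targets, c(chr1 = 1e6), seed = 11)
  expect_identical(m1, m2)
  expect_equal(m1$end - m1$start, targets$end - targets$start)
  # no overlap with the targets themselves
  for (i in seq_len(nrow(m1))) {
    expect_false(any(m1$start[i] < targets$end & m1$end[i] > targets$start))
  }
  too_long <- tibble::tibble(chrom = "chr1", start = 0, end = 2e6)
  expect_error(length_matched_sample(too_long, c(chr1 = 1e6), seed = 1),
               "cannot be placed")
})

test_that("enrichment matches the textbook 2x2 chi-squared and flags degenerate margins", {
  flagsA <- tibble::tibble(category = "cis", has_eqtl = rep(c(TRUE, FALSE),
                                                            c(90, 10)))
  flagsB <- tibble::tibble(category = "cis", has_eqtl = rep(c(TRUE, FALSE),
                                                            c(10, 90)))
  enr <- region_eqtl_enrichment(flagsA, flagsB)
  expect_equal(enr$prop_A, 0.9)
  expect_equal(enr$prop_B, 0.1)
  # textbook chi-squared with no continuity correction: sum (O-E)^2/E
  O <- rbind(c(90, 10), c(10, 90)); E <- outer(rowSums(O), colSums(O)) / 200
  expect_equal(enr$chisq, sum((O - E)^2 / E))
  expect_lt(enr$p, 0.001)

  same <- region_eqtl_enrichment(flagsA, flagsA)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  degenerate <- region_eqtl_enrichment(
    tibble::tibble(category = "cis", has_eqtl = TRUE),
    tibble::tibble(category = "cis", has_eqtl = TRUE))
  expect_false(degenerate$defined)
  expect_true(is.na(degenerate$p))
})
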
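test_that("Hudson components match direct evaluation of the estimator", {
  # fixed difference
  hc <- hudson_components(1, 100, 0, 100, corrected = TRUE)
  expect_equal(hc$num, 1)
  expect_equal(hc$den, 1)

  # identical intermediate frequencies, corrected: negative numerator
  hc <- hudson_components(0.5, 100, 0.5, 100, corrected = TRUE)
  expect_equal(hc$num, -0.25 / 99 - 0.25 / 99)
  expect_equal(hc$den, 0.5)
  expect_equal(hc$num / hc$den, -0.01010101, tolerance = 1e-6)

  # identical frequencies, uncorrected: exactly zero
  hc <- hudson_components(0.3, 10, 0.3, 10, corrected = FALSE)
  expect_equal(hc$num, 0)

  # negative corrected numerators are never clamped
  expect_lt(hudson_components(0.01, 1008, 0.01, 1006)$num, 0)

  expect_error(hudson_components(0.5, 1, 0.5, 100, corrected = TRUE),
               "at least 2")
  expect_error(hudson_components(1.2, 10, 0.5, 10), "\\[0, 1\\]")
})

test_that("region aggregation is a ratio of averages, not a mean of ratios", {
  comp <- tibble::tibble(num = c(0.1, 0.3), den = c(0.4, 0.6))
  est <- fst_region(comp)
  expect_equal(est$fst, 0.4)
  expect_false(isTRUE(all.equal(est$fst, mean(c(0.1 / 0.4, 0.3 / 0.6)))))

  single <- fst_region(tibble::tibble(num = 0.2, den = 0.5))
  expect_equal(single$fst, 0.4)
  expect_equal(single$n_variants, 1L)

  undef <- fst_region(tibble::tibble(num = c(0, 0), den = c(0, 0)))
  expect_false(undef$defined)
  expect_true(is.na(undef$fst))

  empty <- fst_region(tibble::tibble(num = numeric(0), den = numeric(0)))
  expect_false(empty$defined)
})

test_that("windows are multiples of the window size and remnants are excluded", {
  # variants at 1-based positions across 25 kb; the [20000, 25000) remnant
  # must be ignored for 10 kb windows
  hap <- matrix(c(1L, 0L, 0L, 0L,
                  1L, 1L, 0L, 0L,
                  1L, 1L, 1L, 1L), nrow = 3, byrow = TRUE)
  gm <- make_gm(hap, pos = c(5000L, 15000L, 22000L))
  panel <- make_panel(c("S01", "S02"), c("A", "B"))
  w <- windowed_fst(gm, panel, "A", "B", 10000, c(chr1 = 25000),
                    corrected = FALSE)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(0, 10000))
  expect_equal(sum(w$n_variants), 2L)   # the 22 kb variant is excluded

  # identical frequencies in both populations, uncorrected: all windows 0
  hap0 <- matrix(rep(c(1L, 0L, 1L, 0L), 2), nrow = 2, byrow = TRUE)
  gm0 <- make_gm(hap0, pos = c(500L, 10500L))
  w0 <- windowed_fst(gm0, panel, "A", "B", 10000, c(chr1 = 25000),
                     corrected = FALSE)
  expect_equal(w0$fst[w0$defined], c(0, 0))

  # windows without variants are reported undefined, not dropped
  expect_true(any(!w0$defined) || all(w0$n_variants > 0))
  w_empty <- windowed_fst(gm0, panel, "A", "B", 1000, c(chr1 = 25000),
                          corrected = FALSE)
  expect_equal(nrow(w_empty), 25L)
  expect_equal(sum(w_empty$defined), 2L)
})

test_that("uncorrected single-variant estimates stay in [0,1], corrected <= 1", {
  set.seed(1)
  p1 <- runif(200); p2 <- runif(200)
  unc <- hudson_components(p1, 100, p2, 100, corrected = FALSE)
  ok <- unc$den > 0
  expect_true(all(unc$num[ok] / unc$den[ok] >= 0))
  expect_true(all(unc$num[ok] / unc$den[ok] <= 1))
  cor <- hudson_components(p1, 100, p2, 100, corrected = TRUE)
  expect_true(all(cor$num[ok] / cor$den[ok] <= 1))
})

test_that("estimates agree with a brute-force count-table implementation", {
  set.seed(7)
  n_var <- 18
  hap <- matrix(rbinom(n_var * 40, 1, runif(n_var)), nrow = n_var)
  gm <- make_gm(hap)
  panel <- make_panel(sprintf("S%02d", 1:20), rep(c("A", "B"), each = 10))
  fm <- allele_freq_matrix(gm, panel)
  alt1 <- fm$freq[, "A"] * fm$called[, "A"]
  alt2 <- fm$freq[, "B"] * fm$called[, "B"]
  keep <- !(alt1 == 0 & alt2 == 0) & !(alt1 == 20 & alt2 == 20)
  expected <- brute_fst(alt1[keep], fm$called[keep, "A"],
                        alt2[keep], fm$called[keep, "B"], corrected = TRUE)
  pv <- variant_fst(gm, panel, "A", "B", corrected = TRUE)
  got <- fst_region(pv[keep, c("num", "den")])$fst
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("structural-variant estimates cover per-allele and pooled forms", {
  hap <- matrix(c(rep(1L, 4), rep(0L, 4),    # fixed in A, absent in B
                  rep(0L, 8)), nrow = 2, byrow = TRUE)
  hap[2, 1] <- 1L                            # rare in A only
  gm <- make_gm(hap, vclass = "SV-DEL")
  panel <- make_panel(sprintf("S%02d", 1:4), rep(c("A", "B"), each = 2))
  sv <- fst_structural(gm, panel, "A", "B")
  expect_equal(sv$per_allele$fst[1], 1)
  expect_equal(nrow(sv$per_allele), 2L)
  expect_true(sv$pooled$defined)

  # rare in both populations: small negative corrected value, by the formula
  p1 <- 0.01; p2 <- 0.01; n1 <- 1008; n2 <- 1006
  hcalc <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  hc <- hudson_components(p1, n1, p2, n2)
  expect_equal(hc$num, hcalc)
  expect_lt(hc$num, 0)
  expect_gt(hc$num, -1e-4)
})
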
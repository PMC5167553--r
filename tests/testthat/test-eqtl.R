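test_that("MAF filter is strict and uses the pooled analyzed samples", {
  freqs <- c(0.04, 0.05, 0.06, 0.5)
  hap <- do.call(rbind, lapply(freqs, function(f) {
    v <- rep(0L, 100); v[seq_len(round(f * 100))] <- 1L; v
  }))
  gm <- make_gm(hap)
  kept <- filter_maf(gm, threshold = 0.05)
  expect_equal(kept$variants$pos, gm$variants$pos[c(3, 4)])
  # the boundary value 0.05 itself is removed
  expect_false(gm$variants$pos[2] %in% kept$variants$pos)
})

test_that("single fits recover noiseless effects and match the OLS oracle", {
  fit <- fit_eqtl(c(0, 1, 2, 0, 1, 2), 2 * c(0, 1, 2, 0, 1, 2),
                  population = rep(c("A", "B"), each = 3))
  expect_equal(fit$beta, 2)
  expect_lt(fit$p, 1e-10)

  # 6-sample worked fixture against closed-form normal equations
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(1.0, 1.2, 2.1, 1.9, 3.0, 3.2)
  fit <- fit_eqtl(x, y)
  sxx <- sum((x - mean(x))^2)
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - beta_hat * mean(x)) - beta_hat * x
  se <- sqrt(sum(resid^2) / 4 / sxx)
  expect_equal(fit$beta, beta_hat)
  expect_equal(fit$tstat, beta_hat / se)
  expect_equal(fit$p, 2 * pt(-abs(beta_hat / se), 4))
  # and against lm() as an independent route
  lm_fit <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$beta, lm_fit["x", "Estimate"])
  expect_equal(fit$p, lm_fit["x", "Pr(>|t|)"])

  # collinear dosage (constant within covariate strata) is skipped
  skip_fit <- fit_eqtl(rep(c(0, 2), each = 5), rnorm(10),
                       population = rep(c("A", "B"), each = 5))
  expect_true(is.na(skip_fit$beta))
})

test_that("the vectorised scan equals per-pair lm fits with a population covariate", {
  set.seed(3)
  n <- 30
  hap <- matrix(rbinom(5 * 2 * n, 1, 0.4), nrow = 5)
  gm <- make_gm(hap, pos = c(100L, 200L, 5e5L, 2e6L, 3e6L))
  panel <- make_panel(sprintf("S%02d", seq_len(n)),
                      rep(c("A", "B"), length.out = n))
  expr <- matrix(rnorm(2 * n), nrow = 2,
                 dimnames = list(c("f1", "f2"), sprintf("S%02d", seq_len(n))))
  anchors <- tibble::tibble(feature_id = c("f1", "f2"), chrom = "chr1",
                            pos = c(150, 2.5e6))
  scan <- eqtl_scan(gm, expr, anchors, panel, cis_p = 1, trans_p = 1)
  pop <- panel$population
  dos <- dosage_matrix(gm)
  for (i in seq_len(nrow(scan$records))) {
    rec <- scan$records[i, ]
    v <- which(variant_keys(gm) == rec$variant)
    f <- which(anchors$feature_id == rec$feature)
    cf <- summary(lm(expr[f, ] ~ dos[v, ] + pop))$coefficients
    expect_equal(rec$beta, cf[2, "Estimate"], tolerance = 1e-10)
    expect_equal(rec$p, cf[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("cis/trans classification uses an inclusive 1 Mb boundary", {
  expect_equal(classify_cis_trans("chr1", 100, "chr1", 100 + 1e6), "cis")
  expect_equal(classify_cis_trans("chr1", 100, "chr1", 100 + 1e6 + 1), "trans")
  expect_equal(classify_cis_trans("chr1", 100, "chr2", 100), "trans")
})

test_that("per-family thresholds and BH adjustment match the brute-force oracle", {
  recs <- tibble::tibble(kind = "cis", p = c(0.001, 0.02, 0.04, 0.8))
  out <- threshold_and_fdr(recs, cis_p = 1, trans_p = 1)
  expect_equal(out$fdr, c(0.004, 0.04, 0.04 * 4 / 3, 0.8))

  single <- threshold_and_fdr(tibble::tibble(kind = "cis", p = 0.04))
  expect_equal(single$fdr, 0.04)
  expect_true(single$significant)

  # trans tests at p = 0.02 are discarded before FDR
  trans <- threshold_and_fdr(tibble::tibble(kind = "trans", p = c(0.02, 0.005)))
  expect_equal(nrow(trans), 1L)
  expect_equal(trans$p, 0.005)

  # BH property: significant set is exactly {p <= k* alpha / m}
  set.seed(5)
  p <- c(runif(15, 0, 0.04), runif(5, 0, 0.001))
  out <- threshold_and_fdr(tibble::tibble(kind = "cis", p = p), cis_p = 1)
  expect_setequal(out$p[out$significant], p[brute_bh_significant(p, 0.05)])
})

test_that("hotspot counts rank a planted hub first and are empty on empty input", {
  recs <- tibble::tibble(
    variant = c(rep("hub", 50), "other", "other"),
    kind = c(rep("trans", 50), "cis", "trans"),
    significant = TRUE
  )
  hc <- hotspot_counts(recs)
  expect_equal(hc$variant[1], "hub")
  expect_equal(hc$n_trans[1], 50L)
  empty <- hotspot_counts(tibble::tibble(variant = character(0),
                                         kind = character(0),
                                         significant = logical(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("tidy and glance expose records and family counts", {
  set.seed(9)
  n <- 24
  hap <- matrix(rbinom(4 * 2 * n, 1, 0.5), nrow = 4)
  gm <- make_gm(hap, pos = c(100L, 200L, 2e6L, 3e6L))
  panel <- make_panel(sprintf("S%02d", seq_len(n)),
                      rep(c("A", "B"), length.out = n))
  expr <- matrix(rnorm(2 * n), nrow = 2,
                 dimnames = list(c("f1", "f2"), gm$sample_ids))
  anchors <- tibble::tibble(feature_id = c("f1", "f2"), chrom = "chr1",
                            pos = c(150, 2.5e6))
  scan <- eqtl_scan(gm, expr, anchors, panel, cis_p = 1, trans_p = 1)
  expect_s3_class(tidy(scan), "tbl_df")
  g <- glance(scan)
  expect_equal(g$n_tests_cis + g$n_tests_trans, 8L)
})

test_that("transcription ratios guard zero denominators", {
  expr <- matrix(c(1, 1, 0,
                   3, 1, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  tr <- transcription_ratios(expr, gene_of = c("g", "g"))
  expect_equal(tr["t1", "s1"], 0.25)
  expect_equal(tr["t2", "s2"], 0.5)
  expect_true(all(is.na(tr[, "s3"])))
})
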
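test_that("OLS fit matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  fit <- ols_fit(x, y)
  want <- bf_ols(x, y)
  expect_equal(fit$slope, want$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(fit$r, want$r, tolerance = 1e-10)
  expect_equal(fit$p, want$p, tolerance = 1e-10)

  for (seed in 1:10) {
    xx <- withr::with_seed(seed, rnorm(20))
    yy <- withr::with_seed(seed + 99, 1.5 * xx + rnorm(20))
    f <- ols_fit(xx, yy); w <- bf_ols(xx, yy)
    expect_equal(f$slope, w$slope, tolerance = 1e-10)
    expect_equal(f$p, w$p, tolerance = 1e-10)
  }

  exact <- ols_fit(x, 2 * x)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r, 1)
  flat <- ols_fit(x, rep(3, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)
  expect_error(ols_fit(rep(1, 5), y), "zero variance")
  # duplicated points leave the weight-free fit unchanged
  expect_equal(ols_fit(c(x, x), c(y, y))$slope, fit$slope)
})

test_that("binned regression recovers planted per-bin linear models", {
  hits_in_band <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    rec <- withr::with_seed(seed, {
      cai <- runif(100, 0.45, 0.67)          # rare bin
      data.frame(cai = cai, density = 30 - 25 * cai + rnorm(100, 0, 2))
    })
    res <- binned_regression(rec)
    rare <- res[res$bin == "rare", ]
    expect_false(rare$insufficient)
    expect_lt(rare$slope, 0)                 # inverse correlation recovered
    w <- bf_ols(rec$cai, rec$density)
    if (abs(rare$slope - (-25)) <= 2 * w$se_slope) {
      hits_in_band <- hits_in_band + 1L
    }
    # the untouched bins are flagged, not dropped
    expect_true(all(res$insufficient[res$bin != "rare"]))
    expect_equal(nrow(res), 3L)
  }
  expect_gte(hits_in_band, 17L)              # ~95% coverage of 2 SE band

  # shuffled densities: no signal at n = 100
  rec <- withr::with_seed(5, data.frame(cai = runif(100, 0.45, 0.67),
                                        density = rnorm(100, 10, 2)))
  res <- binned_regression(rec)
  expect_gt(res$p[res$bin == "rare"], 0.05)
  expect_error(binned_regression(rec[0, ]), "no records")
})

test_that("binned regression honors the direction filter", {
  rec <- data.frame(cai = c(0.5, 0.55, 0.6, 0.5, 0.55, 0.6),
                    density = c(10, 8, 6, 1, 1, 1),
                    direction = rep(c("up_by_orb2", "down_by_orb2"), each = 3))
  up <- binned_regression(rec, direction = "up_by_orb2")
  expect_equal(up$n[up$bin == "rare"], 3L)
  expect_lt(up$slope[up$bin == "rare"], 0)
  expect_error(binned_regression(rec[, 1:2], direction = "up_by_orb2"),
               "no 'direction' column")
})

test_that("reporter regression detects an inverse CAI/site relationship", {
  perfect <- data.frame(cai = seq(0.5, 1, length.out = 6),
                        site_count = seq(10, 0, length.out = 6))
  fit <- reporter_regression(perfect)
  expect_equal(fit$r, -1)
  expect_error(reporter_regression(perfect[1:2, ]), ">= 3 reporters")

  # panel built end-to-end from package pieces: synthesize reporters across
  # a CAI ladder, count planted sites inversely related to CAI
  panel <- do.call(rbind, lapply(1:10, function(i) {
    target <- 0.55 + 0.045 * (i - 1)
    cds <- synth_cds(300, target, fix_weights, seed = 30 + i, tol = 0.01)
    n_sites <- 10 - i                       # designed inverse relationship
    utr <- plant_motifs(200, "TTTTAT",
                        if (n_sites > 0) seq(1, by = 19, length.out = n_sites)
                        else integer(0), seed = 60 + i)
    hits <- scan_pwm(extract_scan_region(transcript_model(paste0("r", i),
                                                          cds, utr)),
                     fix_pwm, fix_dist)
    data.frame(cai = compute_cai(cds, fix_weights)$cai,
               site_count = sum(hits$hits$class == "significant"))
  }))
  fit2 <- reporter_regression(panel)
  expect_lt(fit2$slope, 0)
  expect_lt(fit2$p, 0.01)
})

test_that("candidate cascade recovers planted survivors exactly", {
  genes <- sprintf("g%02d", 1:40)
  # planted design: 20 upregulated; of those 10 low-CAI; 6 dense; 4 bound;
  # 2 with a brain role
  de <- data.frame(gene = genes,
                   direction = rep(c("up_by_orb2", "unchanged"), each = 20))
  cai <- setNames(c(rep(0.5, 10), rep(0.9, 10), runif(20, 0.4, 1)), genes)
  density <- setNames(c(rep(15, 6), rep(1, 14), rep(15, 20)), genes)
  binding <- genes[1:4]
  brain <- genes[c(1, 2, 30)]
  rep_ <- candidate_cascade(de, cai, density, binding, brain)
  expect_equal(rep_$n, c(20L, 10L, 6L, 4L, 2L))
  sets <- attr(rep_, "gene_sets")
  expect_setequal(sets$brain, c("g01", "g02"))
  # subset chain
  for (i in 2:5) expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  # strictness at the boundaries: CAI == cutoff and density == cutoff fail
  cai2 <- cai; cai2["g01"] <- 0.68
  density2 <- density; density2["g02"] <- 9
  rep2 <- candidate_cascade(de, cai2, density2, binding, brain)
  expect_equal(rep2$n, c(20L, 9L, 4L, 2L, 0L))

  # empty DE table: all stages zero
  rep0 <- candidate_cascade(de[0, ], cai, density, binding, brain)
  expect_equal(rep0$n, rep(0L, 5L))

  # unknown genes are reported, never silently dropped
  de_extra <- rbind(de, data.frame(gene = "mystery", direction = "up_by_orb2"))
  rep3 <- candidate_cascade(de_extra, cai, density, binding, brain)
  expect_equal(attr(rep3, "skipped"), "mystery")
  expect_equal(rep3$n[1L], 20L)
})

test_that("cascade counts are monotone non-increasing on random inputs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 60
      genes <- paste0("g", seq_len(n))
      de <- data.frame(gene = genes,
                       direction = sample(c("up_by_orb2", "down_by_orb2",
                                            "unchanged"), n, replace = TRUE))
      cai <- setNames(runif(n, 0.4, 1), genes)
      density <- setNames(rexp(n, 1 / 8), genes)
      rep_ <- candidate_cascade(de, cai, density,
                                sample(genes, 20), sample(genes, 15))
      expect_true(all(diff(rep_$n) <= 0))
      sets <- attr(rep_, "gene_sets")
      for (i in 2:5) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    })
  }
})

test_that("DE classification maps depletion fold changes to directions", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2FC = c(-2, 1.5, -0.1, -3),
                   padj = c(0.001, 0.01, 0.9, NA))
  cls <- classify_de(de)
  expect_equal(cls$direction, c("up_by_orb2", "down_by_orb2", "unchanged",
                                "unchanged"))
})
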
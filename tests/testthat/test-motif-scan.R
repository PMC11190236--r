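test_that("PWM construction normalizes, pseudocounts, and validates", {
  m <- matrix(c(8, 0, 0, 0), nrow = 4, ncol = 1)
  p <- pwm(m, pseudocount = 1)
  expect_equal(unname(p$mat[, 1]), c(9, 1, 1, 1) / 12)
  expect_equal(sum(p$background), 1)
  expect_error(pwm(matrix(1, 3, 5)), "4 rows")
  p6 <- pwm(matrix(0.25, 4, 6))
  expect_equal(ncol(p6$mat), 6L)
})

test_that("PWM files load in either orientation with labels or comments", {
  tf <- withr::local_tempfile(fileext = ".mat")
  # row-labeled RNA alphabet, 4 x L
  writeLines(c("# U-rich motif", "A 0.05 0.05 0.85", "C 0.05 0.05 0.05",
               "G 0.05 0.05 0.05", "U 0.85 0.85 0.05"), tf)
  p <- read_pwm(tf)
  expect_equal(pwm_consensus(p), "TTA")
  # column-labeled transposed layout (L x 4)
  writeLines(c("A C G U", "0.05 0.05 0.05 0.85", "0.85 0.05 0.05 0.05"), tf)
  p2 <- read_pwm(tf)
  expect_equal(pwm_consensus(p2), "TA")
  # unambiguous unlabeled 4 x L (L != 4)
  writeLines(c("0.1 0.2", "0.1 0.2", "0.1 0.2", "0.7 0.4"), tf)
  expect_equal(pwm_consensus(read_pwm(tf)), "TT")
  # non-numeric cell
  writeLines(c("0.1 oops", "0.1 0.2", "0.1 0.2", "0.7 0.4"), tf)
  expect_error(read_pwm(tf), "non-numeric")
  # ambiguous unlabeled 4 x 4 doubly-stochastic matrix
  writeLines(rep("0.25 0.25 0.25 0.25", 4), tf)
  expect_error(read_pwm(tf), "ambiguous")
})

test_that("DP score distribution equals 4^L brute-force enumeration", {
  for (seed in 1:8) {
    L <- withr::with_seed(seed, sample(2:6, 1))
    p <- withr::with_seed(seed, pwm(matrix(runif(4 * L, 0.02, 1), 4, L),
                                    background = runif(4, 0.1, 1)))
    d <- score_distribution(p)
    bf <- bf_enumerate(p)
    bf_mass <- tapply(bf$prob, bf$score, sum)
    idx <- match(as.integer(names(bf_mass)), d$units)
    expect_false(anyNA(idx))
    expect_equal(unname(d$mass[idx]), unname(as.numeric(bf_mass)),
                 tolerance = 1e-12)
    expect_equal(sum(d$mass), 1, tolerance = 1e-9)
    expect_true(all(diff(d$survival) <= 1e-15))   # survival non-increasing
  }
  # L = 1 uniform PWM, uniform background: single point at score 0
  d1 <- score_distribution(pwm(matrix(0.25, 4, 1)))
  expect_equal(d1$units[d1$mass > 0], 0L)
  expect_equal(sum(d1$mass), 1)
})

test_that("p-value cutoffs match enumeration quantiles and are monotone", {
  # uniform L = 2 motif: every word has p = 1 at score 0
  d_unif <- score_distribution(pwm(matrix(0.25, 4, 2)))
  expect_equal(as.numeric(pvalue_cutoff(d_unif, 1)), min(d_unif$units) * 0.01)

  for (seed in 1:5) {
    L <- withr::with_seed(seed, sample(2:5, 1))
    p <- withr::with_seed(seed, pwm(matrix(runif(4 * L, 0.02, 1), 4, L)))
    d <- score_distribution(p)
    bf <- bf_enumerate(p)
    p_min <- min(d$survival[d$survival > 0])
    for (alpha in c(0.005, 0.01, 0.1)) {
      if (alpha < p_min) {
        # unattainable: maximal score returned, with a warning
        expect_warning(cut <- attr(pvalue_cutoff(d, alpha), "units"),
                       "below minimal attainable")
        expect_equal(cut, max(d$units))
      } else {
        cut <- attr(pvalue_cutoff(d, alpha), "units")
        expect_lte(bf_pvalue(bf, cut), alpha)        # attains alpha
        expect_gt(bf_pvalue(bf, cut - 1L), alpha)    # minimal such score
      }
    }
    expect_gte(as.numeric(suppressWarnings(pvalue_cutoff(d, 0.005))),
               as.numeric(suppressWarnings(pvalue_cutoff(d, 0.01))))
  }
  expect_warning(pvalue_cutoff(fix_dist, 1e-12), "below minimal attainable")
})

test_that("scan region is the codon-aligned last CDS quartile plus 3'UTR", {
  cds400 <- random_cds(400, 1)
  utr <- strrep("A", 200)
  reg <- extract_scan_region(transcript_model("g", cds400, utr))
  expect_equal(reg$length, 500L)                      # 100 codons + 200 nt
  expect_equal(reg$cds_span, c(901L, 1200L))
  expect_equal(reg$utr_span, c(1201L, 1400L))
  expect_equal(reg$region, paste0(substring(cds400, 901, 1200), utr))

  # ceiling rule: 401 codons -> last 101 codons
  reg2 <- extract_scan_region(transcript_model("g", random_cds(401, 2)))
  expect_equal(reg2$length, 101L * 3L)
  expect_null(reg2$utr_span)
})

test_that("scan agrees exactly with the brute-force enumeration scanner", {
  for (seed in 1:12) {
    L <- withr::with_seed(seed, sample(3:6, 1))
    peak <- withr::with_seed(seed, runif(1, 0.5, 0.9))
    cons <- withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), L,
                                                replace = TRUE), collapse = ""))
    p <- make_peaked_pwm(cons, peak = peak)
    d <- score_distribution(p)
    seq <- plant_motifs(150, cons, c(10, 60, 120), seed = seed)
    got <- scan_pwm(seq, p, d)$hits
    want <- bf_scan(seq, bf_enumerate(p))
    expect_equal(got$start, want$start)
    expect_equal(got$class, want$class)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("planted consensus words are recovered as significant hits", {
  cons <- pwm_consensus(fix_pwm)
  seq <- plant_motifs(400, cons, c(5, 200, 390), seed = 3)
  hits <- scan_pwm(seq, fix_pwm, fix_dist)
  sig <- hits$hits[hits$hits$class == "significant", ]
  expect_true(all(c(5, 200, 390) %in% sig$start))
  expect_gte(nrow(sig), 3L)

  # poly-G region vs U-rich PWM: no hits; short region: empty, no error
  expect_equal(nrow(scan_pwm(strrep("G", 100), fix_pwm, fix_dist)$hits), 0L)
  expect_equal(nrow(scan_pwm("ACG", fix_pwm, fix_dist)$hits), 0L)
})

test_that("lowering alpha never increases hits; insertions only shift them", {
  seq <- plant_motifs(300, "TTTTAT", c(50, 150, 250), seed = 9)
  n_strict <- nrow(scan_pwm(seq, fix_pwm, fix_dist, 0.001, 0.005)$hits)
  n_loose <- nrow(scan_pwm(seq, fix_pwm, fix_dist, 0.005, 0.01)$hits)
  expect_lte(n_strict, n_loose)

  # locality: constructed sequence, insertion inside a C-run far from hits
  base <- paste0(strrep("C", 30), "TTTTAT", strrep("C", 30), "TTTTAT",
                 strrep("C", 30))
  h0 <- scan_pwm(base, fix_pwm, fix_dist)$hits
  ins <- paste0(strrep("C", 15), strrep("G", 12), substring(base, 16))
  h1 <- scan_pwm(ins, fix_pwm, fix_dist)$hits
  expect_equal(nrow(h1), nrow(h0))
  expect_equal(h1$start, h0$start + 12L)
})

test_that("halving score granularity does not change hit classes", {
  seq <- plant_motifs(300, "TTTTAT", c(20, 140, 260), seed = 11)
  h1 <- scan_pwm(seq, fix_pwm, score_distribution(fix_pwm, 0.01))$hits
  h2 <- scan_pwm(seq, fix_pwm, score_distribution(fix_pwm, 0.005))$hits
  expect_equal(h1$start, h2$start)
  expect_equal(h1$class, h2$class)
})

test_that("site density normalizes per kilobase and overlaps can merge", {
  expect_equal(site_density(6, 300), 20)
  expect_equal(site_density(0, 500), 0)
  expect_equal(site_density(5, 400), 12.5)
  expect_error(site_density(3, 0), "zero-length")

  hits <- scan_pwm(plant_motifs(250, "TTTTAT", c(10, 100), seed = 4),
                   fix_pwm, fix_dist)
  expect_equal(site_density(hits), nrow(hits$hits) / 0.25)
  # density halves when the same hits sit in a doubled region
  expect_equal(site_density(hits, region_length = 500),
               site_density(hits) / 2)
  # merged overlapping runs never exceed the per-position count
  merged <- scan_pwm(strrep("TTTTAT", 5), fix_pwm, fix_dist,
                     merge_overlaps = TRUE)
  full <- scan_pwm(strrep("TTTTAT", 5), fix_pwm, fix_dist)
  expect_lte(nrow(merged$hits), nrow(full$hits))
})

test_that("frame rarity profile decomposes a motif word per reading frame", {
  # homopolymer word: identical codon in every frame
  prof <- frame_rarity_profile("TTTTTTTTT", "TTT", "TTT", fix_weights)
  expect_equal(nrow(prof), 3L)
  # every frame decomposes into TTT codons only, so classes agree
  expect_equal(unique(unlist(strsplit(prof$codons, ","))), "TTT")
  cls_ttt <- codon_class("TTT", fix_weights)
  n_codons <- lengths(strsplit(prof$codons, ","))
  expect_equal(prof$n_rare,
               if (cls_ttt == "rare") n_codons else rep(0L, 3L))

  # frame shifts change codon identity for a mixed word
  prof2 <- frame_rarity_profile("TTTTAT", "GCA", "CA", fix_weights)
  expect_gt(length(unique(prof2$codons)), 1L)
  # frame 0 decomposition is exactly TTT,TAT with classes from the table
  expect_equal(prof2$codons[1L], "TTT,TAT")
  cls <- codon_class(c("TTT", "TAT"), fix_weights)
  expect_equal(prof2$n_rare[1L], sum(cls == "rare"))
  expect_equal(prof2$n_common[1L], sum(cls == "common"))

  expect_error(frame_rarity_profile("TTTTAT", "", "CC", fix_weights),
               "left flank too short")
})
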
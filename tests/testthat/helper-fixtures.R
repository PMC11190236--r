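# Shared fixtures and independent oracles, built in code at test time.

# usage table / weights used across files (skew 4: w in {1, ~2/3, ..., 1/4})
fix_usage <- synth_usage_table(seed = 101, skew = 4)
fix_weights <- relative_adaptiveness(fix_usage)

# peaked PWM: `peak` probability on the consensus base, rest uniform
make_peaked_pwm <- function(consensus, peak = 0.85,
                            background = rep(0.25, 4)) {
  bases <- strsplit(chartr("U", "T", toupper(consensus)), "")[[1L]]
  mat <- sapply(bases, function(b) {
    col <- rep((1 - peak) / 3, 4)
    col[match(b, c("A", "C", "G", "T"))] <- peak
    col
  })
  pwm(mat, background = background, name = "peaked")
}

# U-rich hexamer motif resembling a CPEB-class binding element
fix_pwm <- make_peaked_pwm("TTTTAT")
fix_dist <- score_distribution(fix_pwm)

# ---- independent oracles ---------------------------------------------------

# brute-force PWM score distribution by full 4^L enumeration, using the same
# integer discretization as the implementation under test
bf_enumerate <- function(p, granularity = 0.01) {
  su <- round(log2(p$mat / p$background) / granularity)
  L <- ncol(su)
  grids <- do.call(expand.grid, rep(list(1:4), L))
  score <- rowSums(sapply(seq_len(L), function(j) su[cbind(grids[[j]], j)]))
  prob <- apply(sapply(seq_len(L), function(j) p$background[grids[[j]]]),
                1L, prod)
  list(su = su, score = score, prob = prob, L = L)
}

bf_pvalue <- function(bf, s_units) {
  vapply(s_units, function(s) sum(bf$prob[bf$score >= s]), numeric(1))
}

# brute-force sliding-window scan: every window scored by enumeration p-value
bf_scan <- function(seq, bf, granularity = 0.01,
                    alpha_sig = 0.005, alpha_sub = 0.01) {
  chars <- strsplit(seq, "")[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  n <- length(code)
  L <- bf$L
  if (n < L) {
    return(data.frame(start = integer(0), p = numeric(0),
                      class = character(0)))
  }
  out <- list()
  for (s in seq_len(n - L + 1L)) {
    b <- code[s:(s + L - 1L)]
    if (any(is.na(b))) next
    sc <- sum(bf$su[cbind(b, seq_len(L))])
    p <- bf_pvalue(bf, sc)
    if (p < alpha_sub) {
      out[[length(out) + 1L]] <- data.frame(
        start = s, score = sc * granularity, p = p,
        class = if (p < alpha_sig) "significant" else "suboptimal")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), score = numeric(0),
                      p = numeric(0), class = character(0)))
  }
  do.call(rbind, out)
}

# brute-force two-sample KS statistic: max ECDF gap over all observed points
bf_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# closed-form OLS via normal equations, with slope standard error
bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2)) / sqrt(sxx)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sxx * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = slope, intercept = intercept, r = r,
       p = 2 * stats::pt(-abs(t), df = n - 2), se_slope = se)
}

# random valid CDS (sense codons only) for property tests
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}

# CDS avoiding Met/Trp, whose single-codon families are "common" by
# definition and so cap the attainable rare-codon fraction
random_cds_no_mw <- function(n_codons, seed) {
  withr::with_seed(seed, {
    gc <- Biostrings::GENETIC_CODE
    multi <- names(gc)[!gc %in% c("*", "M", "W")]
    paste(sample(multi, n_codons, replace = TRUE), collapse = "")
  })
}
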
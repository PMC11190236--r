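#' Construct a position weight matrix (PWM)
#'
#' @param mat numeric matrix, 4 rows (A, C, G, T/U order) by L columns, of
#'   per-position nucleotide probabilities or counts. Counts are normalized
#'   per column.
#' @param background background nucleotide distribution (A, C, G, T), default
#'   uniform.
#' @param pseudocount added to every cell before normalization when any cell
#'   is zero, so log-odds scores stay finite.
#' @param name motif name.
#' @return object of class `pwm`: list with `mat` (4 x L probability matrix,
#'   rownames A,C,G,T), `background`, `name`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.01,
                name = "motif") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(mat) < 1L) stop("PWM must have length >= 1", call. = FALSE)
  if (any(!is.finite(mat)) || any(mat < 0)) {
    stop("PWM cells must be finite and >= 0", call. = FALSE)
  }
  if (any(mat == 0)) mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  rownames(mat) <- NUCS
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  names(background) <- NUCS
  structure(list(mat = mat, background = background, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "', length ", ncol(x$mat), "\n", sep = "")
  cat("  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus word of a PWM (argmax base per column, ties broken A<C<G<T)
#' @param x a `pwm`.
#' @return character consensus string.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(NUCS[apply(x$mat, 2L, which.max)], collapse = "")
}

#' Load a PWM from a matrix text file (RBPmap/MEME-like)
#'
#' Accepts a 4 x L or L x 4 numeric matrix of probabilities or counts, with
#' optional row/column nucleotide labels (ACGT or ACGU) and comment lines
#' starting with `#` or `>`. Orientation is auto-detected: labeled axes win;
#' otherwise the axis whose 4-entry slices sum to 1 is taken as the
#' per-position distribution. A 4 x 4 unlabeled matrix where both readings
#' normalize is ambiguous and rejected.
#'
#' @param path path to the matrix file.
#' @param background background distribution (A,C,G,T); default uniform.
#' @param pseudocount passed to [pwm()].
#' @return a `pwm`.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#>]", lines)]
  if (length(lines) == 0L) stop("no matrix rows in ", path, call. = FALSE)
  toks <- strsplit(lines, "[\\s,]+", perl = TRUE)
  ## optional header line of nucleotide labels (column-labeled layout)
  col_labels <- NULL
  first <- toupper(toks[[1L]])
  if (all(first %in% c("A", "C", "G", "T", "U", "PO", "POS"))) {
    col_labels <- first[first %in% c("A", "C", "G", "T", "U")]
    toks <- toks[-1L]
  }
  row_labels <- character(0)
  rows <- list()
  for (tk in toks) {
    lab <- NA_character_
    if (grepl("^[ACGTUacgtu]$", tk[1L]) ||
        grepl("^[ACGTUacgtu][:|]$", tk[1L])) {
      lab <- toupper(substr(tk[1L], 1L, 1L))
      tk <- tk[-1L]
    } else if (grepl("^[0-9]+[:.]?$", tk[1L]) && length(tk) == 5L &&
               !is.null(col_labels)) {
      tk <- tk[-1L]  # position index column
    }
    vals <- suppressWarnings(as.numeric(tk))
    if (any(is.na(vals))) {
      stop("non-numeric matrix cell in line: ", paste(tk, collapse = " "),
           call. = FALSE)
    }
    row_labels <- c(row_labels, lab)
    rows[[length(rows) + 1L]] <- vals
  }
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) {
    stop("ragged matrix: rows have differing lengths", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  labeled_rows <- !any(is.na(row_labels)) && length(row_labels) == nrow(m)
  norm1 <- function(x) all(abs(x - 1) < 1e-3)
  mat <- NULL
  if (labeled_rows) {
    lr <- chartr("U", "T", row_labels)
    if (!setequal(lr, NUCS)) stop("row labels must be A,C,G,T/U", call. = FALSE)
    mat <- m[match(NUCS, lr), , drop = FALSE]        # 4 x L
  } else if (!is.null(col_labels) && ncol(m) == 4L) {
    lc <- chartr("U", "T", col_labels)
    if (!setequal(lc, NUCS)) stop("column labels must be A,C,G,T/U", call. = FALSE)
    mat <- t(m[, match(NUCS, lc), drop = FALSE])     # L x 4 -> 4 x L
  } else if (nrow(m) == 4L && ncol(m) == 4L) {
    by_col <- norm1(colSums(m)); by_row <- norm1(rowSums(m))
    if (by_col && !by_row) mat <- m
    else if (by_row && !by_col) mat <- t(m)
    else stop("ambiguous 4x4 matrix orientation; label rows or columns",
              call. = FALSE)
  } else if (nrow(m) == 4L) {
    mat <- m
  } else if (ncol(m) == 4L) {
    mat <- t(m)
  } else {
    stop("matrix must be 4 x L or L x 4, got ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  pwm(mat, background = background, pseudocount = pseudocount,
      name = sub("\\.[^.]*$", "", basename(path)))
}

## Integer log-odds score matrix: score units of `granularity` log2 units.
pwm_score_units <- function(x, granularity) {
  if (any(x$mat == 0)) {
    stop("PWM has zero probabilities; rebuild with a pseudocount",
         call. = FALSE)
  }
  round(log2(x$mat / x$background) / granularity)
}

#' Exact score distribution of a PWM under its background
#'
#' Computes the exact probability distribution of the discretized log-odds
#' score of a random background word of length L by position-wise
#' convolution (cost O(L * grid * 4)), not 4^L enumeration. Scores are
#' log2-odds rounded to a grid of width `granularity`; the scanner uses the
#' same discretization, so window p-values are exact with respect to it.
#'
#' @param x a `pwm`.
#' @param granularity score grid width in log2-odds units.
#' @return object of class `score_distribution`: list with `units` (integer
#'   grid points), `mass`, `survival` (`P(score >= s)` per grid point),
#'   `granularity`, `L` and the integer score matrix `score_units`.
#' @export
score_distribution <- function(x, granularity = 0.01) {
  stopifnot(inherits(x, "pwm"), granularity > 0)
  su <- pwm_score_units(x, granularity)
  L <- ncol(su)
  ## mass over an integer grid; empty prefix has score 0 with mass 1,
  ## then one convolution per motif position
  mass <- 1
  cur <- 1L      # length of support so far
  run_lo <- 0L   # grid value of mass[1]
  q <- x$background
  for (j in seq_len(L)) {
    sj <- su[, j]
    new_lo <- run_lo + min(sj)
    new_hi <- run_lo + (cur - 1L) + max(sj)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      shift <- run_lo + sj[b] - new_lo   # index offset into `new`
      idx <- seq_len(cur)
      new[idx + shift] <- new[idx + shift] + mass[idx] * q[b]
    }
    mass <- new
    cur <- length(new)
    run_lo <- new_lo
  }
  total <- sum(mass)
  if (abs(total - 1) > 1e-9) {
    stop("score distribution mass deviates from 1: ", total, call. = FALSE)
  }
  units <- seq.int(run_lo, run_lo + cur - 1L)
  survival <- rev(cumsum(rev(mass)))
  structure(list(units = units, mass = mass, survival = survival,
                 granularity = granularity, L = L, score_units = su),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Exact PWM score distribution: L =", x$L,
      ", grid =", length(x$units), "points, granularity =",
      x$granularity, "log2 units\n")
  invisible(x)
}

## P(score >= s_units) under background
score_pvalue <- function(dist, s_units) {
  i <- s_units - dist$units[1L] + 1L
  n <- length(dist$units)
  out <- numeric(length(i))
  out[i <= 0L] <- 1
  out[i > n] <- 0
  ok <- i >= 1L & i <= n
  out[ok] <- dist$survival[i[ok]]
  out
}

#' Score threshold attaining a target p-value
#'
#' Returns the minimal grid score s such that `P(score >= s) <= alpha` under
#' the background. If `alpha` is below the minimal attainable nonzero
#' p-value, the maximal support score is returned with a warning.
#'
#' @param dist a `score_distribution`.
#' @param alpha target p-value in (0, 1\].
#' @return threshold score in log2-odds units (numeric), with the attained
#'   p-value as attribute `p_attained`.
#' @export
pvalue_cutoff <- function(dist, alpha) {
  stopifnot(inherits(dist, "score_distribution"), alpha > 0, alpha <= 1)
  ok <- which(dist$survival <= alpha)
  if (length(ok) == 0L) {
    warning("alpha ", alpha, " below minimal attainable p-value ",
            min(dist$survival[dist$survival > 0]),
            "; returning maximal score")
    i <- length(dist$units)
  } else {
    i <- ok[1L]
  }
  structure(dist$units[i] * dist$granularity,
            p_attained = dist$survival[i], units = dist$units[i])
}

#' Extract the scan region: last quartile of the CDS plus the 3'UTR
#'
#' CPEB-family proteins act near the 3' end of transcripts, so binding sites
#' are annotated over the last quartile of the CDS (codon-boundary aligned,
#' ceiling rule: the last `ceiling(cds_fraction * n_codons)` codons)
#' concatenated with the 3'UTR. Spans are recorded in 1-based transcript
#' coordinates (CDS position 1 = first CDS nucleotide).
#'
#' @param tx a [transcript_model()].
#' @param cds_fraction fraction of CDS codons (from the 3' end) to include.
#' @return object of class `scan_region`: list with `gene_id`, `region`
#'   (sequence), `cds_span`, `utr_span` (1-based inclusive transcript
#'   coordinates; `utr_span` is `NULL` when the UTR is empty) and `length`.
#' @export
extract_scan_region <- function(tx, cds_fraction = 0.25) {
  stopifnot(inherits(tx, "transcript_model"),
            cds_fraction > 0, cds_fraction <= 1)
  n_codons <- nchar(tx$cds) %/% 3L
  if (n_codons == 0L) stop("empty CDS", call. = FALSE)
  k <- as.integer(ceiling(cds_fraction * n_codons))
  cds_tail_start_nt <- (n_codons - k) * 3L + 1L
  cds_tail <- substring(tx$cds, cds_tail_start_nt, nchar(tx$cds))
  region <- paste0(cds_tail, tx$utr3)
  utr_span <- if (nzchar(tx$utr3)) {
    c(nchar(tx$cds) + 1L, nchar(tx$cds) + nchar(tx$utr3))
  } else NULL
  structure(list(gene_id = tx$gene_id, region = region,
                 cds_span = c(cds_tail_start_nt, nchar(tx$cds)),
                 utr_span = utr_span,
                 length = nchar(region)),
            class = "scan_region")
}

#' Scan a region for PWM matches with exact p-values
#'
#' Every start offset on the sense strand is scored with the discretized
#' log-odds score; offsets with `p < alpha_suboptimal` are reported, and
#' classed `significant` when `p < alpha_significant` (both strict, matching
#' the two-threshold convention p < 0.005 significant / p < 0.01 suboptimal).
#' Overlapping matches are each counted; windows containing N are skipped.
#'
#' @param region a `scan_region` (or a plain nucleotide string).
#' @param x a `pwm`.
#' @param dist matching `score_distribution`; computed if `NULL`.
#' @param alpha_significant p-value threshold for significant hits.
#' @param alpha_suboptimal p-value threshold for reported (suboptimal) hits;
#'   must be >= `alpha_significant`.
#' @param merge_overlaps if `TRUE`, runs of mutually overlapping hits are
#'   collapsed to the best-scoring hit per run (sensitivity analysis only;
#'   the default convention counts each position).
#' @return object of class `motif_hits`: list with `gene_id`, `hits` (a
#'   data.frame: `start` 1-based within region, `score` log2-odds, `p`,
#'   `class`), `region_length`, `alphas`, `background`.
#' @export
scan_pwm <- function(region, x, dist = NULL,
                     alpha_significant = 0.005, alpha_suboptimal = 0.01,
                     merge_overlaps = FALSE) {
  stopifnot(inherits(x, "pwm"),
            alpha_significant <= alpha_suboptimal,
            alpha_significant > 0, alpha_suboptimal < 1)
  gene_id <- NA_character_
  if (inherits(region, "scan_region")) {
    gene_id <- region$gene_id
    seq <- region$region
  } else {
    seq <- canonical_dna(region, "scan region")
  }
  if (is.null(dist)) dist <- score_distribution(x)
  L <- dist$L
  su <- dist$score_units
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), score = numeric(0),
                      p = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (n < L) {
    return(structure(list(gene_id = gene_id, hits = empty,
                          region_length = n,
                          alphas = c(significant = alpha_significant,
                                     suboptimal = alpha_suboptimal),
                          background = x$background),
                     class = "motif_hits"))
  }
  ## integer-coded sequence; windows with N (code NA) are skipped
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], NUCS)
  n_win <- n - L + 1L
  scores <- integer(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    b <- code[seq.int(j, j + n_win - 1L)]
    bad <- is.na(b)
    valid <- valid & !bad
    b[bad] <- 1L
    scores <- scores + su[cbind(b, j)]
  }
  p <- score_pvalue(dist, scores)
  keep <- valid & p < alpha_suboptimal
  hits <- data.frame(
    start = which(keep),
    score = scores[keep] * dist$granularity,
    p = p[keep],
    class = as.character(ifelse(p[keep] < alpha_significant,
                                "significant", "suboptimal")),
    stringsAsFactors = FALSE)
  if (merge_overlaps && nrow(hits) > 1L) {
    keep_rows <- logical(nrow(hits))
    i <- 1L
    while (i <= nrow(hits)) {
      j <- i
      while (j < nrow(hits) && hits$start[j + 1L] < hits$start[i] + L) {
        j <- j + 1L
      }
      block <- i:j
      keep_rows[block[which.max(hits$score[block])]] <- TRUE
      i <- j + 1L
    }
    hits <- hits[keep_rows, , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(gene_id = gene_id, hits = hits, region_length = n,
                 alphas = c(significant = alpha_significant,
                            suboptimal = alpha_suboptimal),
                 background = x$background),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat("Motif hits", if (!is.na(x$gene_id)) paste0("(", x$gene_id, ")"),
      ":", nrow(x$hits), "reported over", x$region_length, "nt (",
      sum(x$hits$class == "significant"), "significant )\n")
  invisible(x)
}

#' Binding-site density in sites per kilobase
#'
#' @param hits a `motif_hits` object, or an integer hit count.
#' @param region_length region length in nt (taken from `hits` if omitted).
#' @param class_filter count only hits of this class (`"significant"`,
#'   `"suboptimal"`, or `"all"`).
#' @return sites per kilobase.
#' @export
site_density <- function(hits, region_length = NULL,
                         class_filter = c("all", "significant", "suboptimal")) {
  class_filter <- match.arg(class_filter)
  if (inherits(hits, "motif_hits")) {
    if (is.null(region_length)) region_length <- hits$region_length
    n <- if (class_filter == "all") nrow(hits$hits)
         else sum(hits$hits$class == class_filter)
  } else {
    n <- hits
    if (is.null(region_length)) stop("region_length required", call. = FALSE)
  }
  if (region_length <= 0) stop("zero-length region", call. = FALSE)
  n / (region_length / 1000)
}

#' Codon composition of a motif word in each reading frame
#'
#' A U-rich binding element can decompose into rare or common codons
#' depending on the reading frame it lands in. For each frame offset (0, 1,
#' 2 nucleotides of the preceding codon before the word start), the word is
#' completed to codon boundaries using the flanking context and each codon is
#' classified with [codon_class()].
#'
#' @param motif_word nucleotide word (length >= 3).
#' @param left_flank nucleotides immediately 5' of the word (>= 2 nt).
#' @param right_flank nucleotides immediately 3' of the word (>= 2 nt).
#' @param weights a `weight_table`.
#' @return data.frame with one row per frame offset: `frame`, `codons`
#'   (comma-separated), `n_rare`, `n_common`, `n_intermediate`.
#' @export
frame_rarity_profile <- function(motif_word, left_flank, right_flank,
                                 weights) {
  motif_word <- canonical_dna(motif_word, "motif word")
  left_flank <- canonical_dna(left_flank, "left flank")
  right_flank <- canonical_dna(right_flank, "right flank")
  if (nchar(motif_word) < 3L) stop("motif word must be >= 3 nt", call. = FALSE)
  gc <- attr(weights, "genetic_code")
  out <- lapply(0:2, function(f) {
    ## f nt of the codon containing the word start precede the word
    if (nchar(left_flank) < f) {
      stop("left flank too short for frame ", f, call. = FALSE)
    }
    pre <- if (f > 0L) substring(left_flank, nchar(left_flank) - f + 1L,
                                 nchar(left_flank)) else ""
    core <- paste0(pre, motif_word)
    pad <- (3L - nchar(core) %% 3L) %% 3L
    if (nchar(right_flank) < pad) {
      stop("right flank too short for frame ", f, call. = FALSE)
    }
    full <- paste0(core, substring(right_flank, 1L, pad))
    codons <- split_codons(full)
    if (any(gc[codons] == "*")) {
      cls <- rep(NA_character_, length(codons))
      ok <- gc[codons] != "*"
      cls[ok] <- codon_class(codons[ok], weights)
      cls[!ok] <- "stop"
    } else {
      cls <- codon_class(codons, weights)
    }
    data.frame(frame = f, codons = paste(codons, collapse = ","),
               n_rare = sum(cls == "rare"),
               n_common = sum(cls == "common"),
               n_intermediate = sum(cls == "intermediate"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
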
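#' Generate a synthetic codon usage table
#'
#' Builds a valid 64-codon usage table in which every multi-codon synonymous
#' family has a max/min frequency ratio equal to `skew` (frequencies within
#' a family are linearly spaced between `skew` and 1, assigned to codons in
#' seeded random order, then scaled to per-thousand units). `skew = 1` is
#' the degenerate equal-usage case: every codon is then maximal-w ("common").
#'
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param skew ratio of max to min synonym frequency within each family
#'   (>= 1).
#' @return a [codon_usage_table()].
#' @export
synth_usage_table <- function(seed, skew = 4) {
  stopifnot(skew >= 1)
  with_seed(seed, {
    gc <- genetic_code()
    fams <- synonymous_families(gc)
    freq <- stats::setNames(numeric(length(gc)), names(gc))
    for (aa in names(fams)) {
      codons <- fams[[aa]]
      k <- length(codons)
      vals <- if (k == 1L) 1 else seq(skew, 1, length.out = k)
      scale <- stats::runif(1, 0.5, 2)   # family abundance varies
      freq[sample(codons, k)] <- vals * scale
    }
    freq <- freq / sum(freq) * 1000
    codon_usage_table(freq, unit = "per_thousand", organism = "synthetic")
  })
}

#' Render a codon usage table as Kazusa-format text
#'
#' @param table a `codon_usage_table`.
#' @param rna print codons over the RNA alphabet (U), as the Kazusa database
#'   does.
#' @return character vector of table lines, parseable by [read_kazusa()].
#' @export
format_kazusa <- function(table, rna = TRUE) {
  stopifnot(inherits(table, "codon_usage_table"))
  codons <- names(table$freq)
  shown <- if (rna) chartr("T", "U", codons) else codons
  counts <- if (!is.null(table$count)) table$count else round(table$freq * 100)
  fields <- sprintf("%s %4.1f(%6d)", shown, table$freq, as.integer(counts))
  ## 4 fields per line, Kazusa style
  apply(matrix(fields, ncol = 4L, byrow = TRUE), 1L, paste, collapse = "  ")
}

#' Synthesize a CDS with a target CAI
#'
#' Encodes a seeded random protein, then tunes the codon mix: starting from
#' the fully optimized sequence (all maximal-w synonyms, CAI = 1), codons
#' are greedily switched to their minimal-w synonyms, in seeded random
#' order, until the log-CAI reaches the target; a refinement sweep over
#' intermediate synonyms then minimizes the residual. Errors if the target
#' is outside the attainable range for the protein.
#'
#' @param n_codons number of sense codons.
#' @param target_cai desired CAI in (0, 1].
#' @param weights a `weight_table`.
#' @param seed integer seed.
#' @param tol acceptable |CAI - target|.
#' @return CDS string (no stop codon) whose [compute_cai()] is within `tol`
#'   of `target_cai`.
#' @export
synth_cds <- function(n_codons, target_cai, weights, seed, tol = 0.005) {
  stopifnot(n_codons >= 1, target_cai > 0, target_cai <= 1, tol > 0)
  gc <- attr(weights, "genetic_code")
  w <- unclass(weights)
  fams <- synonymous_families(gc)
  fams <- fams[names(fams) != "*"]
  aas <- names(fams)
  with_seed(seed, {
    protein <- sample(aas, n_codons, replace = TRUE)
    max_codon <- pick_synonym(weights, max)
    min_codon <- pick_synonym(weights, min)
    codons <- max_codon[protein]
    lw_min <- log(w[min_codon[protein]])       # per-position floor (<= 0)
    min_cai <- exp(mean(lw_min))
    target_log_sum <- n_codons * log(target_cai)
    if (target_cai < min_cai - tol) {
      stop("target CAI ", target_cai, " unattainable for this protein; ",
           "attainable range is [", formatC(min_cai, digits = 3, format = "f"),
           ", 1]", call. = FALSE)
    }
    ## greedy descent toward the target log-sum
    cur <- 0
    for (i in sample.int(n_codons)) {
      if (abs(cur + lw_min[i] - target_log_sum) < abs(cur - target_log_sum)) {
        codons[i] <- min_codon[protein[i]]
        cur <- cur + lw_min[i]
      }
    }
    ## refinement: per position, any synonym that shrinks the residual
    for (i in seq_len(n_codons)) {
      syn <- fams[[protein[i]]]
      lw_cur <- log(w[codons[i]])
      best <- codons[i]
      for (s in syn) {
        delta <- log(w[s]) - lw_cur
        if (abs(cur + delta - target_log_sum) < abs(cur - target_log_sum)) {
          best <- s
        }
      }
      if (best != codons[i]) {
        cur <- cur + log(w[best]) - lw_cur
        codons[i] <- best
      }
    }
    achieved <- exp(cur / n_codons)
    if (abs(achieved - target_cai) > tol) {
      stop("could not reach target CAI ", target_cai, " within tol ", tol,
           " (achieved ", formatC(achieved, digits = 4, format = "f"),
           "); attainable range is [",
           formatC(min_cai, digits = 3, format = "f"), ", 1]", call. = FALSE)
    }
    paste(codons, collapse = "")
  })
}

#' Generate a background sequence with planted motif occurrences
#'
#' Draws background nucleotides from the supplied composition and writes the
#' exact consensus word at each requested position. The background is
#' rejection-sampled so the consensus occurs nowhere else, keeping spurious
#' matches out of planted-recovery tests.
#'
#' @param length_or_template total sequence length, or a template string
#'   whose length is used.
#' @param consensus motif consensus word to plant.
#' @param positions 1-based start positions; must be non-overlapping and in
#'   bounds. May be empty (motif-free sequence).
#' @param seed integer seed.
#' @param background nucleotide composition (A, C, G, T) for non-motif
#'   positions.
#' @param max_tries rejection-sampling cap.
#' @return sequence string with attribute `planted` = `positions`.
#' @export
plant_motifs <- function(length_or_template, consensus, positions, seed,
                         background = rep(0.25, 4), max_tries = 100L) {
  n <- if (is.character(length_or_template)) {
    nchar(length_or_template)
  } else {
    as.integer(length_or_template)
  }
  consensus <- canonical_dna(consensus, "consensus")
  L <- nchar(consensus)
  positions <- as.integer(sort(positions))
  if (length(positions) > 0L) {
    if (positions[1L] < 1L || positions[length(positions)] + L - 1L > n) {
      stop("planted position out of bounds", call. = FALSE)
    }
    if (length(positions) > 1L &&
        any(diff(positions) < L)) {
      stop("planted positions overlap", call. = FALSE)
    }
  }
  stopifnot(length(background) == 4L, all(background >= 0),
            sum(background) > 0)
  background <- background / sum(background)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      chars <- sample(NUCS, n, replace = TRUE, prob = background)
      for (p in positions) {
        chars[p:(p + L - 1L)] <- strsplit(consensus, "")[[1L]]
      }
      seq <- paste(chars, collapse = "")
      found <- gregexpr(consensus, seq, fixed = TRUE)[[1L]]
      found <- found[found > 0L]
      if (setequal(found, positions) ||
          (length(positions) == 0L && length(found) == 0L)) {
        return(structure(seq, planted = positions))
      }
    }
    stop("could not avoid spurious consensus matches after ", max_tries,
         " tries; use a less permissive background", call. = FALSE)
  })
}

#' Generate an expression matrix with planted cell-type-enriched genes
#'
#' Background genes share a gene-level abundance across cell types
#' (log10-normal with sd `gene_sd`) plus independent per-cell-type noise
#' (sd `dispersion`), emulating housekeeping-dominated bulk profiles.
#' Planted genes are set to a low gene-level baseline (the `plant_quantile`
#' of the background distribution) and multiplied by `effect_size` in their
#' own cell type only. Setting `gene_sd = 0` makes all columns independent
#' noise, the null model for chance-call-rate calculations.
#'
#' @param n_genes total genes.
#' @param cell_types character vector of cell-type names (>= 2).
#' @param n_enriched_per_type planted genes per cell type (disjoint across
#'   types; total must not exceed `n_genes`).
#' @param effect_size fold change of a planted gene in its own cell type
#'   (> 1 for planted structure; 1 disables it).
#' @param dispersion per-cell-type log10 noise sd.
#' @param seed integer seed.
#' @param gene_sd gene-level log10 abundance sd shared across cell types.
#' @param mean_log10 mean log10 abundance.
#' @param plant_quantile background quantile at which planted genes' shared
#'   baseline sits.
#' @return list with `matrix` (genes x cell types, FPKM-like), and `truth`
#'   (list: `planted` named list cell type -> gene ids, `params`, `seed`).
#' @export
synth_expression <- function(n_genes, cell_types, n_enriched_per_type,
                             effect_size, dispersion = 0.1, seed = 1,
                             gene_sd = 1, mean_log10 = 1,
                             plant_quantile = 0.25) {
  stopifnot(length(cell_types) >= 2L, effect_size >= 1)
  k <- length(cell_types)
  if (n_enriched_per_type * k > n_genes) {
    stop("more planted genes than genes", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    base <- mean_log10 + gene_sd * stats::rnorm(n_genes)
    planted_ids <- split(genes[seq_len(n_enriched_per_type * k)],
                         rep(cell_types, each = n_enriched_per_type))
    planted_idx <- seq_len(n_enriched_per_type * k)
    if (effect_size > 1) {
      base[planted_idx] <- mean_log10 + gene_sd * stats::qnorm(plant_quantile)
    }
    lg <- matrix(base, n_genes, k) +
      dispersion * matrix(stats::rnorm(n_genes * k), n_genes, k)
    dimnames(lg) <- list(genes, cell_types)
    if (effect_size > 1) {
      for (t in cell_types) {
        lg[planted_ids[[t]], t] <- lg[planted_ids[[t]], t] + log10(effect_size)
      }
    }
    list(matrix = 10^lg,
         truth = list(planted = planted_ids,
                      params = list(n_genes = n_genes,
                                    cell_types = cell_types,
                                    n_enriched_per_type = n_enriched_per_type,
                                    effect_size = effect_size,
                                    dispersion = dispersion,
                                    gene_sd = gene_sd,
                                    mean_log10 = mean_log10,
                                    plant_quantile = plant_quantile),
                      seed = seed))
  })
}

#' Generate a qRT-PCR CT table from a transcription-block decay model
#'
#' CT values follow first-order decay: after `t_minutes` of transcription
#' block, a gene with decay constant k (per hour) retains `exp(-k t)` of its
#' mRNA, raising its CT by `k t / ln 2` cycles relative to the untreated
#' arm. Genotype effects multiply k. The reference (housekeeping) gene CT is
#' constant up to noise.
#'
#' @param decay_constants named numeric vector: gene -> k per hour (>= 0).
#' @param genotype_effects named numeric vector: genotype -> multiplier on k
#'   (e.g. `c(control = 1, rbp_depleted = 2)`).
#' @param t_minutes chase duration.
#' @param noise_sd Gaussian CT noise sd (cycles).
#' @param n_replicates replicates per gene x genotype x treatment.
#' @param seed integer seed.
#' @param baseline_ct untreated target CT baseline.
#' @param ref_ct reference-gene CT.
#' @return list with `table` (data.frame: `sample`, `genotype`, `treatment`,
#'   `timepoint_min`, `gene`, `target_ct`, `ref_ct`) and `truth` (expected
#'   remaining fraction per gene x genotype).
#' @export
synth_ct_table <- function(decay_constants, genotype_effects = c(control = 1),
                           t_minutes = 60, noise_sd = 0.1, n_replicates = 3,
                           seed = 1, baseline_ct = 24, ref_ct = 18) {
  stopifnot(all(decay_constants >= 0), all(genotype_effects >= 0),
            !is.null(names(decay_constants)), !is.null(names(genotype_effects)))
  t_hours <- t_minutes / 60
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (g in names(decay_constants)) {
      for (geno in names(genotype_effects)) {
        k <- decay_constants[[g]] * genotype_effects[[geno]]
        truth[[paste(g, geno, sep = ".")]] <- exp(-k * t_hours)
        for (trt in c("none", "ActD")) {
          shift <- if (trt == "ActD") k * t_hours / log(2) else 0
          for (r in seq_len(n_replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = paste(g, geno, trt, r, sep = "."),
              genotype = geno, treatment = trt,
              timepoint_min = if (trt == "ActD") t_minutes else 0,
              gene = g,
              target_ct = baseline_ct + shift + noise_sd * stats::rnorm(1),
              ref_ct = ref_ct + noise_sd * stats::rnorm(1),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(remaining = unlist(truth), t_minutes = t_minutes,
                      seed = seed))
  })
}

#' Generate a differential-expression table with a rare-codon-biased
#' regulated subset
#'
#' Samples `n_regulated` genes to be up-regulated by the RBP (decreased on
#' depletion: negative log2FC, small adjusted p). With `rare_bias = 0` the
#' regulated set is drawn uniformly; with `rare_bias = 1` it is drawn
#' entirely from the lowest-CAI decile; intermediate values mix the two
#' sampling weights linearly.
#'
#' @param cai_map named numeric vector: gene -> CAI (defines the gene
#'   universe).
#' @param n_regulated number of regulated (up_by_orb2) genes.
#' @param rare_bias in \[0, 1\]: strength of the low-CAI sampling bias.
#' @param seed integer seed.
#' @return list with `table` (data.frame: `gene`, `log2FC`, `padj`,
#'   `direction`) and `truth` (regulated gene ids, parameters).
#' @export
synth_de_table <- function(cai_map, n_regulated, rare_bias, seed) {
  stopifnot(!is.null(names(cai_map)), rare_bias >= 0, rare_bias <= 1)
  n <- length(cai_map)
  if (n_regulated > n) stop("n_regulated exceeds gene count", call. = FALSE)
  genes <- names(cai_map)
  low_decile <- cai_map <= stats::quantile(cai_map, 0.1, names = FALSE)
  if (rare_bias == 1 && n_regulated > sum(low_decile)) {
    stop("rare_bias = 1 requires n_regulated <= lowest-decile size (",
         sum(low_decile), ")", call. = FALSE)
  }
  weight <- (1 - rare_bias) + rare_bias * 10 * as.numeric(low_decile)
  with_seed(seed, {
    reg <- sample(genes, n_regulated, prob = weight)
    is_reg <- genes %in% reg
    log2fc <- ifelse(is_reg, -abs(stats::rnorm(n, 1.5, 0.5)),
                     stats::rnorm(n, 0, 0.2))
    padj <- ifelse(is_reg, stats::runif(n, 0, 0.01), stats::runif(n, 0.1, 1))
    tab <- data.frame(gene = genes, log2FC = log2fc, padj = padj,
                      stringsAsFactors = FALSE)
    tab <- classify_de(tab)
    list(table = tab,
         truth = list(regulated = reg, rare_bias = rare_bias, seed = seed))
  })
}
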
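#' Parse a Kazusa-format codon usage table
#'
#' The Kazusa codon usage database prints tables as repeated
#' `codon frequency-per-thousand (count)` fields, e.g. `UUU 21.1 (158341)`.
#' Both RNA (U) and DNA (T) codons are accepted; codons are stored over the
#' DNA alphabet.
#'
#' @param text character vector of Kazusa table text, or a single string.
#' @param organism optional organism label stored on the table.
#' @return an object of class `codon_usage_table`: a list with `freq`
#'   (named numeric, frequency per thousand for all 64 codons), `count`
#'   (named numeric raw counts, if present in the input), `unit`, `organism`
#'   and `genetic_code` (codon to amino-acid map, `*` = stop).
#' @export
#' @examples
#' txt <- "UUU 20.0 (200)  UUC 10.0 (100)"
#' # a full table needs all 64 codons; see synth_usage_table() for one
read_kazusa <- function(text, organism = NA_character_) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  ## fields look like: UUU 21.1(158341) or UUU 21.1 ( 158341 )
  pat <- "([ACGTUacgtu]{3})\\s+([0-9]+\\.?[0-9]*)\\s*(\\(\\s*([0-9]+)\\s*\\))?"
  m <- gregexpr(pat, text, perl = TRUE)
  hits <- regmatches(text, m)[[1L]]
  if (length(hits) == 0L) stop("no codon entries found", call. = FALSE)
  codons <- character(length(hits))
  freqs <- numeric(length(hits))
  counts <- rep(NA_real_, length(hits))
  for (i in seq_along(hits)) {
    g <- regmatches(hits[i], regexec(pat, hits[i], perl = TRUE))[[1L]]
    codons[i] <- canonical_dna(g[2L], "codon")
    freqs[i] <- as.numeric(g[3L])
    if (length(g) >= 5L && nzchar(g[5L])) counts[i] <- as.numeric(g[5L])
  }
  if (anyDuplicated(codons)) {
    stop("duplicated codon in usage table: ",
         codons[duplicated(codons)][1L], call. = FALSE)
  }
  gc <- genetic_code()
  missing <- setdiff(names(gc), codons)
  if (length(missing) > 0L) {
    stop("usage table is missing ", length(missing), " codon(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(codons, names(gc))
  if (length(extra) > 0L) {
    stop("unknown codon(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  freq <- stats::setNames(freqs, codons)[names(gc)]
  count <- stats::setNames(counts, codons)[names(gc)]
  codon_usage_table(freq,
                    count = if (all(is.na(count))) NULL else count,
                    unit = "per_thousand", organism = organism)
}

#' Construct a codon usage table
#'
#' @param freq named numeric vector of frequencies (or counts) for all 64
#'   codons, names over the DNA alphabet.
#' @param count optional named numeric vector of raw counts.
#' @param unit unit of `freq` (recorded, not interpreted; relative
#'   adaptiveness is scale-free within a synonymous family).
#' @param organism optional organism label.
#' @return an object of class `codon_usage_table`.
#' @export
codon_usage_table <- function(freq, count = NULL, unit = "per_thousand",
                              organism = NA_character_) {
  gc <- genetic_code()
  stopifnot(is.numeric(freq))
  if (is.null(names(freq)) || !setequal(names(freq), names(gc))) {
    stop("freq must be named with exactly the 64 codons", call. = FALSE)
  }
  freq <- freq[names(gc)]
  if (any(freq < 0)) stop("frequencies must be >= 0", call. = FALSE)
  structure(list(freq = freq, count = count, unit = unit,
                 organism = organism, genetic_code = gc),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table (", x$unit, ")",
      if (!is.na(x$organism)) paste0(" for ", x$organism), "\n", sep = "")
  cat("  64 codons; total frequency ", format(sum(x$freq)), "\n", sep = "")
  invisible(x)
}

## synonymous families: amino acid (or '*') -> codons
synonymous_families <- function(gc = genetic_code()) {
  split(names(gc), gc)
}

#' Relative adaptiveness weights from a codon usage table
#'
#' For each sense codon, the relative adaptiveness is
#' `w = f(codon) / max f(synonym)` within its synonymous family (Sharp & Li).
#' The most frequent synonym in each family gets `w = 1`; single-codon
#' families (ATG, TGG) get `w = 1`. Stop codons carry no weight.
#'
#' @param table a `codon_usage_table`.
#' @param zero_floor weight assigned to a codon with zero observed frequency
#'   in a family with nonzero maximum, keeping the geometric mean finite.
#' @return an object of class `weight_table`: a named numeric vector of
#'   weights over the 61 sense codons, with the genetic code attached.
#' @export
relative_adaptiveness <- function(table, zero_floor = 1e-3) {
  stopifnot(inherits(table, "codon_usage_table"))
  gc <- table$genetic_code
  fams <- synonymous_families(gc)
  fams <- fams[names(fams) != "*"]
  w <- stats::setNames(numeric(0), character(0))
  for (codons in fams) {
    f <- table$freq[codons]
    mx <- max(f)
    if (mx == 0) {
      stop("all-zero synonymous family: ", paste(codons, collapse = ","),
           call. = FALSE)
    }
    wi <- f / mx
    wi[wi == 0] <- zero_floor
    w <- c(w, wi)
  }
  sense <- names(gc)[gc != "*"]
  w <- w[sense]
  structure(w, class = "weight_table", genetic_code = gc)
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Relative adaptiveness weights for", length(x), "sense codons\n")
  cat("  w = 1 codons:", sum(unclass(x) == 1), "\n")
  invisible(x)
}

#' Codon adaptation index (CAI) of a coding sequence
#'
#' The CAI is the geometric mean of relative adaptiveness weights over all
#' scored codons. A terminal stop codon is excluded; ATG and TGG are scored
#' with `w = 1` (single-codon families); codons containing N are skipped and
#' tallied. An internal stop codon is an error.
#'
#' @param cds coding sequence, length divisible by 3.
#' @param weights a `weight_table` from [relative_adaptiveness()].
#' @param gene_id optional identifier carried on the result.
#' @return an object of class `cai_score`: list with `gene_id`, `cai`
#'   (in (0, 1]), `n_codons_scored` and `n_skipped`.
#' @export
compute_cai <- function(cds, weights, gene_id = NA_character_) {
  stopifnot(inherits(weights, "weight_table"))
  cds <- canonical_dna(cds, "CDS")
  codons <- split_codons(cds)
  if (length(codons) == 0L) stop("empty CDS", call. = FALSE)
  gc <- attr(weights, "genetic_code")
  stop_codons <- names(gc)[gc == "*"]
  ## terminal stop excluded from scoring
  if (codons[length(codons)] %in% stop_codons) {
    codons <- codons[-length(codons)]
  }
  internal_stop <- codons %in% stop_codons
  if (any(internal_stop)) {
    stop("internal stop codon ", codons[which(internal_stop)[1L]],
         " at codon ", which(internal_stop)[1L], call. = FALSE)
  }
  has_n <- grepl("N", codons, fixed = TRUE)
  scored <- codons[!has_n]
  if (length(scored) == 0L) stop("no scorable codons", call. = FALSE)
  w <- unclass(weights)[scored]
  cai <- exp(mean(log(w)))
  structure(list(gene_id = gene_id, cai = cai,
                 n_codons_scored = length(scored),
                 n_skipped = sum(has_n)),
            class = "cai_score")
}

#' @export
print.cai_score <- function(x, ...) {
  cat("CAI", if (!is.na(x$gene_id)) paste0("(", x$gene_id, ")"), "=",
      formatC(x$cai, digits = 3, format = "f"),
      "over", x$n_codons_scored, "codons",
      if (x$n_skipped > 0) paste0("(", x$n_skipped, " skipped)"), "\n")
  invisible(x)
}

#' CAI for a set of sequences
#'
#' @param records data.frame from [read_fasta()] (columns `id`, `sequence`).
#' @param weights a `weight_table`.
#' @return data.frame with columns `gene_id`, `cai`, `n_codons_scored`,
#'   `n_skipped`, in input order.
#' @export
cai_table <- function(records, weights) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    s <- compute_cai(records$sequence[i], weights, gene_id = records$id[i])
    data.frame(gene_id = s$gene_id, cai = s$cai,
               n_codons_scored = s$n_codons_scored,
               n_skipped = s$n_skipped, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify CAI values into rare / mid / common bins
#'
#' The defaults follow the definitions used for Drosophila brain transcripts:
#' rare-codon-enriched below 0.68, mid-range within \[0.68, 0.78\], and
#' common-codon-enriched above 0.78 (both boundaries belong to the mid bin).
#'
#' @param cai numeric vector of CAI values, or `cai_score` objects.
#' @param boundaries two strictly increasing cut points.
#' @return factor with levels `rare`, `mid`, `common`.
#' @export
#' @examples
#' cai_bin(c(0.585, 0.70, 0.985))
cai_bin <- function(cai, boundaries = c(0.68, 0.78)) {
  if (inherits(cai, "cai_score")) cai <- cai$cai
  stopifnot(length(boundaries) == 2L, boundaries[1L] < boundaries[2L])
  lab <- ifelse(cai < boundaries[1L], "rare",
                ifelse(cai > boundaries[2L], "common", "mid"))
  factor(lab, levels = c("rare", "mid", "common"))
}

#' Classify a codon as common, rare or intermediate within its family
#'
#' By default ("rank" mode) a codon is `common` iff it carries the maximal
#' weight in its synonymous family (ties allowed), `rare` iff it carries the
#' minimal weight in a multi-codon family, and `intermediate` otherwise;
#' single-codon families are `common`. In "threshold" mode the weight is
#' compared against numeric cutoffs instead.
#'
#' @param codon codon string (one or more codons).
#' @param weights a `weight_table`.
#' @param mode `"rank"` (default) or `"threshold"`.
#' @param thresholds for `"threshold"` mode: `c(rare_max, common_min)`; a
#'   codon is rare if `w <= rare_max`, common if `w >= common_min`.
#' @return character vector in `{common, rare, intermediate}`.
#' @export
codon_class <- function(codon, weights, mode = c("rank", "threshold"),
                        thresholds = c(0.5, 1.0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(weights, "weight_table"))
  codon <- canonical_dna(codon, "codon")
  if (any(nchar(codon) != 3L)) stop("codons must be 3 nt", call. = FALSE)
  gc <- attr(weights, "genetic_code")
  if (any(gc[codon] == "*")) {
    stop("stop codon has no class: ",
         codon[which(gc[codon] == "*")[1L]], call. = FALSE)
  }
  w <- unclass(weights)
  fams <- synonymous_families(gc)
  vapply(codon, function(cdn) {
    fam <- fams[[gc[[cdn]]]]
    wf <- w[fam]
    if (mode == "threshold") {
      if (w[[cdn]] >= thresholds[2L]) return("common")
      if (w[[cdn]] <= thresholds[1L]) return("rare")
      return("intermediate")
    }
    if (length(fam) == 1L || w[[cdn]] == max(wf)) return("common")
    if (w[[cdn]] == min(wf)) return("rare")
    "intermediate"
  }, character(1), USE.NAMES = FALSE)
}

#' Percentile of a CAI value within a genome-wide distribution
#'
#' Returns the percentage of genome CAI scores strictly below the query, so a
#' value in the rarest 2% of the coding genome has a percentile below 2.
#'
#' @param cai query CAI (numeric or `cai_score`).
#' @param genome_cai numeric vector of genome-wide CAI scores.
#' @return percentile in \[0, 100\].
#' @export
genome_cai_percentile <- function(cai, genome_cai) {
  if (inherits(cai, "cai_score")) cai <- cai$cai
  if (length(genome_cai) == 0L) stop("empty genome CAI set", call. = FALSE)
  100 * mean(genome_cai < cai)
}
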
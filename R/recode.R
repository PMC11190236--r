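#' Translate a coding sequence with the standard genetic code
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param strict error on internal stop codons (a terminal stop is always
#'   allowed and rendered as `*`).
#' @return amino-acid string; codons containing N translate to `X`.
#' @export
#' @examples
#' translate_cds("ATGTGGTAA")  # "MW*"
translate_cds <- function(cds, strict = FALSE) {
  if (nchar(cds) == 0L) return("")
  cds <- canonical_dna(cds, "CDS")
  codons <- split_codons(cds)
  gc <- genetic_code()
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X", gc[codons])
  if (strict) {
    internal <- aa[-length(aa)]
    if (any(internal == "*")) {
      stop("internal stop codon at codon ", which(internal == "*")[1L],
           call. = FALSE)
    }
  }
  paste(aa, collapse = "")
}

## per-amino-acid synonym chosen by an objective on w; lexicographic
## tie-break keeps the recoding deterministic
pick_synonym <- function(weights, which_fn) {
  gc <- attr(weights, "genetic_code")
  w <- unclass(weights)
  fams <- synonymous_families(gc)
  fams <- fams[names(fams) != "*"]
  vapply(fams, function(codons) {
    wf <- w[codons]
    best <- codons[wf == which_fn(wf)]
    sort(best)[1L]
  }, character(1))
}

recode_with <- function(cds, weights, which_fn) {
  cds <- canonical_dna(cds, "CDS")
  codons <- split_codons(cds)
  if (length(codons) == 0L) return("")
  gc <- attr(weights, "genetic_code")
  choice <- pick_synonym(weights, which_fn)
  out <- vapply(codons, function(cdn) {
    if (grepl("N", cdn, fixed = TRUE)) return(cdn)  # ambiguous: untouched
    aa <- gc[[cdn]]
    if (aa == "*") return(cdn)                      # stops kept verbatim
    choice[[aa]]
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = "")
}

#' Fully codon-optimize a coding sequence
#'
#' Replaces every sense codon with the most common synonym (maximal relative
#' adaptiveness; ties broken alphabetically), so the output has CAI = 1.0 and
#' the same translation. Stop codons and N-containing codons are untouched.
#'
#' @param cds coding sequence, length divisible by 3.
#' @param weights a `weight_table`.
#' @return recoded CDS.
#' @export
optimize_cds <- function(cds, weights) {
  recode_with(cds, weights, max)
}

#' Fully codon-de-optimize a coding sequence
#'
#' Replaces every sense codon with the least common synonym (minimal w), the
#' construction used for rare-codon-enriched reporters. Translation is
#' preserved; output CAI is the minimum attainable for the protein.
#'
#' @inheritParams optimize_cds
#' @return recoded CDS.
#' @export
deoptimize_cds <- function(cds, weights) {
  recode_with(cds, weights, min)
}

## codon indices (1-based) overlapping any window; windows are nucleotide
## 1-based inclusive spans, expanded outward to codon boundaries
codons_in_windows <- function(n_codons, windows) {
  if (is.null(windows) || NROW(windows) == 0L) return(integer(0))
  windows <- as.data.frame(windows)
  stopifnot(all(c("start", "end") %in% names(windows)))
  hit <- logical(n_codons)
  for (i in seq_len(nrow(windows))) {
    s <- windows$start[i]; e <- windows$end[i]
    if (s < 1L || e > n_codons * 3L || s > e) {
      stop("preserved window [", s, ", ", e, "] outside CDS (",
           n_codons * 3L, " nt)", call. = FALSE)
    }
    hit[((s - 1L) %/% 3L + 1L):((e - 1L) %/% 3L + 1L)] <- TRUE
  }
  which(hit)
}

#' Motif-preserving codon optimization
#'
#' Optimizes every codon except those overlapping a preserved window, which
#' keep the endogenous codon. This reproduces transgene designs in which a
#' sequence is codon-optimized everywhere except at RBP binding sites, whose
#' nucleotides are restored from the endogenous sequence. Windows are given
#' in 1-based nucleotide coordinates on the CDS and are expanded outward to
#' codon boundaries (a codon is preserved if any of its 3 nt overlaps a
#' window), so binding-site nucleotides survive intact.
#'
#' @param cds endogenous coding sequence.
#' @param weights a `weight_table`.
#' @param windows data.frame with `start` and `end` columns (1-based
#'   inclusive nucleotide spans within the CDS); `NULL` or 0 rows recodes
#'   everything (identical to [optimize_cds()]).
#' @return recoded CDS with endogenous codons inside the windows.
#' @export
motif_preserving_recode <- function(cds, weights, windows = NULL) {
  cds <- canonical_dna(cds, "CDS")
  codons <- split_codons(cds)
  opt <- split_codons(optimize_cds(cds, weights))
  keep <- codons_in_windows(length(codons), windows)
  opt[keep] <- codons[keep]
  paste(opt, collapse = "")
}

#' Codon-class composition of a CDS split at a breakpoint
#'
#' Summarizes the fraction of common and rare codons 5' and 3' of a codon
#' breakpoint, as used to describe reporters built from a 5' common-codon
#' block followed by a 3' rare-codon block.
#'
#' @param cds coding sequence.
#' @param weights a `weight_table`.
#' @param breakpoint codon index; segment 1 is codons `1..breakpoint`,
#'   segment 2 is the rest. Must satisfy `0 < breakpoint < n_codons`.
#' @return list with `breakpoint`, `classes` (per-codon character track;
#'   stop codons labelled `stop`), and a `summary` data.frame of per-segment
#'   fractions.
#' @export
composition_profile <- function(cds, weights, breakpoint) {
  cds <- canonical_dna(cds, "CDS")
  codons <- split_codons(cds)
  n <- length(codons)
  if (breakpoint <= 0L || breakpoint >= n) {
    stop("breakpoint must be inside the CDS (1 < b < ", n, ")", call. = FALSE)
  }
  gc <- attr(weights, "genetic_code")
  cls <- rep("stop", n)
  sense <- gc[codons] != "*" & !grepl("N", codons, fixed = TRUE)
  cls[sense] <- codon_class(codons[sense], weights)
  seg <- rep(c("5prime", "3prime"), c(breakpoint, n - breakpoint))
  summ <- do.call(rbind, lapply(c("5prime", "3prime"), function(s) {
    k <- cls[seg == s & cls != "stop"]
    data.frame(segment = s, n_codons = length(k),
               frac_common = mean(k == "common"),
               frac_rare = mean(k == "rare"),
               frac_intermediate = mean(k == "intermediate"),
               stringsAsFactors = FALSE)
  }))
  list(breakpoint = breakpoint, classes = cls, summary = summ)
}

#' Attach in-frame 5' and 3' tag sequences to a CDS
#'
#' Models transgene construction where the coding sequence is fused to an
#' N-terminal epitope tag and a C-terminal nanobody-antigen tag. Tags are
#' copied verbatim and must be in frame (length divisible by 3).
#'
#' @param cds coding sequence.
#' @param tag5,tag3 tag nucleotide sequences (may be empty).
#' @return concatenated transgene sequence with frame preserved.
#' @export
attach_tags <- function(cds, tag5 = "", tag3 = "") {
  cds <- canonical_dna(cds, "CDS")
  if (nzchar(tag5)) tag5 <- canonical_dna(tag5, "5' tag")
  if (nzchar(tag3)) tag3 <- canonical_dna(tag3, "3' tag")
  if (nchar(tag5) %% 3L != 0L) stop("5' tag is out of frame", call. = FALSE)
  if (nchar(tag3) %% 3L != 0L) stop("3' tag is out of frame", call. = FALSE)
  paste0(tag5, cds, tag3)
}
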
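#' Ordinary least-squares fit with Pearson correlation
#'
#' Simple linear regression of `y` on `x` with the Pearson correlation
#' coefficient and its two-sided p-value from the t distribution with n - 2
#' degrees of freedom (reported raw, as is conventional for per-group
#' regression panels; apply [stats::p.adjust()] across groups if needed).
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @param label optional group label carried on the result.
#' @return data.frame with one row: `label`, `n`, `slope`, `intercept`,
#'   `r`, `p` (NA when n < 3 or y has zero variance).
#' @export
ols_fit <- function(x, y, label = NA_character_) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need >= 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (stats::sd(y) == 0) {
    r <- 0; p <- NA_real_
  } else {
    r <- stats::cor(x, y)
    p <- if (n >= 3L) {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      if (!is.finite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
    } else NA_real_
  }
  data.frame(label = label, n = n, slope = slope, intercept = intercept,
             r = r, p = p, stringsAsFactors = FALSE)
}

#' Per-CAI-bin regression of binding-site density on CAI
#'
#' Splits gene records into rare / mid / common CAI bins and regresses
#' binding-site density (sites per kb over the scan region) on CAI within
#' each bin. Bins with fewer than 3 records are flagged (`insufficient`),
#' never silently dropped. A Benjamini-Hochberg adjusted p column is added
#' across the bins actually fitted.
#'
#' @param records data.frame with columns `cai` and `density`, and
#'   optionally `direction` (`up_by_orb2`, `down_by_orb2`, `unchanged`).
#' @param boundaries CAI bin boundaries, see [cai_bin()].
#' @param direction optional filter on the `direction` column.
#' @return data.frame with one row per bin: `bin`, `n`, `slope`,
#'   `intercept`, `r`, `p`, `p_adj`, `insufficient`.
#' @export
binned_regression <- function(records, boundaries = c(0.68, 0.78),
                              direction = NULL) {
  stopifnot(is.data.frame(records),
            all(c("cai", "density") %in% names(records)))
  if (!is.null(direction)) {
    if (!"direction" %in% names(records)) {
      stop("records have no 'direction' column", call. = FALSE)
    }
    records <- records[records$direction == direction, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records to regress", call. = FALSE)
  bin <- cai_bin(records$cai, boundaries)
  out <- lapply(levels(bin), function(b) {
    rec <- records[bin == b, , drop = FALSE]
    if (nrow(rec) < 3L || length(unique(rec$cai)) < 2L) {
      return(data.frame(bin = b, n = nrow(rec), slope = NA_real_,
                        intercept = NA_real_, r = NA_real_, p = NA_real_,
                        insufficient = TRUE, stringsAsFactors = FALSE))
    }
    fit <- ols_fit(rec$cai, rec$density, label = b)
    data.frame(bin = b, n = fit$n, slope = fit$slope,
               intercept = fit$intercept, r = fit$r, p = fit$p,
               insufficient = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[c("bin", "n", "slope", "intercept", "r", "p", "p_adj", "insufficient")]
}

#' Regression of annotated binding-site count on CAI across reporters
#'
#' For a panel of codon-altered reporter transgenes, regresses the number of
#' annotated binding sites on CAI; an inverse relationship indicates that
#' rare-codon-enriched designs harbor more binding elements.
#'
#' @param reporters data.frame with columns `cai` and `site_count` (and
#'   optionally `gene_id`).
#' @return one-row data.frame as from [ols_fit()].
#' @export
reporter_regression <- function(reporters) {
  stopifnot(is.data.frame(reporters),
            all(c("cai", "site_count") %in% names(reporters)))
  if (nrow(reporters) < 3L) stop("need >= 3 reporters", call. = FALSE)
  ols_fit(reporters$cai, reporters$site_count, label = "reporters")
}

#' Candidate filter cascade for RBP-regulated rare-codon transcripts
#'
#' Successive filters over differentially expressed genes, in fixed order:
#'
#' 1. genes up-regulated by the RBP (i.e. decreased upon its depletion),
#' 2. CAI strictly below `cai_max`,
#' 3. annotated binding-site density strictly above `min_density` sites/kb
#'    (density over the scan region: last CDS quartile + 3'UTR),
#' 4. membership in an externally supplied set of genes with direct binding
#'    evidence,
#' 5. membership in an externally supplied set of genes with a known role in
#'    the target tissue.
#'
#' Stage order is fixed: the final set is order-independent but the
#' intermediate counts are not. Genes in the DE table missing from `cai` or
#' `density` are reported in the `skipped` attribute, never silently
#' dropped.
#'
#' @param de_table data.frame with columns `gene` and `direction`
#'   (`up_by_orb2` / `down_by_orb2` / `unchanged`), e.g. derived from a
#'   differential-expression result table.
#' @param cai named numeric vector: gene -> CAI.
#' @param density named numeric vector: gene -> sites per kb.
#' @param binding_genes character vector: genes with direct binding
#'   evidence.
#' @param brain_genes character vector: genes with a known role in the
#'   tissue of interest.
#' @param cai_max CAI cutoff (strict `<`), default 0.68.
#' @param min_density density cutoff (strict `>`), default 9 sites/kb.
#' @return object of class `cascade_report`: data.frame with columns
#'   `stage`, `parameter`, `n`; surviving gene ids per stage in attribute
#'   `gene_sets` (a named list), skipped genes in attribute `skipped`.
#' @export
candidate_cascade <- function(de_table, cai, density, binding_genes,
                              brain_genes, cai_max = 0.68, min_density = 9) {
  stopifnot(is.data.frame(de_table),
            all(c("gene", "direction") %in% names(de_table)))
  up <- de_table$gene[de_table$direction == "up_by_orb2"]
  skipped <- setdiff(up, intersect(names(cai), names(density)))
  up_known <- setdiff(up, skipped)
  stages <- list(
    up_by_orb2 = up_known,
    cai = up_known[cai[up_known] < cai_max],
    density = NULL, binding = NULL, brain = NULL)
  stages$density <- stages$cai[density[stages$cai] > min_density]
  stages$binding <- intersect(stages$density, binding_genes)
  stages$brain <- intersect(stages$binding, brain_genes)
  report <- data.frame(
    stage = c("up_by_orb2", "cai_below", "density_above",
              "binding_evidence", "brain_role"),
    parameter = c(NA, cai_max, min_density, NA, NA),
    n = vapply(stages, length, integer(1)),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  structure(report, class = c("cascade_report", "data.frame"),
            gene_sets = stages, skipped = skipped)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Candidate filter cascade:\n")
  print.data.frame(x)
  sk <- attr(x, "skipped")
  if (length(sk) > 0L) {
    cat("  skipped (no CAI/density):", length(sk), "gene(s)\n")
  }
  invisible(x)
}

#' Classify differential-expression results into regulation directions
#'
#' Genes significantly decreased upon RBP depletion are classed as
#' up-regulated by the RBP, significantly increased as down-regulated, and
#' the rest unchanged.
#'
#' @param de data.frame with columns `gene`, `log2FC` (depletion vs control)
#'   and `padj`.
#' @param alpha adjusted-p significance cutoff.
#' @return the input with a `direction` column added.
#' @export
classify_de <- function(de, alpha = 0.05) {
  stopifnot(all(c("gene", "log2FC", "padj") %in% names(de)))
  sig <- !is.na(de$padj) & de$padj < alpha
  de$direction <- ifelse(sig & de$log2FC < 0, "up_by_orb2",
                         ifelse(sig & de$log2FC > 0, "down_by_orb2",
                                "unchanged"))
  de
}
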
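#' Convert FPKM to TPM
#'
#' `TPM_i = (FPKM_i / sum(FPKM)) * 10^6`, so every column sums to one
#' million. (Gene length is already accounted for in FPKM, so the per-column
#' rescaling is all that is required.)
#'
#' @param fpkm numeric vector of FPKM values for one sample (>= 0, not all
#'   zero).
#' @return TPM vector summing to 1e6.
#' @export
#' @examples
#' fpkm_to_tpm(c(1, 1, 2))  # 250000 250000 500000
fpkm_to_tpm <- function(fpkm) {
  stopifnot(is.numeric(fpkm))
  if (any(fpkm < 0)) stop("FPKM values must be >= 0", call. = FALSE)
  s <- sum(fpkm)
  if (s == 0) stop("all-zero FPKM column", call. = FALSE)
  fpkm / s * 1e6
}

## percentile rank (0-100] per column, average ranks for ties
rank_pct <- function(x) {
  100 * rank(x, ties.method = "average") / length(x)
}

#' Call genes with cell-type-specific expression enrichment
#'
#' A gene is called enriched in the target cell type when it is in the top
#' `top_q` fraction of genes expressed in the target (percentile rank >=
#' 100 * (1 - top_q), inclusive) and in the bottom `other_q` fraction
#' (percentile rank <= 100 * other_q, inclusive) in every other cell type in
#' the matrix. Ranks are computed on TPM with average ties; genes with zero
#' abundance in all cell types are dropped before ranking ("genes
#' expressed"). The call is rank-based and hence invariant to monotone
#' rescaling of any column.
#'
#' @param mat numeric matrix, genes x cell types, with row and column names.
#' @param target target cell-type column name.
#' @param top_q top quantile in the target (default 0.25).
#' @param other_q bottom quantile in every other cell type (default 0.60).
#' @param unit `"TPM"` or `"FPKM"`; FPKM columns are converted to TPM first.
#' @param dataset optional dataset label recorded on the result.
#' @return object of class `enriched_set`: list with `cell_type`, `genes`,
#'   `datasets`, `params`, `n_genes_ranked`.
#' @export
call_enriched <- function(mat, target, top_q = 0.25, other_q = 0.60,
                          unit = c("TPM", "FPKM"), dataset = NA_character_) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            top_q > 0, top_q < 1, other_q > 0, other_q < 1)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (ncol(mat) < 2L) stop("need >= 2 cell types", call. = FALSE)
  if (!target %in% colnames(mat)) {
    stop("target cell type '", target, "' not in matrix", call. = FALSE)
  }
  if (any(mat < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (unit == "FPKM") mat <- apply(mat, 2L, fpkm_to_tpm)
  expressed <- rowSums(mat) > 0
  mat <- mat[expressed, , drop = FALSE]
  pct <- apply(mat, 2L, rank_pct)
  others <- setdiff(colnames(mat), target)
  ok_target <- pct[, target] >= 100 * (1 - top_q)
  ok_others <- rowSums(pct[, others, drop = FALSE] <= 100 * other_q) ==
    length(others)
  structure(list(cell_type = target,
                 genes = rownames(mat)[ok_target & ok_others],
                 datasets = dataset,
                 params = c(top_q = top_q, other_q = other_q),
                 n_genes_ranked = nrow(mat)),
            class = "enriched_set")
}

#' @export
print.enriched_set <- function(x, ...) {
  cat("Enriched gene set:", length(x$genes), "genes in", x$cell_type,
      "( top", x$params["top_q"], ", other", x$params["other_q"], ")\n")
  invisible(x)
}

#' Intersect enrichment calls from multiple datasets
#'
#' A gene must be called enriched in the same cell type in every contributing
#' dataset (e.g. in both of two independent RNA-seq datasets).
#'
#' @param sets list of `enriched_set` objects for the same cell type.
#' @return an `enriched_set` holding the intersection, with all dataset
#'   labels recorded.
#' @export
intersect_enriched <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "enriched_set")))
  types <- unique(vapply(sets, `[[`, character(1), "cell_type"))
  if (length(types) != 1L) {
    stop("cell types differ across sets: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
  genes <- Reduce(intersect, lapply(sets, `[[`, "genes"))
  structure(list(cell_type = types,
                 genes = genes,
                 datasets = unlist(lapply(sets, `[[`, "datasets")),
                 params = sets[[1L]]$params,
                 n_genes_ranked = min(vapply(sets, `[[`, numeric(1),
                                             "n_genes_ranked"))),
            class = "enriched_set")
}

#' Compare two CAI distributions (Kolmogorov-Smirnov + t test)
#'
#' Two-sample KS test (D = maximal ECDF gap) as the primary comparison, with
#' a two-tailed Welch t test as a secondary location comparison.
#'
#' @param group_a,group_b numeric vectors of CAI values (each nonempty).
#' @param labels group labels for the report.
#' @return data.frame with one row: group sizes, `ks_D`, `ks_p`, `t_stat`,
#'   `t_p`, `mean_a`, `mean_b`.
#' @export
compare_cai_distributions <- function(group_a, group_b,
                                      labels = c("A", "B")) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(group_a, group_b))
  tt <- if (length(group_a) >= 2L && length(group_b) >= 2L &&
            (stats::sd(group_a) > 0 || stats::sd(group_b) > 0)) {
    stats::t.test(group_a, group_b)
  } else NULL
  data.frame(label_a = labels[1L], label_b = labels[2L],
             n_a = length(group_a), n_b = length(group_b),
             ks_D = unname(ks$statistic), ks_p = ks$p.value,
             t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
             t_p = if (is.null(tt)) NA_real_ else tt$p.value,
             mean_a = mean(group_a), mean_b = mean(group_b),
             stringsAsFactors = FALSE)
}
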
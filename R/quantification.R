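#' Relative mRNA abundance by the 2^dCT method
#'
#' Normalizes a target gene's qRT-PCR cycle threshold to a housekeeping
#' reference (e.g. RP49): `2^(CT_ref - CT_target)`. The sign convention
#' makes the value increase with target abundance: a target amplifying 1
#' cycle earlier than the reference doubles the relative level, and a
#' 10-fold dilution series produces dCT steps of ~3.32 cycles.
#'
#' @param target_ct numeric vector of target-gene CT values.
#' @param ref_ct matching reference-gene CT values (recycled if length 1).
#' @return relative abundance vector.
#' @export
#' @examples
#' relative_level(20, 20)  # 1
#' relative_level(19, 20)  # 2
relative_level <- function(target_ct, ref_ct) {
  if (length(ref_ct) == 1L) ref_ct <- rep(ref_ct, length(target_ct))
  if (length(target_ct) == 1L) target_ct <- rep(target_ct, length(ref_ct))
  stopifnot(length(target_ct) == length(ref_ct))
  if (any(!is.finite(target_ct)) || any(!is.finite(ref_ct))) {
    stop("CT values must be finite (missing reference?)", call. = FALSE)
  }
  2^(ref_ct - target_ct)
}

#' Remaining-mRNA fraction after a transcription-block chase
#'
#' After transcription is blocked (e.g. with actinomycin D) for a fixed
#' time, the ratio of treated to untreated relative mRNA level per replicate
#' measures mRNA stability; for first-order decay with rate k the noiseless
#' ratio is `exp(-k t)`.
#'
#' @param treated,untreated numeric vectors of relative levels, paired by
#'   replicate (equal length).
#' @return list with `ratios` (per-replicate remaining fractions), `mean`
#'   and `sem`.
#' @export
decay_ratio <- function(treated, untreated) {
  if (length(treated) != length(untreated)) {
    stop("treated and untreated replicates are unpaired (",
         length(treated), " vs ", length(untreated), ")", call. = FALSE)
  }
  if (any(untreated <= 0)) stop("untreated levels must be > 0", call. = FALSE)
  ratios <- treated / untreated
  list(ratios = ratios, mean = mean(ratios),
       sem = if (length(ratios) > 1L) {
         stats::sd(ratios) / sqrt(length(ratios))
       } else NA_real_)
}

#' Compare remaining-mRNA fractions between two groups
#'
#' Two-tailed t test on remaining fractions (e.g. control vs RBP-depleted
#' genotype). Welch's unequal-variance test is the default; set
#' `pooled = TRUE` for the classical equal-variance test.
#'
#' @param group_a,group_b numeric vectors of remaining fractions, each with
#'   n >= 2.
#' @param pooled use pooled-variance (Student) instead of Welch.
#' @return data.frame with one row: `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `t_stat`, `p`, `direction` (sign of mean_a - mean_b).
#' @export
compare_decay <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    ## degenerate: no within-group variance
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(data.frame(n_a = length(group_a), n_b = length(group_b),
                      mean_a = mean(group_a), mean_b = mean(group_b),
                      t_stat = if (same) 0 else
                        sign(mean(group_a) - mean(group_b)) * Inf,
                      p = if (same) 1 else 0,
                      direction = sign(mean(group_a) - mean(group_b)),
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = pooled)
  data.frame(n_a = length(group_a), n_b = length(group_b),
             mean_a = mean(group_a), mean_b = mean(group_b),
             t_stat = unname(tt$statistic), p = tt$p.value,
             direction = sign(mean(group_a) - mean(group_b)),
             stringsAsFactors = FALSE)
}

#' Normalize measurements to the mean of on-slide controls
#'
#' Each value is divided by the mean of the control measurements acquired
#' alongside it (e.g. all control brains on the same slide).
#'
#' @param values numeric vector of measurements.
#' @param control_values numeric vector of control measurements (nonempty,
#'   positive mean).
#' @return normalized vector.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0L) stop("no control values", call. = FALSE)
  m <- mean(control_values)
  if (m <= 0) stop("control mean must be > 0", call. = FALSE)
  values / m
}

#' Protein output per mRNA, as a percentage
#'
#' `100 * protein / mRNA` on control-normalized mean abundances; 100% means
#' protein output proportional to mRNA input relative to the normalizer.
#' (Protein and mRNA means may come from unpaired samples.)
#'
#' @param mean_protein_norm control-normalized mean protein abundance.
#' @param mean_mrna_norm control-normalized mean mRNA abundance (> 0).
#' @return percentage.
#' @export
protein_per_mrna <- function(mean_protein_norm, mean_mrna_norm) {
  if (mean_mrna_norm <= 0) stop("mRNA mean must be > 0", call. = FALSE)
  100 * mean_protein_norm / mean_mrna_norm
}

#' Fit a first-order decay rate from remaining fractions (optional extra)
#'
#' Converts remaining fractions at a single chase time into a decay constant
#' and half-life under first-order kinetics. Single-timepoint chases are the
#' primary design; this helper extrapolates beyond it and is marked as such.
#'
#' @param remaining remaining fraction(s) in (0, 1].
#' @param t_hours chase duration in hours.
#' @return data.frame with `k_per_hour` and `half_life_hours`.
#' @export
decay_rate_fit <- function(remaining, t_hours) {
  stopifnot(t_hours > 0)
  if (any(remaining <= 0) || any(remaining > 1)) {
    stop("remaining fractions must be in (0, 1]", call. = FALSE)
  }
  k <- -log(remaining) / t_hours
  data.frame(k_per_hour = k,
             half_life_hours = ifelse(k > 0, log(2) / k, Inf))
}
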
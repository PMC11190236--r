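---
title: "Codon usage and RBP binding-site convergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage and RBP binding-site convergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecode)
```

# The scientific problem

Synonymous codons are used at very different genome-wide frequencies, and
mRNAs enriched in rarely used ("nonoptimal") codons are generally less
stable and less efficiently translated. In some tissues — notably neural
tissue — this logic inverts: differentiated neurons can stabilize and
express rare-codon-enriched mRNAs that their progenitors cannot. One
mechanism is an RNA-binding protein (RBP) of the CPEB family that binds a
U-rich element near the 3' end of transcripts and stabilizes its targets.
Because U-rich elements decompose, in frame, into codons that are often
rare, rare codons and RBP binding sites can physically converge on the same
transcripts.

`rarecode` implements the quantitative pipeline needed to study this
convergence: codon adaptation index (CAI) scoring and binning, PWM motif
scanning of the 3' end of transcripts with exact p-values, synonymous
recoding for transgene design, cell-type expression enrichment calling,
CAI-binned binding-site regressions with a candidate filter cascade, and
qRT-PCR decay quantification — plus seeded generators that plant known
structure into synthetic inputs so every stage is testable end to end
without downloads.

# Codon adaptation index

For a codon usage table (Kazusa-format text is parsed by `read_kazusa()`),
the relative adaptiveness of a codon is

$$w_c = \frac{f_c}{\max_{c' \in \mathrm{syn}(c)} f_{c'}},$$

so the most frequent synonym in each family has $w = 1$ (Sharp & Li). The
CAI of a coding sequence is the geometric mean of $w$ over scored codons:

$$\mathrm{CAI} = \Big(\prod_{i=1}^{n} w_{c_i}\Big)^{1/n}.$$

Conventions (chosen for compatibility with the widely used CAIcal tool):

* the terminal stop codon is excluded; internal stops are an error;
* ATG and TGG (single-codon families) are scored with $w = 1$;
* codons containing N are skipped and tallied, not scored;
* a zero-frequency codon in an otherwise used family receives a small
  floor weight (default $10^{-3}$) so the geometric mean stays finite.
  Real genome tables have no zero sense codons; this only matters for
  synthetic tables.

CAI bins follow the convention used for Drosophila brain transcripts:
*rare* below 0.68, *mid* in [0.68, 0.78] (both boundaries inclusive,
since the defining phrases are "below 0.68" and "greater than 0.78"),
*common* above 0.78. `codon_class()` labels individual codons by rank
within their family (max-w = common, min-w = rare, otherwise intermediate);
no universal numeric threshold exists for this, so a threshold mode is
provided as an alternative.

```{r cai}
usage <- synth_usage_table(seed = 1, skew = 4)
weights <- relative_adaptiveness(usage)
cds <- synth_cds(300, target_cai = 0.62, weights, seed = 2)
compute_cai(cds, weights)
cai_bin(compute_cai(cds, weights)$cai)
```

# Exact PWM scanning of the 3' scan region

CPEB-family proteins act near the 3' end of transcripts, and RBPs once
thought to bind only 3'UTRs also act through the coding sequence, so the
scan region is the **last quartile of the CDS plus the 3'UTR**
(`extract_scan_region()`). The quartile is codon-boundary aligned with a
ceiling rule (the last $\lceil 0.25\,n_{codons} \rceil$ codons), which
keeps reading-frame semantics intact for `frame_rarity_profile()`.

Windows are scored with the log2-odds of the PWM against a background
distribution. To attach exact p-values, `score_distribution()` discretizes
per-position scores on a grid (default 0.01 log2 units) and convolves the
four-outcome distributions position by position — cost
$O(L \cdot \mathrm{grid} \cdot 4)$ rather than $4^L$ enumeration. The
scanner uses the *same* discretization, so a window's p-value is exactly
the survival function of the distribution at its score; the test suite
verifies bit-level agreement with full $4^L$ enumeration for $L \le 6$.

Two strict thresholds classify reported matches: $p < 0.005$ significant,
$p < 0.01$ suboptimal. Numerical and convention choices:

* background defaults to uniform (0.25 each) and is recorded on every hit
  set so results are auditable; a region-composition background can be
  supplied;
* overlapping matches are each counted (per-position convention);
  `merge_overlaps = TRUE` collapses overlapping runs for sensitivity
  analysis;
* scanning is sense-strand only (targets are mRNAs);
* windows containing N are skipped; regions shorter than the motif yield
  an empty hit set, not an error;
* halving the grid granularity must not change any hit class (checked in
  the suite);
* zero motif probabilities are rejected at scoring time — load matrices
  with a pseudocount.

Binding-site density is hits per kilobase of the region actually scanned
(`site_density()`), matching the convention that counts are normalized to
the length of sequence queried.

```{r scan}
p <- read_pwm(system.file("extdata", "u_rich_hexamer_synthetic.pwm",
                          package = "rarecode"))
d <- score_distribution(p)
utr <- plant_motifs(200, pwm_consensus(p), c(20, 120), seed = 3)
tx <- transcript_model("demo", cds, utr)
hits <- scan_pwm(extract_scan_region(tx), p, d)
hits$hits
site_density(hits, class_filter = "significant")
```

# Synonymous recoding

`optimize_cds()` / `deoptimize_cds()` replace every sense codon with the
maximal- / minimal-w synonym (lexicographic tie-break, so recoding is
deterministic); `motif_preserving_recode()` optimizes everywhere except
user-specified windows, which keep the endogenous codons — the design used
for transgenes that are codon-optimized except at RBP binding sites.
Windows are nucleotide spans expanded outward to codon boundaries, so
binding-site nucleotides survive intact. Published constructs restored
"most" sites without listing which were dropped, so the operation takes
explicit window lists rather than inferring them. Protein preservation
under all modes is property-tested over random CDSs.

# Expression enrichment calling

`fpkm_to_tpm()` rescales each column to sum to $10^6$ (the standard TPM
definition; gene length is already in FPKM). A gene is called enriched in
a target cell type when its percentile rank is at or above the top-25%
boundary in the target **and** at or below the bottom-60% boundary in
*every* other column supplied (both boundaries inclusive; average ranks
for ties; all-zero genes dropped before ranking, since only expressed
genes are ranked). Calls from independent datasets are intersected with
`intersect_enriched()`. Because the call is rank-based it is invariant
under monotone rescaling of any column, and relaxing either quantile can
only add genes — both properties are tested. CAI distributions between
cell types are compared with a two-sample Kolmogorov–Smirnov test plus a
secondary Welch t test.

# Convergence statistics and the candidate cascade

`ols_fit()` is simple least squares with the Pearson r and its two-sided
p from the t distribution with $n-2$ df; p-values are reported raw (as in
per-group regression panels), with a BH-adjusted column added across bins
in `binned_regression()` for transparency. `binned_regression()` splits
genes by CAI bin and regresses binding-site density on CAI per bin; bins
with fewer than 3 usable records are flagged, never dropped. The expected
signature for RBP-stabilized rare-codon transcripts is an inverse
rare-bin slope: more sites at lower CAI.

`candidate_cascade()` applies, in fixed order: up-regulated by the RBP →
CAI strictly `< 0.68` → density strictly `> 9` sites/kb (over the scan
region, not whole-transcript length) → membership in a supplied
direct-binding evidence set → membership in a supplied known-tissue-role
set. The inequalities are strict because the defining phrases are "less
than" and "more than"; the stage order is fixed because intermediate
counts depend on it even though the final set does not. External evidence
sets are user-supplied gene lists: curation against published datasets is
deliberately not computed here.

# Decay and qRT-PCR quantification

Relative abundance uses $2^{\Delta CT}$ with $\Delta CT = CT_{ref} -
CT_{target}$; this sign convention makes a 10-fold dilution series step by
$\log_2 10 \approx 3.32$ cycles in the physically sensible direction.
After a transcription-block (actinomycin D) chase of duration $t$, the
treated/untreated ratio per replicate estimates the remaining fraction;
noiseless first-order decay gives exactly $e^{-kt}$, which the suite
verifies through the CT layer. Genotype comparisons use Welch's two-tailed
t test by default (pooled variance by flag), with a closed-form degenerate
path (zero variance in both groups) so identical groups give $t = 0$,
$p = 1$. `decay_rate_fit()` converts single-timepoint remaining fractions
into $k$ and half-life under first-order kinetics; single-timepoint
designs are the primary use, and the fit is an extrapolation beyond them.
The label in `protein_per_mrna()` follows the computation (protein ÷
mRNA, as a percentage) rather than the ambiguous "mRNA/protein" phrasing
sometimes attached to it.

# The synthetic-data generators

Every generator is a pure function of (parameters, seed) — byte-identical
reruns — and returns a truth object sufficient to recompute the expected
output of the stage it feeds.

* `synth_usage_table(skew)`: every multi-codon family has a max/min
  frequency ratio of exactly `skew`; `skew = 1` is the degenerate
  equal-usage table.
* `synth_cds(n, target, tol)`: greedy switching from maximal- to
  minimal-w synonyms in seeded random order, then a refinement sweep over
  intermediate synonyms; reaches a 0.005 CAI tolerance at n = 500, and
  errors (stating the attainable range) if the target is below the
  protein's floor.
* `plant_motifs()`: exact consensus at requested positions; background
  drawn from the PWM background composition and rejection-sampled so the
  consensus occurs nowhere else. Near-consensus words still occur at the
  calibrated chance rate — planted recovery is guaranteed, exact hit
  *counts* are not.
* `synth_expression()`: background genes share a gene-level log10
  abundance (sd `gene_sd = 1`) plus per-cell-type noise (`dispersion =
  0.1`); planted genes sit at the 25th-percentile baseline and are
  multiplied by `effect_size` in their own cell type. The shared baseline
  emulates the strong between-cell-type correlation of real expression
  profiles and is what makes exact planted recovery attainable at
  `effect_size = 100`; setting `gene_sd = 0` gives independent columns,
  the null model under which the chance call rate is
  $q_{top} \cdot q_{other}^{k-1}$.
* `synth_ct_table()`: CT values shift by $kt/\ln 2$ cycles under
  treatment, with Gaussian CT noise; the reference gene is constant.
* `synth_de_table(rare_bias)`: regulated genes are sampled uniformly
  (`rare_bias = 0`), entirely from the lowest-CAI decile (`rare_bias =
  1`), or a linear mix.

## What the generators do and do not emulate

The generators reproduce the *statistical structure* each stage assumes:
target CAI, planted motif positions, rank-separable enrichment,
first-order decay, and a low-CAI-biased regulated set. They do not emulate
UTR length distributions, sequencing depth effects, isoform structure,
count overdispersion (expression is log-normal, not negative binomial,
because the pipeline consumes FPKM/TPM, not counts), or correlated
measurement error. Passing tests therefore demonstrate correctness of the
computations under controlled conditions, not biological validity on any
particular real dataset.

# Problem sizes and verification

The shipped test-suite and acceptance-script runs use: 500-codon synthetic
CDSs for CAI targeting; 20 random PWMs of length 3–6 checked against full
$4^L$ enumeration; 1000-gene × 3-cell-type expression matrices with 50
planted genes per type; 30-gene end-to-end cascades; 1000 null
simulations for the decay-test type-I error (n = 5 per group, nominal
$\alpha = 0.05$, acceptance band [0.03, 0.07]); and 500–1000 random CDSs
for protein-preservation checks. These sizes give stable pass/fail
behavior at desk scale while exercising every code path.

# Known limitations

* Reproduction of published per-gene values (reference CAIs, per-transgene
  hit counts, published enriched-gene counts) requires the corresponding
  reference inputs — genome CDS FASTA, the experimentally determined RBP
  matrix, deposited expression matrices — supplied by the user under
  `inst/extdata/reference/`; the package deliberately ships no guess for
  the RBP matrix.
* The scanner models a single PWM; no co-occurrence, secondary structure,
  or conservation weighting.
* Enrichment calling starts from FPKM/TPM matrices; upstream scRNA-seq
  processing is out of scope.
* Differential expression is consumed as a table (gene, log2FC, adjusted
  p), not computed.
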
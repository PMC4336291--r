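---
title: "Detecting incorrect sequence-phenotype assignments in selection screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting incorrect sequence-phenotype assignments in selection screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chispas)
```

## The problem

Selection-based saturation mutagenesis relates protein variants to
phenotypes by sequencing pooled colonies: colonies that die under induction
of a toxic gene carry functionally wild-type protein, colonies that survive
carry a variant mutated at a critical residue. Two kinds of error corrupt
the resulting sequence-phenotype map:

* **cell-derived variation** — mutations outside the sequenced window
  (e.g. in the promoter) change the phenotype while the sequenced region
  stays wild-type, and
* **experimental error** — the selection is *leaky* (a colony with
  wild-type activity occasionally survives) and amplification/sequencing
  substitutions reassign reads between variants.

Either way the same variable-region sequence turns up in **both** phenotype
pools: an *incorrect sequence-phenotype assignment* (ISPA). ISPAs caused by
cell-derived variation ("true ISPAs") are biologically meaningful and
should be flagged; ISPAs explainable by experimental error ("false ISPAs")
should not be mistaken for them. This package implements a quality-control
test that separates the two, and a downstream analysis that quantifies what
a given ISPA rate does to critical-residue predictors.

## Data model

Amplicon reads arrive as two pools (one per phenotype). Each read is
screened for the two fixed flanks of the mutagenised amplicon and the
variable region between them — here three codons with **SNS** degeneracy
(S = G/C, N = any base), which encode 10 amino acids
(L, P, H, Q, R, V, A, D, E, G) and no stop codon. Reads failing the flank
check, the length check, or the per-codon pattern check are rejected with a
tagged reason; the pattern check doubles as the filter for the genomic DNA
that is spiked into such libraries to give the sequencer cluster diversity.

One deliberate exception: the wild-type template of the mutagenised region
generally does *not* match the degeneracy pattern (no SNS codon encodes Ile
or Thr, the first two wild-type residues of the HokC window). Since the
wild-type variant is a legitimate — and diagnostically central — member of
the screen, `amplicon_spec()` carries a `wildtype_dna` whitelist accepted
despite failing the pattern. The default stand-in translates to
Ile-Thr-Ala; the literature does not print the true wild-type codons, so
any codon choice with that translation is equivalent at the amino-acid
level at which results are reported.

Accepted regions are grouped (amino-acid level by default, merging
synonymous codons; DNA level for diagnostics) and counted per pool. With
$N$ accepted reads, variants observed in a single pool form the set $U$
(sizes $U_i$, $m$ variants) and variants observed in both pools form the
set $B$ (sizes $B_j$, $n$ variants), with

$$N \ge \sum_{i=1}^{m} U_i + \sum_{j=1}^{n} B_j,$$

equality holding when no read is discarded. Only $B$-set variants are
testable ISPAs.

## The error budget $\mu = E + G$

The expected rate at which a read lands in the wrong pool combines the
point estimate $E$ of the experimental error with its dispersion $G$.
Two components are calibrated:

* **Leakiness** — the false-positive rate of the selection, measured by
  plating colonies that carry the wild-type gene and counting survivors
  under induction. Pooling plates gives $\hat p$; the package computes the
  Agresti-Coull interval
  $$p' \pm z_{1-\alpha/2}\sqrt{p'(1-p')/n'}, \qquad
    n' = n + z^2,\; p' = \frac{x + z^2/2}{n'},$$
  chosen over the plain Wald interval because error rates are small. With
  the default calibration assay (12 survivors / 400 colonies) this is
  3.0% (1.67%–5.23% at 95%), so $G_\text{Leakiness} = 2.23\%$.
* **Sequencing** — short-read substitution error, taken as
  $e_\text{seq} = 1\%$ per read with $G_\text{Sequencing} = 0$ by default.

Under the binomial model the budget is composed as the leakiness *upper
limit* plus the sequencing term:
$\mu = 5.23\% + 1\% \approx 0.062$. The composition, and $\mu$ itself, are
overridable — the upper-limit-plus-$e_\text{seq}$ default is the
decomposition that reproduces the budget used in the original HokC screen,
whose exact construction is not stated in the literature.

A whole-experiment sanity check accompanies the per-variant tests:
$N\mu \ge \sum_j \min(B_j^\text{wt}, B_j^\text{mut})$ must hold if
everything in $B$ is error-derived; exceeding the budget signals
cell-derived variation (or an underestimated $\mu$).

## Binomial model (BiM)

For a $B$-set variant with counts $(w, m)$, $N_v = w + m$, the minority
proportion $x = \min(w, m)/N_v$ is tested one-sided against $\mu$:

$$Z = \frac{x - \mu}{\sqrt{\mu(1-\mu)/N_v}},$$

with $Z \le z_{0.95} = 1.645$ (at $\alpha = 0.05$) meaning the variant is
explainable by experimental error (FALSE_ISPA) and larger $Z$ flagging a
TRUE_ISPA. The canonical worked example: 30 wild-type-pool reads against
300 mutant-pool reads gives $x = 9.1\%$ and $Z = 2.18 > 1.645$, a true
ISPA — the minority rate is too high for leakiness plus sequencing error.

The normal approximation is anticonservative at very small $N_v$; the test
suite documents the divergence zone against an exact binomial tail oracle
(agreement above 90% over random pairs with $N_v \le 50$, with
disagreements concentrated at depths below ~20). An optional
Benjamini-Hochberg flag corrects across the $B$ set; it is off by default
because the original analysis applied no correction.

## Bayesian model (ByM)

The minority proportion receives a conjugate Beta posterior:
$\text{Beta}(a_0 + \min(w,m),\, b_0 + \max(w,m))$ with a flat
$\text{Beta}(1,1)$ prior by default. The reported statistic is the
discrepancy $\mu - \mathbb{E}[\phi \mid x]$: positive means the observed
minority rate is within the error budget (FALSE_ISPA), negative flags a
TRUE_ISPA, and the boundary (discrepancy exactly zero) is assigned
FALSE_ISPA as a tie-break. The highest-posterior-density (HPD) interval —
the shortest interval holding the requested mass — is reported alongside,
computed by one-dimensional optimisation over the lower endpoint; for
shapes with a boundary mode ($a \le 1$ or $b \le 1$) the interval is
one-sided in closed form, and for the bimodal $a<1, b<1$ case the
equal-tailed interval is returned with a warning.

This is a deliberate re-design: the original ByM was a Bayesian logistic
regression fitted in SAS, whose priors and setup are not recoverable from
the text. The conjugate Beta-binomial keeps the described intent — a prior
over the error rate updated by binomial phenotype assignments, summarised
by an HPD interval — while being deterministic, dependency-free and exactly
reproducible. Consequently ByM-specific published figures (a 4.0% HPD upper
limit for the leakiness; 248 ByM true ISPAs) are treated as qualitative
context, not as values this implementation promises to reproduce.

## Reliability of critical-residue predictors under ISPAs

The downstream question: if some fraction of a protein's "known" critical
residues are in fact ISPAs, how much does that perturb the evaluation of a
critical-residue predictor? The analysis follows the published design:

* A predictor is an ordered residue list. At each threshold
  $t \in \{0.05, 0.10, \dots, 0.95\}$ the top $\lceil tL \rceil$ positions
  are called positive and sensitivity $TP/P$, specificity $TN/F$, and the
  Matthews correlation coefficient are computed. MCC uses the standard
  square-root denominator (defined as 0 when the denominator vanishes);
  the printed formula in the source literature omits the root, which we
  treat as a typographical slip since its usage matches standard MCC.
* Each perturbation replicate removes a random 20% of the critical set
  (round-half-even count; $0.2 \times 25 = 5$ exactly for HokC) and
  re-scores the *fixed* predictor ranking. Metrics are computed against the
  perturbed set by default — each replicate defines its own "new critical
  residues" — with `score_against = "original"` available for sensitivity
  analysis. 100 replicates plus the unperturbed evaluation are emitted
  (the "101 groups").
* The **reliable region** is the maximal contiguous threshold run where
  the predictor's envelope minimum strictly exceeds a random predictor's
  envelope maximum; a predictor is **competent** for a protein when the
  region contains the protein's critical fraction $|P|/L$.

Two benchmark critical-residue sets ship with the package, stored as the
verbatim printed position lists and expanded at call time: HokC
($L = 50$, 25 positions — half the protein) and the HIV-1 protease
($L = 99$; the full list is printed as "46 residues" but expands to 47
distinct positions, a discrepancy the package reports without resolving;
the conserved-position criterion gives 23). External predictor rankings
(conservation- or structure-based) are consumed as input files only, with
score ties broken by ascending position and short rankings padded with the
remaining positions (with a warning).

## The synthetic-screen generator

`simulate_screen()` produces screens with known ground truth so that every
pipeline stage is testable without external data. Its defaults are the
study conditions of the HokC screen: 246 wild-type-pool and 699
mutant-pool colonies (each carrying a distinct amino-acid variant drawn
from the 1000 reachable SNS tri-peptides), $10^5$ reads (scaled down from
the ~3.5 × 10^5 of the original run), leakiness 0.03, one expected
substitution per hundred variable regions, a 4 × 100-colony leakiness
assay, and a planted wild-type ISPA at 28% minority rate with expected
depth 1821 reads — mirroring the flagship wild-type case (510
mutant-assigned reads). Two details worth noting:

* Substitution errors are applied per base uniformly across the region
  *and* both flanks, so sequencing error causes flank-mismatch read loss
  exactly as in real data, and can move a read between variant keys.
* Decoy genomic-contamination reads are added at 5% of the read total
  (half without flanks, half with flanks around a non-SNS region). The
  original protocol states that genomic DNA was spiked in but not at what
  fraction; 5% is a realistic spike that exercises both rejection paths
  without dominating runtime.

What the generator does **not** emulate: indels and chimeric reads,
quality-score structure, PCR amplification bias beyond an optional
log-normal depth skew, promoter-region sequences, and colony-count
variation between biological replicates. Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the stated
error taxonomy, not robustness to artefacts outside it.

`recovery_experiment()` wraps the full loop — simulate, extract, count,
calibrate $\mu$ from the simulated assay, classify, score against ground
truth. Two standing results, recomputed by the test suite and the
acceptance script: in error-only screens (no planted ISPAs) the mean
fraction of $B$-set variants miscalled TRUE_ISPA stays below 0.07 at
$\alpha = 0.05$, and a planted 28%-rate ISPA at depth ≥ 300 is recovered
with power ≥ 0.95. These runs use the full colony complement with read
depth scaled to 3 × 10^4 per replicate across 100 replicates — enough
depth for ~30 reads per colony, which is where the method's per-variant
statistics are meaningfully exercised.

## Numerical and design choices

* The reported per-variant frequency column follows the published table
  convention $100 \cdot m/(w+m)$ (mutant share of reads) even when the
  wild-type pool is the minority; classification always tests the
  *minority* proportion.
* Reads are searched for flanks in the given orientation first, then
  reverse complement (pools are unstranded); multiple flank matches take
  the leftmost with a warning; flank matching is exact by default
  (`max_flank_mismatch = 0`) since the protocol verifies the wild-type
  flanks without a stated tolerance.
* Call tables are ordered by descending total count, then variant, so
  reruns are byte-identical.
* Percentages are carried at full precision internally; the calibration
  literature truncates for display (1.668% printed as 1.6%), which the
  package documents but does not imitate.
* Unique-variant totals are always the package's own count. (The source
  screen prints 844 + 842 unique sequences with 475 shared — 1211 — yet
  reports "1212 different sequences"; nothing in this package hard-codes
  either number.)
* The per-variant supplementary table of the original screen is
  third-party data and is not shipped; the printed wild-type row (510
  minority reads, 28%) and the property/recovery suites stand in for it.

## A minimal session

```{r example, eval = FALSE}
library(chispas)
library(dplyr)

# calibrate the error budget from a leakiness assay
assay <- data.frame(colonies_total = rep(100, 4), survivors = c(6, 2, 3, 1))
em <- compose_mu(estimate_leakiness(assay), e_seq = 0.01)

# simulate a screen, or read real pools with read_pool()
cfg <- sim_config(seed = 1)
sim <- simulate_screen(cfg)
tab <- sim$reads |>
  extract_variable_region(cfg$amplicon) |>
  count_variants(level = "aa")

res <- classify_table(tab, em)
glance(res)           # summary counts, error budget
tidy(res)             # per-variant calls

# reliability of a predictor under 20% ISPAs
hokc <- hokc_critical_residues()
set.seed(1)
perf <- reliability_envelope(perfect_predictor(hokc), hokc,
                             predictor = "perfect")
rand <- reliability_envelope(random_predictor(50), hokc,
                             predictor = "random")
reliable_region(perf, rand, "sensitivity")
autoplot(dplyr::bind_rows(perf, rand))
```

## Limitations

* $e_U$ — the error rate among single-phenotype variants — is not
  estimable from sequencing data alone and is deliberately not computed.
* The BiM Z-test is anticonservative for variants with very few reads in
  both pools; treat TRUE_ISPA calls at $N_v \lesssim 10$ with caution or
  enable the BH flag.
* The ByM here is the conjugate Beta-binomial, not the original logistic
  regression; its calls agree with BiM on clear cases but its published
  intermediate numbers are not reproduction targets.
* Reliability conclusions for external predictors depend entirely on the
  supplied rankings; the package computes none itself.
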
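# chispas

Quality control for sequence-phenotype assignments in selection-based
saturation-mutagenesis screens.

In such screens, colonies are sorted by phenotype (e.g. killed vs. surviving
under induction of a toxic gene such as *E. coli* `hokC`), pooled, and the
mutagenised region is amplicon-sequenced per pool. Any variant observed in
**both** phenotype pools is an *incorrect sequence-phenotype assignment*
(ISPA). Some ISPAs are real biology — cell-derived variation outside the
sequenced window (a promoter mutation, say) flips the phenotype while the
sequenced region stays wild-type — and some are merely experimental error:
a leaky selection or sequencing substitutions. Telling the two apart
matters, because false critical-residue assignments propagate into every
downstream structure-function analysis.

`chispas` separates them with an experimentally calibrated error budget
μ = E + G: the leakiness of the selection (point estimate E with
Agresti-Coull dispersion G) plus the per-read sequencing error. Each
both-phenotype variant with counts (w, m), N_v = w + m and minority
proportion x = min(w, m)/N_v is tested two ways:

* **BiM** (binomial model): one-sided Z-test,
  Z = (x − μ) / √(μ(1 − μ)/N_v); Z > 1.645 (α = 0.05) flags a TRUE_ISPA
  (cell-derived), smaller Z a FALSE_ISPA (explainable by error).
* **ByM** (Bayesian model): conjugate Beta posterior for x with a flat
  prior; the sign of μ − E[ϕ|x] makes the call, with a
  highest-posterior-density interval reported alongside.

The package also quantifies what a given ISPA rate does to
critical-residue predictors: confusion metrics (sensitivity, specificity,
MCC) over top-k% thresholds, random 20%-perturbation envelopes over 100
replicates, perfect/random baseline predictors, the *reliable region*
(where a predictor's envelope separates from random) and *competence*
(whether that region contains the protein's critical-residue fraction).
A synthetic-screen generator with known ground truth (SNS codon libraries,
leakiness, sequencing error, genomic-DNA decoys, planted ISPAs) makes the
whole pipeline testable end to end.

## Worked example

Calibrate the error budget from a leakiness assay (4 plates of 100
wild-type colonies, 12 survivors), then classify:

```r
library(chispas)

assay <- data.frame(colonies_total = rep(100, 4), survivors = c(6, 2, 3, 1))
fit <- estimate_leakiness(assay)
fit
#> <leakiness_fit> 12/400 survivors: p_hat = 0.03
#>   Agresti-Coull 95% CI: 0.01668 - 0.05226 (G = 0.02226)
#>   Beta(13, 389) posterior 95% HPD: 0.01613 - 0.04991 (G = 0.01991)

em <- compose_mu(fit, e_seq = 0.01)
em
#> <error_model> BIM: mu = 0.06226 (leakiness upper 0.05226 + e_seq 0.01 + G_seq 0)
```

So the selection misassigns ~3% of colonies (upper limit 5.2% at 95%
confidence), and with 1% sequencing error the per-read error budget is
μ ≈ 0.062. A variant read 30 times in the wild-type pool and 300 times in
the mutant pool is then a *true* ISPA — its 9.1% minority rate is too high
for experimental error:

```r
classify_bim(30, 300, em$mu)
#>   minority_count minority_phenotype bim_sigma bim_z  bim_p bim_call
#> 1             30 WT                    0.0133  2.15 0.0156 TRUE_ISPA
```

The same machinery runs on whole screens. On a simulated screen at the
default study scale (945 colonies, 10^5 reads, a wild-type ISPA planted at
28% minority rate):

```r
cfg <- sim_config(seed = 1)
sim <- simulate_screen(cfg)
tab <- count_variants(extract_variable_region(sim$reads, cfg$amplicon))
res <- classify_table(tab, em)
res
#> <ispa_result> 966 unique variants (806 U, 160 B), N = 96718 reads, mu = 0.06226
#>   BiM: 3 TRUE / 157 FALSE ISPAs (0.311% of unique variants)
#>   ByM: 3 TRUE / 157 FALSE ISPAs (0.311% of unique variants)
#>   common TRUE: 3; error budget ok (N*mu = 6022 vs 665)

dplyr::filter(tidy(res), variant_aa == "ITA")
#>   variant_aa wt_count mut_count observed_ispa_pct bim_z bim_call  bym_call
#> 1 ITA            1257       490              28.0  37.7 TRUE_ISPA TRUE_ISPA
```

The planted wild-type ISPA (amino acids Ile-Thr-Ala) is recovered at its
28% rate and called TRUE_ISPA by both models; the 157 variants shared
between pools through leakiness and sequencing error alone are correctly
attributed to the error budget.

For the reliability analysis, the HokC (25/50 critical residues) and HIV-1
protease fixtures ship with the package:

```r
hokc <- hokc_critical_residues()
set.seed(1)
perf <- reliability_envelope(perfect_predictor(hokc), hokc, predictor = "perfect")
rand <- reliability_envelope(random_predictor(50), hokc, predictor = "random")
reliable_region(perf, rand, "sensitivity")   # contains 0.5 -> competent
autoplot(dplyr::bind_rows(perf, rand))
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/chispa.R simulate --seed 1 --out-dir screen/
Rscript inst/cli/chispa.R count --wt screen/wt.fastq --mut screen/mut.fastq --out variants.tsv
Rscript inst/cli/chispa.R leakiness --assay screen/assay.tsv --out error_model.txt
Rscript inst/cli/chispa.R classify --table variants.tsv --error-model error_model.txt --out report.tsv
Rscript inst/cli/chispa.R reliability --criticals hokc --seed 1 --out envelope.tsv
```

## Package layout

* `R/amplicon.R` — read pools, flank/SNS validation, variant counting
* `R/error_model.R` — Agresti-Coull, Beta posterior + HPD, μ composition
* `R/ispa.R` — BiM/ByM per-variant tests, screen-level report and budget
* `R/reliability.R`, `R/fixtures.R` — predictor evaluation under
  perturbation; HokC / HIV-1 protease critical-residue sets
* `R/simulate.R` — synthetic screens and recovery experiments
* `inst/cli/chispa.R` — command-line front end
* `vignettes/chispas-methods.Rmd` — models, assumptions, design decisions
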
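# srdetect

Differential alternative-splicing detection from splice-junction read
counts, for bulk RNA-seq comparisons of treatment against control samples
(e.g. a knockdown against its controls), together with the downstream
cohort-association stage and a proteome-microarray candidate filter.

## The method

A splice junction's **splicing ratio** (SR) in a sample is its uniquely
mapped read count divided by the summed counts of junctions sharing the
same 5' splice site (5' SR) or 3' splice site (3' SR). An
alternative-splicing event is a pair of junctions sharing a splice site —
typed as cassette exon (CA), alternative 3'/5' splice site (A3SS/A5SS) or
mutually exclusive exons (MXE) from the relative positions of the three
exons involved. For an event in treatment sample *j* against *N*<sub>c</sub>
controls the **splicing-ratio-difference** score is

```
srd = (1 + Σᵢ (SR_tj − SR_ci)) / (1 + sd(SR_c) / N_c)
```

so srd = 1 means "unchanged". Per treatment sample, the srd distribution
over all events is fitted with a power-law tail (maximum-likelihood
exponent, KS-minimising cutoff); an event's significance is the fitted
tail's complementary CDF. Candidates are events whose **median**
significance across treatment samples falls below a dynamic threshold
derived from leave-one-out control comparisons, and are ranked by the sum
of absolute inclusion- and skipping-isoform expression differences.
Downstream, cohort events are screened by occurrence frequency (> 5%),
tested for association with a binary group label (exact Fisher test by
hypergeometric enumeration) and for survival association (log-rank test
and Cox hazard ratio), and microarray spots are filtered on
SNR ≥ 3, fold change ≥ 5 and duplicate-spot CV < 0.15.

A synthetic-data module generates every input with known ground truth:
junction counts at controlled PSI with negative-binomial noise, matched
isoform tables, cohorts with planted odds ratios and hazard ratios, and
duplicate-spot microarray tables with planted binders.

## Worked example

```r
library(srdetect)

models <- simulate_gene_models(c(CA = 1000))            # 1000 cassette genes
sim <- simulate_junction_counts(models, n_treatment = 2, n_control = 3,
                                depth = 100, n_planted = 50,
                                delta_psi = 0.3, seed = 1)
fit <- srd_detect(sim$junctions, sim$treatment, sim$control,
                  annotation = models$annotation)
print(fit)
#> Differential alternative-splicing detection (srd)
#>   2000 events from 2 treatment / 3 control samples
#>   selection threshold (q = 0.05 background quantile): 0.1631
#>   selected: 78 events
#>   by type: CA=78

detection_performance(fit, sim$truth$gene_id[sim$truth$planted])[1:3]
#> $sensitivity
#> [1] 0.9
#> $fdr
#> [1] 0.0625
#> $n_selected_events
#> [1] 78

print(fit$fits[["T1"]])
#> Power-law tail fit
#>   alpha = 7.7597, xmin = 1.314
#>   tail: 520 of 2000 points; KS distance 0.0288
```

Each cassette gene yields two reciprocal junction-pair events (one per
shared splice site), hence 2000 events from 1000 genes; 45 of the 50
planted genes are recovered (sensitivity 0.9) with 5 false-positive genes
among the selections (FDR 0.06). The fitted tail exponent and cutoff shown
by `print(fit$fits[["T1"]])` describe the null model used to convert srd
scores to significances in sample T1.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/srdetect.R simulate --out study/ --seed 17
Rscript inst/cli/srdetect.R detect --dir study/ --treatment T1,T2 \
        --control C1,C2,C3 --out events.tsv
Rscript inst/cli/srdetect.R cohort --cohort study/cohort.tsv --out cohort.tsv
Rscript inst/cli/srdetect.R hpm-filter --spots study/spots.tsv --out hpm.tsv
```

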
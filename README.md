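# namgwas

Full-genetic-model GWAS and breeding prediction for nested association
mapping (NAM) populations.

## The problem

NAM populations — families of recombinant inbred lines sharing a common
parent, such as the maize B73 NAM panel — are a workhorse for mapping
quantitative traits like ear weight, length, rank and row number.  Most
association scans fit additive effects only.  That leaves dominance,
digenic epistasis and gene-by-environment (G×E) interaction variance
unexplained, and it cannot answer the breeder's actual question: *which
multi-locus genotype combination — possibly heterozygous — maximizes the
trait, and in which environment?*

`namgwas` implements the complete workflow around a full genetic model:

$$y_{hk} = \mu + c_{hk} + \textstyle\sum_i a_i x_{A} + \sum_i d_i x_{D}
+ \sum_{i<j}(aa\,x_{AA} + ad\,x_{AD} + da\,x_{DA} + dd\,x_{DD})
+ e_h + \sum(ae + de + aae + ade + dae + dde)\,u + \varepsilon_{hk}$$

with $x_A \in \{1, 0, -1\}$ for QQ/Qq/qq (Q = non-B73 allele), $x_D$ the
heterozygote indicator, epistasis contrasts as products of the single
locus contrasts, genetic effects fixed, and environment plus every G×E
family random.  The stages:

1. **Simulation** of NAM-like genotypes and multi-environment phenotypes
   with a known architecture (`simulate_nam_genotypes()`,
   `make_architecture()`, `simulate_phenotypes()`), so every estimator is
   testable without any data download.
2. **QC**: MAF < 0.05 and call-rate < 90% SNP filters; per
   trait-by-environment IQR fences (Q1 − 1.5 IQR, Q3 + 1.5 IQR) and
   3-s.d. standardized-residual phenotype outlier removal.
3. **GMDR prescreening** of loci and locus pairs by cross-validated
   balanced accuracy of high/low-risk genotype cells (`gmdr_scan()`).
4. **Association**: Henderson method III F-tests, within-environment
   permutation thresholds controlling the experiment-wise error
   (`henderson_scan()`, `permutation_threshold()`), REML variance
   components, Gibbs-sampling effect estimation (`fit_full_model()`,
   `gibbs_estimate()`), and heritability partitioning into twelve
   components with the aggregates $h^2_T$, $h^2_{D+}$, $h^2_{GE}$
   (`heritability()`).
5. **Breeding prediction**: total genotypic values of arbitrary genotype
   combinations, best existing line, superior line (homozygotes only) and
   superior hybrid (heterozygotes allowed), by exact enumeration or
   deterministic multi-start stepwise tuning
   (`predict_breeding_table()`).

`run_pipeline()` chains all stages from a single seeded config and writes
TSV tables (scan, effects, per-environment effects, heritability,
breeding) plus a log.

## Worked example

```r
library(namgwas)

geno  <- simulate_nam_genotypes(n_families = 5, lines_per_family = 80,
                                n_snps = 100, het_rate = 0.05, seed = 11)
arch  <- make_architecture(n_loci = 3, n_pairs = 1,
                           target_h2 = c(A = 0.15, D = 0.05, AE = 0.08),
                           seed = 12, n_envs = 2, ref_geno = geno)
pheno <- simulate_phenotypes(geno, arch, n_envs = 2, seed = 13)

qc    <- filter_snps(geno)
cand  <- gmdr_scan(pheno, qc$geno, dims = c(1, 2), top_k = 5,
                   survivors = 10, seed = 14)
terms <- candidate_terms(cand)
thr   <- permutation_threshold(qc$geno, pheno, terms$loci, terms$pairs,
                               n_perm = 500, alpha = 0.05, seed = 15)
sig   <- thr$terms[thr$terms$significant, c("term", "F", "p_ew")]
```

The experiment-wise significant terms (true causal loci were `S1_100000`,
`S2_100000`, `S3_100000`; the remaining hits are family-structure
proxies):

```
        term        F        p_ew
 a@S2_100000 92.62309 0.001996008
 a@S1_100000 61.00897 0.001996008
 a@S3_100000 39.70708 0.001996008
 ...
 d@S2_100000 68.82807 0.001996008
 d@S3_100000 22.96460 0.001996008
```

Joint estimation and heritability on the surviving loci:

```r
loci <- unique(sub("^[ad]@", "", sig$term[grepl("^[ad]@", sig$term)]))
dm   <- build_design(qc$geno, pheno, loci)
fit  <- fit_full_model(dm)
est  <- gibbs_estimate(fit, n_iter = 5000, burn_in = 1000, seed = 16)
heritability(est, dm)
#> heritability components (% of phenotypic variance):
#>  component h2_pct
#>          A  19.20
#>          D  10.02
#>         AE   7.69   (other components ~0)
#> aggregates: h2_T = 36.91, h2_D+ = 10.02, h2_GE = 7.69
```

Posterior means are in trait units: e.g. `a@S2_100000 = -0.373 (sd
0.042)` is the additive substitution effect of that SNP, and the
aggregates say ~37% of phenotypic variance is genetic, 10 points of it
dominance-related and 7.7 points environment-interacting.  Breeding
prediction over the significant loci:

```r
eff <- effects_to_architecture(est, dm)
predict_breeding_table(eff, qc$geno)
#>            entry      G  G_GE1  G_GE2
#>               mu -0.069  0.567 -0.705
#>               QQ -0.538 -0.007 -1.069
#>               qq  0.538  0.007  1.069
#>               F1 -0.454 -0.455 -0.453
#>        best_line  2.305  2.180  2.433
#>    superior_line  1.234  0.936  1.627
#>  superior_hybrid  2.305  2.180  2.524
```

Rows are total genotypic values relative to the mean (the `mu` row is
absolute): the uniform QQ/qq/F1 combinations, the best existing line, and
the predicted optimal homozygous (superior line) and unrestricted
(superior hybrid) combinations, overall (`G`) and per environment
(`G_GE1`, `G_GE2`).  Here the best existing line carries favorable
heterozygous calls, so it beats the best purely homozygous combination
and ties the hybrid optimum overall — exactly the situation where
hybrid-line breeding has more headroom than pure-line breeding.

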
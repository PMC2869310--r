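# costex

Cost–benefit modelling of gene-expression fitness and post-WGD ohnolog
retention analysis.

## The problem

After a whole-genome duplication (WGD), most duplicated gene pairs
(*ohnologs*) are eventually reduced back to a single copy, but the survivors
are not a random sample: highly expressed genes keep both copies far more
often. `costex` packages, in one tested pipeline, a simple explanation and
the analyses needed to detect the pattern:

* **The model.** A gene expressed at absolute level `X` pays a Monod-type
  resource cost `C(X) = kX / (1 − X/M)` (with `M` the cellular expression
  capacity and `k` a cost scale) and draws a benefit `B(x)` from its
  product, where `x = X/X₀` is expression relative to the gene's optimum
  `X₀`. Relative fitness is `w(x) = B(x) − C(X₀·x)`, calibrated so that
  `w(1) = 1` and `w′(1) = 0`. Because the cost is convex and the convexity
  grows with `X₀`, the curvature `w″(1) = B″(1) − X₀²·C″(X₀)` is more
  negative for highly expressed genes: every perturbation of dosage or
  function costs them more. Three selection coefficients fall out:
  * halving of expression (ohnolog loss): `s = −w″(1)/8` (Taylor) or
    `s = 1 − w(½)` (exact);
  * pseudogenization (functionless peptide still expressed):
    `s_ψ = X₀·C′(X₀)`, a lower bound;
  * a missense allele reducing the benefit by a fraction `α`:
    loss `= α·B(1) = α·(1 + C(X₀))`.
* **The simulator.** Selection coefficients become loss-fixation hazards via
  the diffusion fixation-probability ratio `r(s) = 4Nₑs / (e^{4Nₑs} − 1)`;
  an ohnologon with two copies is retained to time `T` with probability
  `exp(−2·λ₀·r(s)·T)`.
* **The pipeline.** Quantile normalization across arrays, per-gene
  expression level as log2 of the median signal, random-member expression
  assignment per ohnologon, fixed-interval retention binning (bins under 30
  ohnologons excluded), extreme-decile comparison with chi-square/Fisher
  tests, stratified (protein complexes, phylogenetic groups) and
  functional-category analyses, ohnolog expression-divergence metrics
  (Pearson, Euclidean), Ka-vs-expression correlation, and heterozygous-KO
  fitness binned by expression.
* **The generator.** A fully seeded synthetic-data module emulates the
  statistical structure of the ciliate microarray/ohnologon data (58
  conditions, log-normal expression, expression-dependent retention, Ka and
  profile divergence, complex-membership retention bonus, yeast-like KO
  fitness) so that every stage of the pipeline is testable offline.

## Worked example

```r
library(costex)

g <- gene_model(X0 = c(10, 50, 90), k = 0.01, M = 100)
data.frame(X0 = g$X0,
           curvature    = curvature_at_optimum(g),
           s_taylor     = sel_coeff_halving(g, "taylor"),
           s_exact      = sel_coeff_halving(g, "exact"),
           s_pseudogene = as.numeric(sel_coeff_pseudogene(g)))
#>   X0     curvature     s_taylor      s_exact s_pseudogene
#> 1 10 -2.743484e-02 3.429355e-03  0.003248863    0.1234568
#> 2 50 -4.000000e+00 5.000000e-01  0.333333333    2.0000000
#> 3 90 -1.620000e+03 2.025000e+02 36.818181818   90.0000000
```

The fitness peak sharpens dramatically with `X₀` (curvature −0.03 → −1620),
so selection against losing one copy — or against a function-damaging
allele — grows with expression. Running the full synthetic pipeline:

```r
cfg <- generator_config(n_genes = 5000, seed = 42)
b <- run_end_to_end(cfg, interval = 0.5)
b$summary
#> overall retention: 0.511
#> bottom/top decile: 0.174 / 1.000 (fold 5.75, p = 5e-155)
#> Ka vs expression: r = -0.272
#> divergence vs expression: 1-Pearson r = -0.785, Euclidean r = -0.906
#> min KO fitness vs expression: r = -0.135
head(b$bins)
#>    lo  hi   n retention
#> 1 3.0 3.5  36 0.1666667
#> 2 3.5 4.0  52 0.2115385
#> 3 4.0 4.5 100 0.1900000
#> ...
```

Genome-wide retention is calibrated to ~0.5; the retention frequency rises
with expression level across bins; the top expression decile retains both
copies several times more often than the bottom decile; Ka and both
expression-divergence measures correlate negatively with expression; and
mean heterozygous-KO fitness falls with expression — the qualitative
signature the model predicts.

## Command line

```sh
costex generate --seed 1 --out data/           # write synthetic input TSVs
costex run-all  --seed 1 --out run/            # full pipeline + summary.json
costex analyze-retention --ohnologons data/ohnologons.tsv \
       --expression data/expression.tsv --interval 0.2
costex model-curves --x0 10,50,90 --out curves.tsv
```

(`exec/costex` is installed with the package; equivalently call
`costex::costex_cli(c("run-all", "--seed", "1", "--out", "run"))`.)

## Layout

* `R/model.R` — cost/benefit/fitness equations and selection coefficients
* `R/simulate.R` — fixation-scaled loss simulator (+ iterated-WGD cascade)
* `R/generate.R` — seeded synthetic-data generator
* `R/retention.R` — normalization, summarization, binning, decile, strata,
  categories
* `R/divergence.R` — divergence metrics, Ka correlation, KO-fitness analysis
* `R/io.R`, `R/pipeline.R`, `R/cli.R` — TSV/config I/O, end-to-end run, CLI
* `vignettes/costex-methods.Rmd` — model derivation, generator assumptions,
  numerical choices, limitations
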
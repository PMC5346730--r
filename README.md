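# netprior

Prioritizing candidate drug-resistance genes by combining two-condition
differential expression with cohort co-expression modules, and validating
the candidates on survival.

## The problem

Comparing a drug-resistant cell line with its parental line (the motivating
case is trastuzumab resistance in HER2-positive breast cancer) yields
hundreds of differentially expressed genes, most of which have nothing to
do with the resistance phenotype. `netprior` implements a
network-filtering strategy for that list, aimed at computational biologists
who have (a) a transcript-level two-condition expression profile and (b) a
patient cohort expression matrix with clinical traits and follow-up:

1. **Differential expression** — one representative (most expressed)
   isoform per protein-coding gene, log2 fold-changes with a pseudocount,
   outlier filtering, and selection of the top fraction *q* = 10% of genes
   by |log2FC|.
2. **Co-expression modules** on the cohort, on the genes common to both
   data sets: unsigned weighted adjacency *a<sub>ij</sub>* =
   |cor(x<sub>i</sub>, x<sub>j</sub>)|<sup>β</sup>, topological overlap
   TOM<sub>ij</sub> = (ℓ<sub>ij</sub> + a<sub>ij</sub>) /
   (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>), average-linkage
   clustering of 1 − TOM, module eigengenes (first principal component),
   and eigengene-trait correlations (tumor/normal, ER, PR, HER2).
3. **Enrichment scoring** — each module's count *k* of top-DE genes among
   its *n* universe genes is tested against the uniform null with the exact
   binomial upper tail p = P(X ≥ k), X ~ B(n, q); the module score is
   −ln p, and modules with p < α and k/n > q are *enriched*. Top-DE genes
   inside enriched modules form the candidate ranking (module score, then
   |log2FC|).
4. **Survival validation** — for each leading candidate: median split of
   its cohort expression, Kaplan–Meier curves, log-rank test, and a Cox
   proportional-hazards fit reporting the hazard ratio, 95% Wald CI and
   hazard elevation 100·(HR − 1) (an HR of 1.181 is an 18.1% elevation).

Because the original inputs (cell-line RNA-Seq, clinical cohort) cannot be
bundled, the package includes a seeded latent-factor simulator
(`simulate_study()`) that generates a module-structured cohort, a planted
DE profile concentrated in the tumor-associated module, and
proportional-hazards survival tied to one designated target gene — with
ground truth, so the whole pipeline is testable end to end. See the
vignette (`vignettes/target-prioritization.Rmd`) for the model, parameter
defaults, and design rationale.

## Worked example

```r
library(netprior)
report <- run_pipeline(list(seed = 1))
print(report)
```

```
Target-prioritization run (seed 1)
  stage counts: transcripts=1239, genes_de=490, genes_filtered=490, universe=490, top_genes=49, candidates=39, validated=5
  soft-threshold power: 6; modules: 5
  enriched modules:
    ME1: n=60, k=39, -ln(p)=55.3, tumor r=0.56
  top candidates: g0038 (ME1), g0021 (ME1), g0050 (ME1)
  lead candidate g0038: HR 1.211 (95% CI 0.971-1.510), +21.1% hazard, log-rank p 0.08901
```

Reading this: of 1239 simulated transcripts, 490 protein-coding genes
survive representative-isoform selection and filtering; all are present in
the cohort (universe = 490) and the top 49 by |log2FC| are tested against
the 5 detected modules. Module ME1 holds 39 of the 49 top genes versus ~6
expected under uniformity (−ln p = 55.3) and correlates with tumor status
(r = 0.56), so its top-DE members become candidates. The planted target
gene (`report$truth$target_gene`, here g0021) ranks 2nd, and the lead
candidate's high-expression group shows a +21% hazard elevation — at the
simulation's planted HR of 1.2 and 444 patients, individual log-rank tests
sit near the edge of detectability, which is faithful to studies of this
size.

The same stages can be run as separate, inspectable steps via the numbered
drivers in `analysis/` (simulate → DE → network → enrichment → survival),
which persist every intermediate table under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_diffexpr.R
Rscript analysis/03_network.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_survival.R
```

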
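# gbanet

Guilt-by-association gene function prediction on co-expression networks,
for small two-group expression studies (the motivating design: eight
early-onset preeclampsia placentas vs eight matched controls).

Given a gene × sample log2 expression matrix with a two-group design and
gene → GO-term annotations, `gbanet`:

1. screens **differentially expressed genes** (DEGs) with a moderated
   two-sample t-test (empirical-Bayes variance shrinkage, implemented in
   the package) at the strict thresholds *p* < 0.02 and |log2FC| > 2;
2. builds the **complete weighted co-expression network** over the DEGs,
   with Spearman's rank correlation coefficient (SRCC) as edge weight —
   *n* genes always give *n(n−1)/2* edges — reports hub degrees and
   extracts the |SRCC| > 0.8 subnetwork (edge-list TSV + GraphML for
   Cytoscape);
3. filters GO terms to those annotating **more than 20** network genes;
4. scores each gene/term pair by **weighted neighbor voting**,
   score(i,K) = Σⱼ |wᵢⱼ|·1[j ∈ K, j visible] / Σⱼ |wᵢⱼ|·1[j visible],
   under 3-fold cross-validation over genes, and evaluates every term by
   its mean held-out **ROC AUC** (Mann–Whitney form), alongside the
   per-gene **multifunctionality** baseline
   MFᵢ = Σ_{K∋i} 1/(Num_in_K·Num_out_K);
5. reports terms with mean AUC strictly above 0.7 as the **optimal
   functions**.

A synthetic-data module generates matched expression + annotation data
with planted DE genes, latent-factor co-expression modules, and
module-coherent terms, so the full pipeline is testable with no
external downloads.

## Worked example

A fully synthetic run in which the simulated condition perturbs ten
25-gene co-expressed modules (module correlation 0.9) annotated by ten
strongly coherent GO terms:

```r
library(gbanet)
cfg <- pipeline_config(
  simulation = simulation_config(
    n_genes = 500, n_per_group = 8, n_de_genes = 400, de_lfc_mean = 3,
    n_modules = 10, module_size = 25, module_rho = 0.9, noise_sd = 1,
    n_terms = 10, term_size = 25, term_coherence = 0.9, seed = 42,
    de_covers_modules = TRUE, de_sign = "by_module"),
  seed = 42, out_dir = "readme_run")
res <- run_pipeline(cfg)
print(res$network)
#> coexpression_network: 393 nodes, 77028 edges
res$optimal[1:3, c("term", "in_count", "mean_auc", "mf_auc")]
#>         term in_count  mean_auc    mf_auc
#> 1 GO:0000008       24 0.9573552 0.8606594
#> 2 GO:0000002       24 0.9498645 0.8526423
#> 3 GO:0000010       25 0.9484624 0.6069565
```

393 of the 500 genes pass the DEG screen (the planted effect is 3 log2
units), the complete network has 393·392/2 = 77,028 edges, all 10
planted terms survive the >20-gene filter, and all 10 are selected as
optimal functions: their mean cross-validated AUCs (0.87–0.96) measure
how well the network ranks each term's held-out member genes above
non-members — 0.5 would be chance. The `mf_auc` column is the
annotation-bias baseline: terms whose voting AUC only matches their MF
AUC owe their score to annotation structure rather than co-expression.
Each stage's table (DEG table, edge lists, GraphML, SRCC matrix,
per-term performance, MF scores, AUC histogram, run manifest) is written
to `out_dir`; identical config + seed reproduces them byte for byte.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --config run.yaml` or `--synthetic`).

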
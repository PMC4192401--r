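# dcoexnet

Differential co-expression network analysis for two-class transcriptional
profiling.

## The problem

Two groups of patients can share a diagnosis yet differ in how their
transcriptomes are *wired*: a gene may keep the same mean expression in
both groups while gaining or losing most of its co-expression partners.
`dcoexnet` implements a complete pipeline for finding such genes and
turning them into a diagnostic marker panel, for studies that profile two
patient classes (here generically `classA` / `classB`) against a shared
control arm — the motivating use case being the molecular discrimination
of traditional-medicine syndrome classes among hepatitis-B cirrhosis
patients.

## The method

1. **Preprocessing** — log2 transform, probe filtering at signal-to-noise
   ratio SNR > 2, quantile normalization.
2. **Two-step differential expression** — each patient class is compared
   with the control arm, then with the other class; a gene is a DEG when
   |fold change| ≥ 2 and two-sided t-test p < 0.05, and the final set is
   the class-vs-class DEGs gated by the control step.
3. **Class-specific co-expression networks** — over the DEG set, one
   network per class: an edge joins genes *g*, *h* when their Pearson
   correlation over that class's samples satisfies |r| ≥ 0.8 and the
   correlation t-test (df = n − 2) gives p < 0.05. Negative correlations
   form signed edges.
4. **Core genes by degree difference** — candidate hubs are genes with
   degree ≥ 10 and local clustering coefficient ≥ 0.2 in at least one of
   the two networks; *core genes* are candidates with

   ΔDegree = |degree_A − degree_B| ≥ 8,

   the statistic that captures "connected in one class, isolated in the
   other".
5. **Marker panel** — logistic regression (IRLS, optional ridge, forward
   stepwise by AIC) combines the core genes; performance is the area
   under the ROC curve (equal to the normalized Mann–Whitney U) with a
   stratified percentile-bootstrap 95% CI.
6. **Validation & enrichment** — comparative-Ct (ΔΔCt) quantification of
   qPCR measurements, Mann–Whitney group tests, and hypergeometric
   gene-set over-representation reported as −log10(p).

A synthetic-data module generates expression matrices with planted
differential expression and class-specific latent-factor modules, probe
signal/noise tables, and Ct tables, so every stage is testable with known
ground truth and no external downloads.

## Worked example

Simulate a study with 2000 genes, 20 samples per class, 30 DE genes
(|log2 FC| = 2.5) of which genes g1–g12 also form a co-expression module
active only in class A, then run the analysis:

```r
library(dcoexnet)

de  <- data.frame(gene = 1:30,
                  log2_effect = c(rep(2.5, 12), rep(c(2.5, -2.5), 9)))
syn <- synthetic_config(2000, n_per_class = 20, de_genes = de,
                        modules = list(planted_module(1:12, "classA",
                                                      latent_loading = 2)),
                        noise_sd = 0.5, seed = 7)
x    <- generate_expression(syn)
degs <- two_step_degs(x)                      # 30 DEGs

net_a <- build_network(x, "classA", degs$gene_id, r_threshold = 0.8)
net_b <- build_network(x, "classB", degs$gene_id, r_threshold = 0.8)
net_a
#> coexpression_network [classA]: 30 nodes, 66 edges (0 negative)
net_b
#> coexpression_network [classB]: 30 nodes, 0 edges (0 negative)

core <- select_core_genes(locate_candidates(net_a, net_b), net_a, net_b,
                          ddeg_min = 8, de_records = degs)
head(core, 4)
#>   gene_id description style degree_a degree_b delta_degree
#> 1      g1                up       11        0           11
#> 2     g10                up       11        0           11
#> 3     g11                up       11        0           11
#> 4     g12                up       11        0           11
```

The planted module is fully connected in the class-A network (each of the
12 genes linked to its 11 partners) and absent from class B, so every
module gene scores ΔDegree = 11 and nothing else qualifies. A three-gene
panel then separates the classes:

```r
ab    <- names(x$sample_class)[x$sample_class %in% c("classA", "classB")]
feats <- t(x$values[core$gene_id[1:3], ab])
model <- fit_logistic(feats, x$sample_class[ab],
                      positive_class = "classB", penalty = 1e-4)
roc   <- roc_auc(predict_prob(model, feats), x$sample_class[ab],
                 positive_class = "classB", ci = TRUE, n_boot = 2000,
                 seed = 7)
roc
#> roc_result: AUC = 0.975 (95% CI 0.91 to 1, 2000 bootstraps)
```

`run_pipeline(pipeline_config(synthetic = syn, seed = 7))` performs the
same stages end to end and writes TSV/JSON outputs plus a provenance
manifest.

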
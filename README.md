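# coexsub

Molecular subtyping of cancer samples from **subtype-specific
co-expression modules** and network-perturbation features.

Expression-based subtype classifiers usually work on per-gene expression
levels. `coexsub` works on the co-expression *structure* instead: it
finds, for each subtype, the gene module whose co-expression pattern
exists only in that subtype, and then classifies a sample by how much it
disturbs that structure. This targets cohorts where subtypes differ in
regulatory wiring more than in marginal expression, and where heavy class
imbalance (a handful of samples for one receptor-defined subtype, hundreds
for another) breaks standard classifiers.

## Method

For a cohort with subtypes `1..T`:

1. **Aggregated networks.** Per subtype, draw `F` subsampled folds of
   `Ns` samples and compute Spearman correlations with t-approximation
   p-values per fold; combine as
   `cor = (1/F) Σ_f cor_f` and `P = (Π_f p_f)^(1/F)`.
   Keep edges with `P ≤ 0.01`, drop genes without any significant edge.
2. **Modules.** Soft-threshold the significant edges
   (`a_ij = |cor_ij|^β`, β from the scale-free fit index), cluster the
   topological-overlap dissimilarity by average linkage, cut statically,
   and trim weakly attached members; unassignable genes form Module0.
3. **Specific module and edges.** Rank each module by (i) its maximal
   overlap ratio `|M_i^s ∩ M_j^t| / |M_i^s|` with other subtypes'
   modules, ascending, and (ii) the minimal gap between its mean edge
   correlation in `s` and in every other subtype (absent edges count 0),
   descending. The module with the smallest rank sum is the specific
   module; its top `E` edges by `Δcor = cor^s − max_{x≠s} cor^x` are the
   specific edges.
4. **Perturbation features.** Build reference networks from `P` training
   samples per subtype; a sample's feature vector is
   `|cor' − cor|` at all `T·E` specific edges after appending the sample
   to each subtype's reference network. Training vectors are augmented
   over multiple reference sets until all subtypes contribute similar
   numbers.
5. **Classification.** A 50–10 ReLU network with softmax output and
   cross-entropy loss (SGD, early stopping) classifies each vector; a
   sample's label is the majority vote over its reference sets. Reported
   metrics: accuracy, macro-P, macro-R, and macro-F1
   `= 2·P·R/(P+R)` on the macro averages.

## Worked example

The package ships a seeded generator that plants one subtype-exclusive
co-expression block per group (plus a shared block and noise genes), so
the whole pipeline can be exercised without any download:

```r
library(coexsub)

sim <- simulate_expression(simulation_spec(seed = 7))
sim$dataset
#> expression_dataset: 300 genes x 117 samples
#> subtypes: control (20), subtypeA (60), subtypeB (12), subtypeC (25)
#> log2-transformed: FALSE

res <- run_pipeline(sim$dataset, pipeline_config(n_edges = 50, seed = 7))

head(as.data.frame(res$specificity$subtypeB$edges), 3)
#>   gene_a gene_b delta cor_control cor_subtypeA cor_subtypeB cor_subtypeC
#> 1  g0053  g0064 0.972           0            0        0.972            0
#> 2  g0055  g0074 0.970           0            0        0.970            0
#> 3  g0067  g0070 0.968           0            0        0.968            0

res$report
#> accuracy 1.000 | macro-P 1.000 | macro-R 1.000 | macro-F1 1.000
#> per-class recall: control 1.000, subtypeA 1.000, subtypeB 1.000, subtypeC 1.000

head(res$predictions, 3)
#>   sample_id predicted n_votes_for_winner
#> 1      s008   control                 10
#> 2      s004   control                  7
#> 3      s056  subtypeA                 10
```

The edge table reads: pair `g0053–g0064` is strongly co-expressed in
subtypeB (`cor 0.972`) and has no significant correlation in any other
group, giving the maximal specificity margin `delta`. The evaluation
block shows the held-out 10% of each subtype classified by vote — here
all 11 test samples, including the single held-out sample of the
12-sample minority subtype, are recovered.

For real data, `load_expression()` reads a genes × samples TSV plus a
two-column sample/subtype file (use `log_transform = TRUE` for
FPKM-like values), and the same `run_pipeline()` call applies. A thin
command-line front end is included:

```sh
Rscript inst/cli/scm.R simulate --seed 7 --outdir sim/
Rscript inst/cli/scm.R run --matrix sim/expression.tsv \
    --labels sim/labels.tsv --seed 7 --edges 50 --outdir out/
```

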
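# phenosim

Cross-species phenotype similarity and disease-gene prioritization — with
the bias diagnostics that tell you when a "good" result is an artifact.

## The problem

Model-organism databases record the phenotypes caused by loss-of-function
mutations; human diseases are annotated with human phenotype classes. If
orthologous genes produce similar phenotypes, a mouse (or fish, fly, yeast)
gene whose mutant phenotypes resemble a disease's profile is a candidate for
that disease. Making that comparison requires an *integrated* phenotype
ontology in which species-specific vocabularies are bridged by equivalence
assertions, a similarity measure over annotation sets, and a ranking
protocol. It also requires skepticism: disease-gene orthologs are annotated
more heavily and more specifically than other genes, and both semantic
similarity scores and machine-learning models can exploit that study bias to
"predict" associations with no biological signal at all.

phenosim is for computational biologists who build or evaluate such
pipelines. It provides:

* an integrated phenotype ontology model — OBO-subset parsing, equivalence
  handled by canonical-representative merging, ancestor closure,
  cross-species subsumption counts, anatomy-derived abnormality classes;
* annotation corpora with true-path propagation, and phenotype pooling
  across organisms via orthology;
* four similarity methods: Resnik/best-match-average over information
  content, and three skip-gram embedding variants (undirected walks with
  equivalence edges, directed walks without them, axiom sentences) trained
  by a deterministic single-threaded word2vec-style trainer;
* a disease-independent **naive classifier** (rank genes by summed
  annotation IC) and a supervised perceptron over concatenated embeddings
  with leakage-audited, disease-stratified cross-validation;
* the rank-based evaluation protocol: per-disease TPR/FPR at every rank,
  macro-averaged ROC, trapezoidal AUC, paired-bootstrap AUC comparison;
* bias diagnostics: a one-tailed Student's t-test on total annotation IC,
  and the IC-gap statistic (distance from a model-organism class to its
  most informative human superclass);
* a synthetic benchmark generator with controllable signal fidelity and
  study-bias knobs, so the whole pipeline is testable offline.

## The core quantities

For a corpus of annotated entities, `p(c)` is the fraction whose propagated
annotation set contains class `c`, and `IC(c) = -log2 p(c)`. Two classes are
compared by the IC of their most informative common ancestor (Resnik), and
two annotation sets by the symmetric best match average:

    BMA(A,B) = 1/2 * ( mean_a max_b sim(a,b) + mean_b max_a sim(a,b) )

For each disease, all genes are ranked by similarity; TPR and FPR are taken
at every rank over a fixed gene universe, averaged across diseases at each
rank, and summarized as the trapezoidal ROCAUC (0.5 = random, 1.0 =
perfect).

## Worked example

```r
library(phenosim)

# a small benchmark: 80-class subtrees, 60 genes, 25 diseases
cfg <- synthetic_config(n_human_classes = 80, n_model_classes = 80,
                        n_genes = 60, n_diseases = 25, seed = 42)
bundle <- generate_bundle(cfg)
bundle
#> <benchmark_bundle> mouse: 161 classes, 60 genes, 25 diseases, 25 associations

genes <- combine_organism_annotations(bundle$gene_corpora,
                                      list(bundle$orthology), "human")
ic <- compute_ic(list(genes, bundle$disease_corpus))
sim <- similarity_matrix_resnik(genes, bundle$disease_corpus, ic,
                                bundle$ontology)
roc <- rank_genes(sim, truth = bundle$truth) |> roc_from_rankings()
roc
#> <roc_result> macro ROCAUC 0.9993 over 25 diseases (universe 60 genes)
```

At the default signal fidelity (90% of disease phenotypes mirrored into the
associated gene's mouse ortholog through the ontology bridges), Resnik-BMA
recovers the planted associations almost perfectly. The naive classifier —
which ranks genes by summed annotation IC and predicts the *same* list for
every disease — sits at chance on this unbiased corpus, and the
paired-bootstrap comparison confirms the difference:

```r
naive <- naive_rank(ic, genes, sort(unique(bundle$truth$disease_id)),
                    truth = bundle$truth) |> roc_from_rankings()
naive
#> <roc_result> macro ROCAUC 0.4569 over 25 diseases (universe 60 genes)

compare_auc(roc, naive, n_boot = 1000, seed = 1)
#> # A tibble: 1 × 6
#>   auc_a auc_b estimate p.value n_boot n_diseases
#>   <dbl> <dbl>    <dbl>   <dbl>  <int>      <int>
#> 1 0.999 0.457    0.542 0.00200   1000         25

study_bias_test(total_ic(genes, ic), unique(bundle$truth$gene_id))
#> # A tibble: 1 × 6
#>   statistic p.value mean_disease mean_other n_disease n_other
#>       <dbl>   <dbl>        <dbl>      <dbl>     <int>   <int>
#> 1    -0.657   0.743         16.9       18.0      25      35
```

With the bias knobs off there is no total-IC difference between
disease-associated and other genes (p = 0.74). Regenerate the bundle with
`fidelity = 0, bias_multiplier = 3, depth_bias = TRUE` and the picture
inverts: the naive classifier scores well above chance despite zero
biological signal, and the t-test rejects decisively — annotation bias
masquerading as predictive performance. `autoplot()` on any `roc_result`
draws the curve; `tidy()`/`glance()` return the points and the summary.

An end-to-end experiment (bundle generation, every requested method,
rankings, ROC TSVs, bias report, manifest) runs from one config:

```r
run_experiment(list(seed = 1, methods = c("resnik_bma", "naive", "dl2vec")),
               out_dir = "results/demo")
```

A thin CLI wrapper for generate/run/eval lives at
`inst/scripts/phenosim.R`.

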
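# pldaCells

Penalized latent Dirichlet allocation (pLDA) for single-cell RNA-seq,
with a hierarchical cell-type-then-age prediction pipeline and per-topic
gene-set enrichment.

## The problem

A droplet scRNA-seq experiment yields a sparse gene-by-cell count matrix
in which each cell runs a handful of latent biological programs.
Treating cells as documents and genes as words, LDA summarizes each cell
by a K-simplex of topic frequencies Θ and each topic by a gene-frequency
simplex (a row of the K×G matrix β).  Many genes, however, are expressed
at near-identical relative frequency in every program — biological "stop
words" that add noise without separating topics.  pLDA augments the
variational LDA objective with a tuning parameter λ that shrinks each
gene's per-topic frequencies toward their across-topic mean:

    maximize  l(α, β) − λ Σ_k Σ_g (β_kg − (1/K) Σ_l β_lg)²

Homogeneous genes can then be recognised (cosine distance of their β
column to the uniform direction) and filtered before interpretation.
λ = 0 recovers standard variational LDA.

On top of the model the package provides:

* **fold-in** (`inferProfiles`): topic profiles for new cells with the
  trained β frozen — a transfer-learning step;
* **classification** (`trainClassifier`, `predictHierarchical`): √Θ
  features into one multiclass cell-type SVM, then one binary age SVM
  per cell type, applied to the *predicted* type;
* **interpretation** (`filterHeterogeneousGenes`,
  `conditionalEnrichment`): heterogeneous-gene universe, argmax topic
  assignment, exact (conditionally eliminated, if a DAG is given)
  hypergeometric enrichment against user GMT gene sets;
* **evaluation** (`confusionCounts`, `recallByAge`,
  `hierarchicalConfusion`, `learningCurve`);
* **simulation** (`makeTopics`, `makeArchetypes`, `simulateCells`,
  `presetScenario`): Dirichlet-multinomial corpora with planted cell
  types, ages, marker genes and stop-word genes, so the entire pipeline
  is testable offline.

Audience: computational biologists who want an interpretable, low-
dimensional summary of scRNA-seq counts and a reproducible protocol for
predicting cell identity and age group from it.

## Worked example

```r
library(pldaCells)
library(SummarizedExperiment)

## a ~1,500-cell synthetic aging-blood-like corpus: 5 cell types
## (one rare), K = 8 topics, 20 stop-word genes, old-age topic shift 0.3
sce <- presetScenario("small", seed = 1)
ann <- as.data.frame(colData(sce))

## stratified half split within each cell type; rare-type audit
sp   <- stratifiedSplit(ann, seed = 2)
rare <- flagRareTypes(ann, sp)            # "RBC" (24 young cells)

counts <- assay(sce, "counts")
mTr <- filterGenesMinCount(counts[, sp$train], 1)
mTe <- counts[rownames(mTr), sp$test]
aTr <- ann[match(sp$train, ann$cell_id), ]
aTe <- ann[match(sp$test,  ann$cell_id), ]

## penalized topic model on the training half
fit <- fitPLDA(mTr, K = 8, lambda = 100, seed = 3)
fit
#> TopicModel (penalized LDA fit)
#>   topics: 8  genes: 240  cells: 732
#>   lambda: 100  alpha[1]: 0.125
#>   EM iterations: 17 (converged)
#>   final penalized objective: -2355694.8

## hierarchical SVMs on sqrt(theta); fold-in of the test half
bundle <- trainClassifier(topicProfiles(fit), aTr$major_type, aTr$age,
                          seed = 3)
pred <- predictHierarchical(inferProfiles(mTe, fit), bundle)

mean(pred$predicted_type == aTe$major_type)   # cell-type accuracy
#> [1] 1
ageGiven <- predictAgeGivenType(inferProfiles(mTe, fit), bundle,
                                aTe$major_type)
mean(ageGiven == aTe$age)                     # age accuracy, correct type given
#> [1] 0.9043716

## stop-word filtering and per-topic enrichment of the planted markers
keep   <- filterHeterogeneousGenes(topicGeneFreq(fit), cutoff = 0.3)
assign <- assignGenesToTopics(topicGeneFreq(fit), keep)
```

Cell-type accuracy is perfect on this clean synthetic corpus and the
age call (given the correct type) recovers the planted 0.3 topic shift
for ~90% of test cells; with `presetScenario("small", ageShift = 0)`
the same pipeline sits at chance, as it should.  The methods vignette
(`vignettes/plda-methods.Rmd`) documents the model, the penalty-sign
convention, the solver, all defaults, and what the simulation does and
does not emulate.

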
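# scImageHier

Hierarchical cell-type annotation for single-cell RNA-seq, by classifying
**image renderings** of per-cell expression profiles with a convolutional
network trained under an **adaptive hierarchical focal loss**.

## The problem and who this is for

Annotating immune cells is a two-level problem: a cell belongs to a major
lineage (T, B, NK, ...) and usually to a finer subtype within it (CD8+ T,
IgA+ plasma, ...). Flat classifiers ignore that structure: abundant, easy
classes dominate training while the hard part — telling apart
transcriptionally similar subtypes inside one lineage, some of them rare —
is exactly where they fail. This package is for researchers who want
taxonomy-aware annotation with per-cell probabilities at both levels, a
principled screen for populations missing from the reference taxonomy, and
per-gene attributions for every class decision.

## The method

1. **Tabular-to-image transform.** Genes are laid out in 2-D by t-SNE (or
   UMAP) on reference expression, so co-expressed genes land together, then
   mapped injectively to pixels by linear sum assignment (cost = squared
   distance to pixel centers), eliminating collisions. A cell's image holds
   each gene's min-max-normalized expression at its pixel. Random masking
   of gene pixels during training makes the model robust to query datasets
   that lack part of the gene panel.
2. **Hierarchical classifier.** A compact CNN feeds two heads: base types
   and subtypes. Training minimizes

   L_total = α·FL_base + (1−α)·FL_sub,  with FL(p) = −(1−p_true)^γ log p_true (γ = 2),

   and α updated each step by momentum smoothing of the loss ratio,

   α(t+1) = β·α(t) + (1−β)·FL_base/(FL_base+FL_sub),  β = 0.9,

   so optimization pressure flows to whichever level is currently harder.
   After training, each head gets a temperature fitted on validation
   likelihood, so reported probabilities are calibrated.
3. **Masked inference.** The predicted base type zeroes all foreign
   subtypes; survivors are renormalized. Terminal lineages (no subtypes)
   end at the base prediction.
4. **Rare-population score.** `max(base probs) − max(masked subtype
   probs)`: high for cells confidently placed in a lineage that none of
   the trained subtypes fits — candidate novel populations.
5. **Attribution.** Expected-gradients SHAP or exact occlusion maps,
   folded back through the pixel assignment to per-gene importances per
   class.

## Worked example

The package ships a synthetic-data generator with planted hierarchical
marker structure (T and B lineages with three subtypes each, a terminal NK
lineage), so the whole pipeline runs end-to-end without downloads. Here
the standard 120-cells-per-population scenario trains the model and a
fresh draw of 40 cells per population from the same generative model
serves as the query:

```r
library(scImageHier)

scn   <- standardScenario(nCellsPerSubtype = 160L)
sce   <- logNormalize(simulateCells(scn))
train <- unlist(lapply(0:6, function(p) p * 160L + 1:120))
query <- setdiff(seq_len(ncol(sce)), train)

map <- fitPixelMap(sce[, train], gridDim = c(32L, 32L), seed = 3)
map
#> PixelMap: 200 genes on a 32x32 grid (tsne, perplexity 15, seed 3)

model <- trainClassifier(sce[, train], map, scn@hierarchy,
                         epochs = 80, lr = 3e-3, seed = 5,
                         config = classifierConfig(featureDim = 128L,
                                                   f1 = 16L, f2 = 32L))
ev <- evaluateClassifier(model, sce[, query], map)
round(c(base = ev$base$accuracy, subtype = ev$subtype$accuracy), 3)
#>    base subtype
#>   0.989   0.912
```

Base-type accuracy is near-perfect and subtype accuracy stays above 90% on
cells the model never saw, under 30% dropout noise. Annotation attaches
labels, calibrated probabilities and the novelty screen to the query:

```r
ann <- annotateCells(sce[, query], model, map)
head(colData(ann)[, c("baseLabel", "subLabel", "baseProb", "rareScore")], 4)
#>           baseLabel    subLabel  baseProb rareScore
#> cell00121         T       CD4 T  0.979562 0.3325099
#> cell00122         T       CD4 T  0.999999 0.0706046
#> cell00123         T       CD4 T  1.000000 0.0926084
#> cell00124         T       CD8 T  0.999998 0.5802114
```

and gene attribution recovers the generator's planted markers — the top
five genes for the CD8 T subtype are exactly its five marker genes:

```r
imp <- geneImportance(model, sce[, query], map, "CD8 T",
                      level = "subtype", method = "occlusion")
topGenes(imp, "CD8 T", "subtype", 5)
#> [1] "G0021" "G0023" "G0025" "G0022" "G0024"
```

A command-line interface (`inst/exec/scImageHier`) exposes the same
pipeline as `simulate`, `fit-mapper`, `train`, `predict` and `explain`
subcommands.

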
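# dtafuse

Drug–target affinity (DTA) regression from molecular graphs and protein
contact-map graphs, with structure-aware attention and early fusion.

## What it does, and for whom

Estimating how strongly a small molecule binds a protein — as a pKd
(`-log10(Kd / 1e9)`, Kd in nM) or a KIBA-style composite score — is the
workhorse regression task of virtual screening and drug repositioning.
`dtafuse` is for computational chemists and method developers who want a
fully inspectable, single-CPU implementation of a structure-aware DTA
model: every stage is an exported, tested R function, and a synthetic data
generator makes the whole pipeline runnable with no external datasets,
pretrained weights, or GPUs.

The model, end to end:

* **Drug featurization** — SMILES/SDF to a heavy-atom graph; nine integer
  atom attributes and three bond attributes against frozen dictionaries.
* **Structural encodings** — degree-centrality embeddings added to node
  features, plus two additive attention biases per atom pair: a learnable
  scalar per shortest-path-distance bucket, and the mean learnable
  projection of bond features along one (deterministic) shortest path.
* **Sparse-attention drug encoder** — three top-S self-attention layers
  (logits `(h_i W_Q)(h_j W_K)^T / sqrt(d)` + biases; only the S queries
  with the highest max-minus-mean sparsity scores attend exactly, the
  rest emit the mean value vector), interleaved with two distillation
  layers (width-3 Conv1d, ELU, stride-2 max pool) that halve the node
  axis, then global max pooling to one drug vector.
* **GCN drug encoder** — `ReLU(Â H W)` layers with
  `Â = D̃^{-1/2}(A + I)D̃^{-1/2}`, residual blocks `ReLU(F(H) + H)`,
  global max pooling and two linear layers to the drug super-node vector.
* **Protein graph** — residue nodes carrying sequence-embedding ⊕ one-hot
  8-state secondary structure ⊕ relative solvent accessibility; contact
  edges between residues at sequence separation ≥ 2 and distance < 8 Å,
  plus backbone edges.
* **Early fusion** — the drug super node is joined to every residue of
  the protein graph, the heterograph is refined by GCN + residual blocks,
  and a node-type mask separates the refined drug and protein parts.
* **Affinity head** — concat(pre-fusion drug feature, refined drug node)
  and pooled refined protein features through a fully connected block to
  one real number, trained with Adam on MSE via the package's own
  reverse-mode autodiff engine.
* **Metrics** — MSE, RMSE, Pearson, Spearman, concordance index (ties
  count 0.5; fast path cross-checked against an O(n²) reference), r².

## Worked example

Generate a synthetic benchmark, split it 6 ways, train the model, and
evaluate on the held-out part:

```r
library(dtafuse)

spec <- dta_fixture_spec(n_drugs = 8, n_proteins = 6, n_pairs = 48,
                         protein_length = c(25, 40), noise_sd = 0.1,
                         seed = 42)
ds   <- gen_dataset(spec)
#> <dta_dataset: 8 drugs, 6 proteins, 48 pairs (pkd)>
plan <- make_splits(ds, seed = 42)
#> <dta_split_plan: 48 pairs, parts 8/8/8/8/8/8, test part 6>
tr   <- train_model(ds, plan, dta_config(epochs = 30L), seed = 42)
ev   <- evaluate_model(tr, ds, plan)
print(ev$metrics)
#> affinity metrics (n = 8)
#>   MSE 0.0176 | RMSE 0.1326 | Pearson 0.9836 | Spearman 0.7619 | CI 0.7857 | r2 0.9622
head(ev$predictions, 3)
#>   drug_id protein_id   y_true   y_pred
#> 1    D005       P002 2.607692 2.691948
#> 2    D005       P003 1.162321 1.283467
#> 3    D008       P006 1.190553 1.159943
```

The synthetic labels are a known function of drug descriptors (size,
aromatic rings), protein descriptors (mean accessibility, helix fraction)
and their interaction, plus Gaussian noise (sd 0.1) — so an MSE of 0.018
against a label standard deviation of ≈ 0.45 means the model has
recovered essentially all of the available signal on the eight held-out
pairs; the rank metrics (Spearman, CI) are coarser at n = 8.  Individual
stages are exported too (`parse_molecule()`, `build_drug_graph()`,
`compute_spd()`, `sparsepro_attention()`, `esc_forward()`,
`encode_drug()`, `build_protein_graph()`, `fuse()`, `dtg_refine()`,
`masked_split()`, `predict_affinity()`), and
`inst/scripts/dtafuse.R` offers `synth` / `featurize` / `train` /
`predict` / `evaluate` subcommands for shell use.

See the vignette (`vignettes/dtafuse-methods.Rmd`) for the model's
assumptions, parameter meanings, and what the synthetic generator does
and does not emulate.

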
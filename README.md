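# cytosupercell

Supercell aggregation for large flow and mass cytometry datasets.

Cytometry experiments routinely profile millions of cells, while most of
the analysis ecosystem — clustering, batch correction, differential
expression and abundance — is comfortable with tens of thousands of
observations. `cytosupercell` bridges that gap for analysts working in R:
it groups phenotypically similar cells of the same sample into
**supercells**, runs the heavy analyses at the supercell level, and
expands results back to single cells (a free lookup) wherever per-cell
resolution matters.

## The method

For each sample with *n* cells and marker matrix *X* (arcsinh scale):

1. **PCA**: centre *X* per marker, keep the top `min(n_pcs, n_markers)`
   components (default 10).
2. **kNN graph**: exact Euclidean *k*-nearest neighbours (default
   *k* = 5) on the PC scores, symmetrised by union.
3. **Walktrap**: community detection by length-4 random walks yields a
   complete merge dendrogram per connected component.
4. **Gamma cut**: the dendrogram is cut into *k* = round(*n*/γ) groups
   (half rounded up, clamped to [components, *n*]). γ is the ratio of
   cells to supercells — γ = 20 turns 85,715 cells into exactly 4,286
   supercells.
5. **Aggregation**: per supercell, the mean (or median) of each marker
   plus the member count; a cell→supercell map records the partition.

Because steps 1–3 are independent of γ, a stored dendrogram can be
**re-cut** at any other γ in milliseconds (`recut()`), bit-identically to
a fresh run. Multi-sample data are processed strictly per sample —
supercells never span samples — with samples scheduled across workers in
descending cell-count order; outputs are identical for any worker count.

The package also ships the evaluation metrics used to judge supercell
quality (per-supercell purity, adjusted Rand index, normalised mutual
information, proportion-weighted label-transfer accuracy, and binned
earth mover's distance for batch assessment), downstream plumbing
(majority-vote annotation, pseudobulk sample×cell-type matrices, the
"more than 3 cells per sample" cluster filter, single-cell proportion
tables), a Gaussian-mixture synthetic data generator with known truth,
and a minimal FCS 3.0/3.1 reader.

## Worked example

```r
library(cytosupercell)
library(data.table)

cfg <- sim_config(n_samples = 2, cells_per_sample = 5000, seed = 42)
tab <- generate_mixture(cfg)                      # 10,000 cells, 10 markers, 5 types
run <- run_all_samples(tab, core_params(gamma = 20, seed = 42))
run
#> supercell run: 10000 cells -> 500 supercells across 2 sample(s) (gamma = 20)

supercell_purity(run$partition, tab[, .(cell_id, cell_type)])
#> purity over 500 supercells (10000 labelled cells): mean 0.9914, 89.0% fully pure

head(run$expression[, 1:6], 3)
#>    supercell_id sample_id n_cells       m1        m2        m3
#> 1: sample1_SC_1   sample1      48 1.165327 0.8025437 0.7686124
#> 2: sample1_SC_2   sample1      50 1.086217 1.0828898 1.9402127
#> 3: sample1_SC_3   sample1      24 1.063483 1.1437036 2.1511282

# re-cut one sample at a coarser granularity, without recomputing
p50 <- recut(run$dendrograms[["sample1"]], new_gamma = 50)
length(unique(p50$supercell_id))
#> [1] 100
```

At γ = 20 each sample of 5,000 cells is cut into 250 supercells whose
sizes centre on γ; the purity line says the average supercell is 99%
homogeneous in true cell type, with 89% of supercells perfectly pure —
the compression loses almost no biological signal on well-separated
populations.

A command-line interface wraps the same functions
(`inst/cli/cytosupercell run | recut | simulate | qc | downstream`); see
the vignette for parameter guidance and design notes.

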
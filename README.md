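# hanppis

Residue-level prediction of protein–protein interaction (PPI) sites with a
two-level hierarchical attention network, in R.

A PPI site is a residue whose solvent-accessible surface changes when the
protein binds a partner. `hanppis` scores every residue of a protein from
six sequence-derived feature blocks — one-hot identity, PSI-BLAST PSSM,
DSSP secondary structure, Kyte–Doolittle hydropathy, relative sequence
position, and a projected per-residue embedding — fused into a
101-dimensional vector. A sliding window (default 7 residues) around each
target residue is segmented into K-mers (default 3); a bidirectional GRU
plus attention pooling encodes residues into K-mer vectors, a second
Bi-GRU plus attention encodes K-mers into a fragment vector, and a softmax
head emits `p(site)`:

    s_t = u' tanh(W h_t + b),   α = softmax(s),   v = Σ_t α_t h_t

applied once over residues within each K-mer and once over K-mers. The
attention weights α are the model's interpretability output. Training uses
class-weighted cross-entropy (positive weight 7 against the ~1:5.5
site/non-site imbalance) with Adam, batch size 3, and 86 hidden units per
GRU direction — the published setting. The forward/backward core is
hand-derived and compiled (RcppArmadillo); a pure-R reference
implementation and a finite-difference gradient oracle pin it down in the
test suite.

Everything runs without external databases: a seeded synthetic generator
plants a short motif in background sequence and labels its occurrences, so
the full pipeline (features → fragments → training → evaluation →
attention) is testable end to end, and file-based runs consume the real
formats (FASTA, PSI-BLAST ASCII PSSM, classic DSSP, tabular embeddings).

## Worked example

```r
library(hanppis)

# a labeled synthetic corpus: 60 proteins, planted "KDY" motif,
# ~5.5:1 class imbalance
recs <- generate_proteins(synth_config(n_proteins = 60,
                                       len_range = c(50, 50), seed = 1))
src  <- synth_feature_source(sigma = 0, seed = 1)

cfg  <- han_config(seed = 1)          # w=7, k=3, u=86, P=50, weight 7
ds   <- build_dataset(recs, src, cfg) # protein-level 80/20 split
ds
#> <han_dataset> 60 proteins (48 train / 12 test), 3000 fragments, 480 positive

model <- han_train(ds, cfg)
evaluate_model(model, ds)
#> <metrics_report> accuracy 0.998  precision 0.990  recall 1.000  F1 0.995

# attention for one residue: which K-mers and residues drove the call?
explain_attention(model, ds$records[[1]], src, position = 5)
#> <attention_report> synth0001 position 5 (D), window DYKDYSA, p(site) = 0.997
#>   K-mer 1 'DYK'    weight 0.0285 | residues: 0.0000 0.0417 0.9583
#>   K-mer 2 'DYS'    weight 0.9498 | residues: 0.0000 0.3739 0.6261
#>   K-mer 3 'A'      weight 0.0218 | residues: 1.0000
```

The test F1 of 0.995 reflects the synthetic task's construction: the
label is an exact function of the 7-residue window, so a correctly
implemented model should approach perfect recovery. The attention report
shows the model putting 95% of its K-mer-level weight on the K-mer
carrying the labeled residue. Numbers are from this configuration and
seed; any fixed seed reproduces its own numbers bit-for-bit.

The same pipeline is scriptable from a shell via the CLI launcher, which
installs with the package (find it with
`system.file("exec", "hanppis", package = "hanppis")`; symlink it onto
your `PATH` or call it directly):

```sh
hanppis simulate --out-dir data --n-proteins 60 --min-len 50 --max-len 50 --seed 1
hanppis train    --fasta data/sequences.fasta --labels data/labels.txt \
                 --pssm-dir data/pssm --dssp-dir data/dssp --emb-dir data/emb \
                 --out model.json --seed 1
hanppis predict  --model model.json --fasta data/sequences.fasta \
                 --emb-dir data/emb --out predictions.tsv
hanppis explain  --model model.json --fasta data/sequences.fasta \
                 --protein synth0001 --position 25 --out attention.tsv
```

`ablate` (drop one feature block and retrain) and `sweep` (window sizes
7–15) reproduce the corresponding experiment tables on whatever corpus you
point them at.

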